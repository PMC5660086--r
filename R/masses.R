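## Monoisotopic mass bookkeeping for residues, modifications, peptides
## (including branched remnant peptides) and fragment ions.

# Monoisotopic residue (i.e. dehydrated amino-acid) masses, Da.
.RESIDUE_MASS <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.MASS_WATER  <- 18.01056468
.MASS_PROTON <- 1.00727646688
.MASS_NH3    <- 17.02654910
.MASS_H      <- 1.00782503207

#' Monoisotopic residue mass table
#'
#' Returns the monoisotopic masses (Da) of the 20 standard amino-acid
#' residues (dehydrated, i.e. as incorporated in a peptide chain), together
#' with the water and proton masses used throughout the package.
#'
#' @return A list with elements \code{residues} (named numeric vector of 20
#'   residue masses), \code{water} and \code{proton} (scalars, Da).
#' @examples
#' residueMasses()$residues[["G"]]   # 57.02146
#' @export
residueMasses <- function() {
  list(residues = .RESIDUE_MASS, water = .MASS_WATER, proton = .MASS_PROTON)
}

## ---- modification registry --------------------------------------------

# Registry environment: name -> list(deltaMass, targets, position).
.mod_registry <- new.env(parent = emptyenv())

.register_builtin_mods <- function() {
  # GlyGly: the diglycyl remnant left on a modified lysine; as an isopeptide
  # adduct its delta is two glycine residue masses (no extra water).
  registerModification("GlyGly", 2 * .RESIDUE_MASS[["G"]], "K")
  # Heavy lysine 13C6 15N2: 6 x (13C - 12C) + 2 x (15N - 14N).
  registerModification("HeavyK",
    6 * (13.00335484 - 12) + 2 * (15.00010890 - 14.00307401), "K")
  registerModification("Carbamidomethyl", 57.02146372, "C")
  registerModification("Oxidation", 15.99491462, "M")
}

#' Register a modification
#'
#' Adds a named modification to the package registry so that it can be
#' referenced by name in peptides, PSM tables and the localization scorer.
#' Built-ins: \code{GlyGly} (+114.04293, K), \code{HeavyK} (13C6 15N2
#' SILAC lysine, +8.01420, K), \code{Carbamidomethyl} (+57.02146, C),
#' \code{Oxidation} (+15.99491, M).
#'
#' @param name Unique modification name.
#' @param deltaMass Monoisotopic delta mass in Da (finite).
#' @param targets Character vector of one-letter residue codes the
#'   modification may sit on.
#' @param position Positional constraint: \code{"anywhere"},
#'   \code{"N-term"} or \code{"C-term"}.
#' @param overwrite Replace an existing registration of the same name?
#' @return The registered definition, invisibly.
#' @export
registerModification <- function(name, deltaMass, targets,
                                 position = c("anywhere", "N-term", "C-term"),
                                 overwrite = FALSE) {
  position <- match.arg(position)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(deltaMass) || length(deltaMass) != 1L || !is.finite(deltaMass))
    stop("deltaMass must be a single finite number")
  targets <- unique(toupper(as.character(targets)))
  bad <- setdiff(targets, names(.RESIDUE_MASS))
  if (length(bad)) stop("unknown target residue(s): ", paste(bad, collapse = ", "))
  if (!overwrite && exists(name, envir = .mod_registry, inherits = FALSE) &&
      !isTRUE(all.equal(get(name, envir = .mod_registry)$deltaMass, deltaMass)))
    stop("modification '", name, "' already registered with a different mass")
  def <- list(name = name, deltaMass = unname(deltaMass),
              targets = targets, position = position)
  assign(name, def, envir = .mod_registry)
  invisible(def)
}

#' Look up a modification delta mass
#'
#' @param name Registered modification name.
#' @return Monoisotopic delta mass in Da.
#' @examples
#' modMass("GlyGly")   # 114.04293
#' @export
modMass <- function(name) {
  getModification(name)$deltaMass
}

#' @rdname modMass
#' @return \code{getModification} returns the full definition (name, delta
#'   mass, allowed targets, positional constraint).
#' @export
getModification <- function(name) {
  if (!exists(name, envir = .mod_registry, inherits = FALSE))
    stop("unknown modification: '", name, "'")
  get(name, envir = .mod_registry, inherits = FALSE)
}

#' @rdname modMass
#' @export
listModifications <- function() {
  sort(ls(envir = .mod_registry))
}

## ---- Peptide ----------------------------------------------------------

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  if (!nzchar(sequence)) stop("empty peptide sequence")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.RESIDUE_MASS))
  if (length(bad))
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  res
}

#' @export
setClass("Peptide", representation(
  sequence = "character",
  mods     = "data.frame",   # columns: position (integer), name (character)
  charge   = "integer"
))

setValidity("Peptide", function(object) {
  msg <- character()
  res <- tryCatch(.check_sequence(object@sequence),
                  error = function(e) {msg <<- c(msg, conditionMessage(e)); NULL})
  m <- object@mods
  if (!all(c("position", "name") %in% names(m)))
    msg <- c(msg, "mods must have columns 'position' and 'name'")
  else if (!is.null(res) && nrow(m)) {
    if (any(m$position < 1L | m$position > length(res)))
      msg <- c(msg, "modification position out of range")
    else for (i in seq_len(nrow(m))) {
      def <- tryCatch(getModification(m$name[i]),
                      error = function(e) {msg <<- c(msg, conditionMessage(e)); NULL})
      if (!is.null(def) && !(res[m$position[i]] %in% def$targets))
        msg <- c(msg, sprintf("residue %s at position %d not a valid target for %s",
                              res[m$position[i]], m$position[i], m$name[i]))
    }
  }
  if (length(object@charge) == 1L && !is.na(object@charge) && object@charge < 1L)
    msg <- c(msg, "charge must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a (possibly modified) peptide
#'
#' @param sequence Residue string (one-letter codes, standard 20).
#' @param mods Either \code{NULL}, a data.frame with columns
#'   \code{position} (1-based) and \code{name} (registered modification
#'   name), or a named numeric-like convenience vector
#'   \code{c("5" = "GlyGly")} mapping positions to names.
#' @param charge Optional precursor charge (integer >= 1).
#' @return A \code{Peptide} object.
#' @examples
#' p <- Peptide("HAADKGGSAAK", mods = data.frame(position = 5, name = "GlyGly"))
#' peptideMass(p)
#' @export
Peptide <- function(sequence, mods = NULL, charge = NA_integer_) {
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), name = character(),
                       stringsAsFactors = FALSE)
  } else if (is.character(mods) && !is.null(names(mods))) {
    mods <- data.frame(position = as.integer(names(mods)),
                       name = unname(mods), stringsAsFactors = FALSE)
  } else {
    mods <- as.data.frame(mods, stringsAsFactors = FALSE)
  }
  mods$position <- as.integer(mods$position)
  new("Peptide", sequence = sequence, mods = mods,
      charge = as.integer(charge))
}

setMethod("show", "Peptide", function(object) {
  s <- strsplit(object@sequence, "")[[1]]
  if (nrow(object@mods)) {
    ann <- vapply(seq_along(s), function(i) {
      nm <- object@mods$name[object@mods$position == i]
      if (length(nm)) paste0(s[i], "(", paste(nm, collapse = ","), ")") else s[i]
    }, character(1))
    s <- ann
  }
  cat("Peptide: ", paste(s, collapse = ""), "\n", sep = "")
  if (!is.na(object@charge)) cat("  charge: ", object@charge, "\n", sep = "")
  cat("  neutral mass: ", format(peptideMass(object), nsmall = 5), " Da\n", sep = "")
})

#' Peptide sequence and modifications accessors
#' @param x A \code{Peptide}.
#' @return \code{peptideSequence}: the residue string;
#'   \code{peptideMods}: the modification data.frame.
#' @export
peptideSequence <- function(x) x@sequence

#' @rdname peptideSequence
#' @export
peptideMods <- function(x) x@mods

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses, plus one water, plus
#' all modification delta masses (a branched diglycyl remnant counts as a
#' +114.04293 delta on its lysine).
#'
#' @param p A \code{Peptide}, or a plain residue string (taken unmodified).
#' @return Neutral mass in Da.
#' @export
peptideMass <- function(p) {
  if (is.character(p)) p <- Peptide(p)
  res <- .check_sequence(p@sequence)
  m <- sum(.RESIDUE_MASS[res]) + .MASS_WATER
  if (nrow(p@mods))
    m <- m + sum(vapply(p@mods$name, modMass, numeric(1)))
  unname(m)
}

## ---- fragment ions ----------------------------------------------------

#' Theoretical fragment ions
#'
#' Computes b/y (CID) and c/z (ETD) fragment m/z values for a peptide,
#' carrying modification masses on whichever fragment contains the modified
#' residue. Conventions: neutral b_i = sum of the first i residue masses
#' (+ mods), y_j = sum of the last j residue masses + water (+ mods),
#' c = b + NH3, and z (z-dot radical) = y - NH3 + H. m/z at charge
#' \eqn{z} is (neutral + z protons)/z.
#'
#' @param p A \code{Peptide} (length >= 2) or residue string.
#' @param series Character vector drawn from \code{c("b","y","c","z")}.
#' @param maxCharge Highest fragment charge to report (>= 1).
#' @return data.frame with columns \code{label} (e.g. \code{"b3^2"}),
#'   \code{series}, \code{index}, \code{charge}, \code{mz}.
#' @examples
#' fragmentIons("AG", series = "b", maxCharge = 1)$mz   # 72.04439
#' @export
fragmentIons <- function(p, series = c("b", "y"), maxCharge = 1L) {
  if (is.character(p)) p <- Peptide(p)
  series <- unique(series)
  bad <- setdiff(series, c("b", "y", "c", "z"))
  if (length(bad)) stop("unknown ion series: ", paste(bad, collapse = ", "))
  maxCharge <- as.integer(maxCharge)
  stopifnot(maxCharge >= 1L)
  res <- .check_sequence(p@sequence)
  n <- length(res)
  if (n < 2L) stop("peptide must have length >= 2 for fragmentation")
  delta <- numeric(n)                 # per-position modification mass
  if (nrow(p@mods))
    for (i in seq_len(nrow(p@mods)))
      delta[p@mods$position[i]] <- delta[p@mods$position[i]] + modMass(p@mods$name[i])
  masses <- .RESIDUE_MASS[res] + delta
  prefix <- cumsum(masses)[-n]        # neutral b_i, i = 1..n-1
  suffix <- rev(cumsum(rev(masses)))[-1] + .MASS_WATER  # neutral y_j, j = n-1..1
  suffix <- rev(suffix)               # y_1 .. y_(n-1)
  neutral <- list(
    b = prefix,
    y = suffix,
    c = prefix + .MASS_NH3,
    z = suffix - .MASS_NH3 + .MASS_H
  )
  out <- do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(seq_len(maxCharge), function(z) {
      data.frame(
        label = sprintf("%s%d^%d", s, seq_len(n - 1L), z),
        series = s, index = seq_len(n - 1L), charge = z,
        mz = (neutral[[s]] + z * .MASS_PROTON) / z,
        stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
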