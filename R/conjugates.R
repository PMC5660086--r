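## Ubiquitin-like modifier attachment and remnant prediction.
##
## A modifier conjugated to a substrate lysine through an isopeptide bond
## is itself digested by the protease; whatever suffix of the modifier lies
## C-terminal to its last cleavage site stays attached to the lysine. For
## Ub under trypsin (...LRGG) and SUMO under WaLP (...QTGG) that suffix is
## the diglycyl (GG) remnant.

#' @export
setClass("ModifierProtein", representation(
  name     = "character",
  sequence = "character"
))

setValidity("ModifierProtein", function(object) {
  msg <- character()
  if (!nzchar(object@sequence)) msg <- c(msg, "sequence is empty")
  else tryCatch(.check_sequence(object@sequence),
                error = function(e) msg <<- c(msg, conditionMessage(e)))
  if (length(msg)) msg else TRUE
})

#' Ubiquitin-like modifier protein
#'
#' Holds the mature (processed) sequence of a modifier conjugated to
#' substrate lysines via its C-terminal glycine. Mature Ubl sequences end
#' in the attachment diglycine; a custom sequence that does not is accepted
#' with a warning (set \code{requireGG = FALSE} to silence).
#'
#' @param name Modifier name (e.g. \code{"SUMO1"}, \code{"Ub"}).
#' @param sequence Mature residue string.
#' @param requireGG Warn when the sequence does not end in \code{"GG"}?
#' @return A \code{ModifierProtein}.
#' @examples
#' ub <- ModifierProtein("toyUb", "MRGG")
#' remnant(ub, protease("trypsin"))   # "GG", 114.04293 Da
#' @export
ModifierProtein <- function(name, sequence, requireGG = TRUE) {
  sequence <- toupper(sequence)
  if (requireGG && !endsWith(sequence, "GG"))
    warning("modifier '", name, "' does not end in the attachment diglycine")
  new("ModifierProtein", name = name, sequence = sequence)
}

setMethod("show", "ModifierProtein", function(object) {
  n <- nchar(object@sequence)
  tail <- substring(object@sequence, max(1L, n - 9L), n)
  cat("ModifierProtein '", object@name, "': ", n,
      " aa, C-terminus ...", tail, "\n", sep = "")
})

#' @rdname ModifierProtein
#' @param x A \code{ModifierProtein}.
#' @export
modifierName <- function(x) x@name

#' @rdname ModifierProtein
#' @export
modifierSequence <- function(x) x@sequence

#' Built-in mature modifier sequences
#'
#' Loads the packaged modifier FASTA (mature C-termini). The packaged file
#' is a synthetic snapshot: sequences reconstructed from published mature
#' C-terminal regions, adequate for remnant prediction (which depends only
#' on the C-terminal suffix) but not a substitute for a curated database.
#'
#' @param path Optional path to a user FASTA of mature modifiers.
#' @return Named list of \code{ModifierProtein} objects.
#' @export
builtinModifiers <- function(path = system.file("extdata",
                                                "modifiers_synthetic.fasta",
                                                package = "sumoKGG")) {
  recs <- readFasta(path)
  mods <- lapply(seq_len(nrow(recs)), function(i)
    ModifierProtein(recs$id[i], recs$sequence[i]))
  names(mods) <- recs$id
  mods
}

#' Predicted proteolytic remnant of a modifier
#'
#' The remnant is the modifier suffix C-terminal to its last cleavage site
#' under \code{spec}; with no cleavage site the whole modifier remains
#' attached. The remnant mass is the sum of its residue masses (an
#' isopeptide adduct: the condensation with the lysine epsilon-amine loses
#' the water that a free peptide would carry), so \code{"GG"} weighs
#' 114.04293 Da.
#'
#' @param modifier A \code{ModifierProtein}.
#' @param spec A \code{ProteaseSpec}.
#' @return List with \code{sequence} and \code{mass} (Da).
#' @examples
#' sumoToy <- ModifierProtein("toySUMO", "MQKARTGG")
#' remnant(sumoToy, protease("walp"))      # "GG"
#' remnant(sumoToy, protease("trypsin"))   # "TGG"
#' @export
remnant <- function(modifier, spec) {
  seqc <- modifier@sequence
  n <- nchar(seqc)
  sites <- cleavageSites(seqc, spec)
  sites <- sites[sites < n]        # a cut after the final residue leaves nothing
  if (length(sites)) {
    start <- max(sites) + 1L
    remseq <- substring(seqc, start, n)
  } else {
    remseq <- seqc
  }
  res <- strsplit(remseq, "")[[1]]
  list(sequence = remseq, mass = unname(sum(.RESIDUE_MASS[res])))
}

# Ensure a remnant modification named e.g. "remnant:TGG" is registered so
# peptides can carry arbitrary remnants by name. "GG" maps to "GlyGly".
.remnant_mod_name <- function(remseq) {
  if (identical(remseq, "GG")) return("GlyGly")
  nm <- paste0("remnant:", remseq)
  if (!nm %in% listModifications()) {
    res <- strsplit(remseq, "")[[1]]
    registerModification(nm, unname(sum(.RESIDUE_MASS[res])), "K")
  }
  nm
}

#' Remnant-bearing peptides for a modified substrate site
#'
#' Digests the substrate with the modified lysine cleavage-blocked and
#' returns every peptide covering the site (over the allowed missed
#' cleavages), each carrying the modifier's predicted remnant as a
#' modification at the site.
#'
#' @param substrate Substrate residue string.
#' @param site 1-based position of the modified lysine.
#' @param modifier A \code{ModifierProtein}.
#' @param spec A \code{ProteaseSpec}.
#' @param params A \code{DigestParams}.
#' @return data.frame: \code{start}, \code{end}, \code{peptide},
#'   \code{missed}, \code{modPosition} (site position within the peptide),
#'   \code{remnant}, \code{remnantMass}, \code{peptideMass} (neutral, Da).
#' @examples
#' remnantPeptides("MARHAADKGGSAAKR", 8, ModifierProtein("toyUb", "MRGG"),
#'                 protease("trypsin"), DigestParams())
#' @export
remnantPeptides <- function(substrate, site, modifier, spec,
                            params = DigestParams()) {
  res <- .check_sequence(substrate)
  site <- as.integer(site)
  if (site < 1L || site > length(res)) stop("site out of range: ", site)
  if (res[site] != "K") stop("residue at site ", site, " is not K")
  rem <- remnant(modifier, spec)
  modname <- .remnant_mod_name(rem$sequence)
  peps <- digest(substrate, spec, params, blocked = site)
  peps <- peps[peps$start <= site & peps$end >= site, , drop = FALSE]
  if (!nrow(peps)) {
    return(data.frame(start = integer(), end = integer(),
                      peptide = character(), missed = integer(),
                      modPosition = integer(), remnant = character(),
                      remnantMass = numeric(), peptideMass = numeric()))
  }
  peps$modPosition <- site - peps$start + 1L
  peps$remnant <- rem$sequence
  peps$remnantMass <- rem$mass
  peps$peptideMass <- vapply(seq_len(nrow(peps)), function(i)
    peptideMass(Peptide(peps$peptide[i],
                        mods = data.frame(position = peps$modPosition[i],
                                          name = modname))),
    numeric(1))
  rownames(peps) <- NULL
  peps
}

#' Group modifiers by remnant distinguishability
#'
#' Partitions a set of modifiers into groups leaving identical remnants
#' under a protease — modifiers in one group cannot be told apart by
#' remnant profiling (e.g. Ub and Nedd8 under trypsin, both ...RGG; SUMO
#' and Fat10-like modifiers under WaLP). Comparison is by remnant sequence
#' by default; \code{by = "mass"} groups isobaric remnants instead
#' (Leu/Ile remnants merge).
#'
#' @param modifiers List of \code{ModifierProtein} objects.
#' @param spec A \code{ProteaseSpec}.
#' @param by \code{"sequence"} or \code{"mass"}.
#' @param tol Mass tolerance (Da) for \code{by = "mass"}.
#' @return Named list: remnant key -> character vector of modifier names.
#' @export
remnantGroups <- function(modifiers, spec, by = c("sequence", "mass"),
                          tol = 1e-4) {
  by <- match.arg(by)
  if (!length(modifiers)) stop("empty modifier collection")
  rems <- lapply(modifiers, remnant, spec = spec)
  nms <- vapply(modifiers, modifierName, character(1))
  if (by == "sequence") {
    key <- vapply(rems, `[[`, character(1), "sequence")
  } else {
    mass <- vapply(rems, `[[`, numeric(1), "mass")
    key <- as.character(round(mass / tol) * tol)
  }
  split(nms, key)
}

#' Remnant report table
#'
#' One row per (modifier, protease): predicted remnant sequence and mass.
#'
#' @param modifiers List of \code{ModifierProtein}.
#' @param specs List of \code{ProteaseSpec}.
#' @return data.frame: \code{modifier}, \code{protease}, \code{remnant},
#'   \code{remnantMass}.
#' @export
remnantReport <- function(modifiers, specs) {
  rows <- list()
  for (sp in specs) for (m in modifiers) {
    r <- remnant(m, sp)
    rows[[length(rows) + 1L]] <- data.frame(
      modifier = modifierName(m), protease = sp@name,
      remnant = r$sequence, remnantMass = r$mass)
  }
  do.call(rbind, rows)
}
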