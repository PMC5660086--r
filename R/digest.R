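## In-silico proteolysis under configurable cleavage-specificity rules.
##
## Coordinates are 1-based inclusive; "cleavage after position i" cuts the
## chain between residues i and i+1.

#' @export
setClass("ProteaseSpec", representation(
  name          = "character",
  cleaveAfter   = "character",
  notBefore     = "character",
  blockedByMod  = "logical"
))

setValidity("ProteaseSpec", function(object) {
  msg <- character()
  aa <- names(.RESIDUE_MASS)
  if (!length(object@cleaveAfter)) msg <- c(msg, "cleave-after set is empty")
  if (length(setdiff(object@cleaveAfter, aa)))
    msg <- c(msg, "cleave-after set contains invalid residue codes")
  if (length(setdiff(object@notBefore, aa)))
    msg <- c(msg, "not-before set contains invalid residue codes")
  if (length(msg)) msg else TRUE
})

#' Protease cleavage specificity
#'
#' A named rule set: cleave C-terminal to any residue in
#' \code{cleaveAfter}, suppressed when the following residue is in
#' \code{notBefore}; when \code{blockedByMod} a modified residue in the
#' cleave-after set (e.g. a remnant-bearing lysine) does not cleave.
#'
#' Built-ins, via \code{protease()}:
#' \describe{
#'   \item{trypsin}{cleave after K/R, not before P, blocked by modification.}
#'   \item{walp}{wild-type alpha-lytic protease; cleave after A/S/T/V/L/I.
#'     WaLP prefers threonine, also cuts after Leu and to some extent Ile,
#'     and rarely after arginine, so Arg is excluded. The set is a
#'     configurable judgment call: no full preference distribution has been
#'     published.}
#' }
#'
#' @param name Spec name.
#' @param cleaveAfter Residues cleaved after (one-letter codes).
#' @param notBefore Residues that suppress cleavage when immediately
#'   C-terminal to the cleavage residue.
#' @param blockedByMod Does a modification on the cleavage residue block
#'   cleavage?
#' @return A \code{ProteaseSpec}.
#' @examples
#' protease("trypsin")
#' ProteaseSpec("walp-strict", cleaveAfter = c("T", "L"))
#' @export
ProteaseSpec <- function(name, cleaveAfter, notBefore = character(),
                         blockedByMod = TRUE) {
  new("ProteaseSpec", name = name,
      cleaveAfter = toupper(cleaveAfter),
      notBefore = toupper(notBefore),
      blockedByMod = isTRUE(blockedByMod))
}

#' @rdname ProteaseSpec
#' @export
protease <- function(name = c("trypsin", "walp")) {
  name <- match.arg(tolower(name), c("trypsin", "walp"))
  switch(name,
    trypsin = ProteaseSpec("trypsin", c("K", "R"), notBefore = "P"),
    walp    = ProteaseSpec("walp", c("A", "S", "T", "V", "L", "I"))
  )
}

setMethod("show", "ProteaseSpec", function(object) {
  cat("ProteaseSpec '", object@name, "': cleave after [",
      paste(object@cleaveAfter, collapse = ""), "]", sep = "")
  if (length(object@notBefore))
    cat(", not before [", paste(object@notBefore, collapse = ""), "]", sep = "")
  if (object@blockedByMod) cat(", blocked by modification")
  cat("\n")
})

#' @rdname ProteaseSpec
#' @param x A \code{ProteaseSpec}.
#' @export
cleaveAfter <- function(x) x@cleaveAfter

#' @export
setClass("DigestParams", representation(
  missedCleavages = "integer",
  minLength       = "integer",
  maxLength       = "integer",
  specificity     = "character"
))

setValidity("DigestParams", function(object) {
  msg <- character()
  if (object@missedCleavages < 0L) msg <- c(msg, "missedCleavages must be >= 0")
  if (object@minLength > object@maxLength) msg <- c(msg, "minLength > maxLength")
  if (!object@specificity %in% c("full", "semi"))
    msg <- c(msg, "specificity must be 'full' or 'semi'")
  if (length(msg)) msg else TRUE
})

#' Digestion parameters
#'
#' @param missedCleavages Maximum missed cleavages (>= 0).
#' @param minLength,maxLength Peptide length bounds (inclusive).
#' @param specificity \code{"full"} (both termini at cleavage sites or
#'   protein ends) or \code{"semi"} (at least one specific terminus).
#' @return A \code{DigestParams}.
#' @export
DigestParams <- function(missedCleavages = 0L, minLength = 1L,
                         maxLength = 100L, specificity = "full") {
  new("DigestParams",
      missedCleavages = as.integer(missedCleavages),
      minLength = as.integer(minLength),
      maxLength = as.integer(min(maxLength, .Machine$integer.max)),
      specificity = specificity)
}

setMethod("show", "DigestParams", function(object) {
  cat("DigestParams: mc<=", object@missedCleavages, ", length ",
      object@minLength, "-", object@maxLength, ", ", object@specificity,
      " specificity\n", sep = "")
})

#' Cleavage site positions
#'
#' Positions \code{i} such that residue \code{i} is in the spec's
#' cleave-after set, no suppression rule fires (next residue not in
#' \code{notBefore}), and \code{i} is not blocked by a modification.
#' Cleavage occurs between \code{i} and \code{i+1}; a hit at the final
#' residue is reported but cuts nothing.
#'
#' @param sequence Residue string.
#' @param spec A \code{ProteaseSpec}.
#' @param blocked Integer positions carrying a cleavage-blocking
#'   modification (ignored unless the spec has \code{blockedByMod}).
#' @return Sorted integer vector of 1-based positions.
#' @examples
#' cleavageSites("AKRGGK", protease("trypsin"))      # 2 3 6
#' cleavageSites("AKPRG", protease("trypsin"))       # 4
#' @export
cleavageSites <- function(sequence, spec, blocked = integer()) {
  res <- .check_sequence(sequence)
  n <- length(res)
  hit <- which(res %in% spec@cleaveAfter)
  if (length(spec@notBefore)) {
    supp <- hit[hit < n & res[pmin(hit + 1L, n)] %in% spec@notBefore]
    hit <- setdiff(hit, supp)
  }
  if (spec@blockedByMod && length(blocked))
    hit <- setdiff(hit, as.integer(blocked))
  sort(hit)
}

# Fully-cleaved fragment spans (mc = 0, no length filter): matrix of
# (start, end) between consecutive cut points.
.base_fragments <- function(n, sites) {
  cuts <- sites[sites < n]            # a "cleavage" after the last residue is a no-op
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  cbind(start = starts, end = ends)
}

#' In-silico digest
#'
#' Enumerates proteolytic peptides: all concatenations of at most
#' \code{missedCleavages + 1} adjacent fully-cleaved fragments, filtered by
#' length bounds. With \code{specificity = "semi"} every peptide sharing at
#' least one fully-specific terminus (all prefixes and suffixes of the
#' fully-specific peptides) is also returned.
#'
#' @inheritParams cleavageSites
#' @param params A \code{DigestParams}.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive), \code{peptide}, \code{missed} (missed-cleavage count; NA
#'   for semi-specific fragments).
#' @examples
#' digest("AKRGGK", protease("trypsin"), DigestParams())
#' @export
digest <- function(sequence, spec, params = DigestParams(),
                   blocked = integer()) {
  res <- .check_sequence(sequence)
  n <- length(res)
  sites <- cleavageSites(sequence, spec, blocked)
  frags <- .base_fragments(n, sites)
  k <- nrow(frags)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    jmax <- min(k, i + params@missedCleavages)
    js <- i:jmax
    out[[i]] <- data.frame(start = unname(frags[i, "start"]),
                           end = unname(frags[js, "end"]),
                           missed = js - i)
  }
  out <- do.call(rbind, out)
  if (params@specificity == "semi" && nrow(out)) {
    semi <- lapply(seq_len(nrow(out)), function(r) {
      s <- out$start[r]; e <- out$end[r]
      if (e <= s) return(NULL)
      rbind(
        data.frame(start = s, end = s:(e - 1L), missed = NA_integer_),
        data.frame(start = (s + 1L):e, end = e, missed = NA_integer_)
      )
    })
    out <- rbind(out, do.call(rbind, semi))
    out <- out[!duplicated(out[c("start", "end")]), ]
  }
  len <- out$end - out$start + 1L
  out <- out[len >= params@minLength & len <= params@maxLength, , drop = FALSE]
  out$peptide <- substring(sequence, out$start, out$end)
  out <- out[order(out$start, out$end), c("start", "end", "peptide", "missed")]
  rownames(out) <- NULL
  out
}

#' Fully-specific peptide covering a modified site
#'
#' The peptide a protease would produce around a modification site when the
#' site's own residue is cleavage-blocked (a remnant-bearing lysine does not
#' cleave): boundaries are the nearest unblocked cleavage sites, or the
#' protein termini. This is what makes, e.g., remnant sites recovered by an
#' orthogonal protease fall in very long (or very short) tryptic peptides.
#'
#' @inheritParams cleavageSites
#' @param site 1-based position of the modified residue (warn if not K).
#' @return One-row data.frame: \code{start}, \code{end}, \code{peptide},
#'   \code{length}.
#' @examples
#' peptideCoveringSite("MARHAADKGGSAAKR", protease("trypsin"), 8)  # 4-14
#' @export
peptideCoveringSite <- function(sequence, spec, site) {
  res <- .check_sequence(sequence)
  n <- length(res)
  site <- as.integer(site)
  if (site < 1L || site > n) stop("site out of range: ", site)
  if (res[site] != "K")
    warning("residue at site ", site, " is ", res[site], ", not K")
  sites <- cleavageSites(sequence, spec, blocked = site)
  upstream <- sites[sites < site]
  start <- if (length(upstream)) max(upstream) + 1L else 1L
  downstream <- sites[sites >= site & sites < n]
  end <- if (length(downstream)) min(downstream) else n
  data.frame(start = start, end = end,
             peptide = substring(sequence, start, end),
             length = end - start + 1L)
}

#' Read a protease spec from a key-value configuration file
#'
#' Plain-text format, one \code{key = value} pair per line, \code{#}
#' comments allowed. Keys: \code{name}, \code{cleave_after} (residues,
#' optionally comma-separated), \code{not_before}, \code{blocked_by_mod}
#' (true/false).
#'
#' @param path File path.
#' @return A \code{ProteaseSpec}.
#' @export
readProteaseSpec <- function(path) {
  kv <- .read_keyvalue(path)
  if (is.null(kv$name) || is.null(kv$cleave_after))
    stop("protease config must define 'name' and 'cleave_after'")
  split_res <- function(x)
    toupper(strsplit(gsub("[ ,]+", "", x), "")[[1]])
  ProteaseSpec(kv$name, split_res(kv$cleave_after),
               notBefore = if (is.null(kv$not_before)) character()
                           else split_res(kv$not_before),
               blockedByMod = is.null(kv$blocked_by_mod) ||
                              tolower(kv$blocked_by_mod) %in% c("true", "yes", "1"))
}
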