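## Sequence-window extraction around modified lysines and classification
## against the SUMO consensus motifs.

# Default hydrophobic (Psi) set of the SUMO forward consensus Psi-K-x-[E/D].
.PSI_DEFAULT <- c("A", "I", "L", "M", "P", "F", "V")

#' Extract a sequence window around a site
#'
#' Returns the window of \code{2*flank + 1} residues centered on the site,
#' padded with \code{"-"} where it runs past a protein terminus. Padded
#' positions never match any residue class.
#'
#' @param sequence Protein residue string.
#' @param site 1-based center position.
#' @param flank Residues on each side (default 5).
#' @return Character window of length \code{2*flank + 1}.
#' @examples
#' extractWindow("KDEAA", 1, flank = 2)   # "--KDE"
#' @export
extractWindow <- function(sequence, site, flank = 5L) {
  n <- nchar(sequence)
  site <- as.integer(site)
  if (site < 1L || site > n) stop("site out of range: ", site)
  lo <- site - flank; hi <- site + flank
  left <- strrep("-", max(0L, 1L - lo))
  right <- strrep("-", max(0L, hi - n))
  paste0(left, substring(sequence, max(1L, lo), min(n, hi)), right)
}

#' Classify a window against the SUMO consensus motifs
#'
#' Classes, checked in order of precedence:
#' \describe{
#'   \item{forward}{\eqn{\Psi}KX[E|D]: hydrophobic residue at -1 and E or D
#'     at +2 relative to the central K.}
#'   \item{inverted}{[E|D]XK: E or D at -2.}
#'   \item{none}{neither pattern.}
#' }
#' Forward takes precedence when a window satisfies both. The hydrophobic
#' set defaults to \{A, I, L, M, P, F, V\}.
#'
#' @param window Window string of odd length (center = K), flank >= 2.
#' @param psi Hydrophobic residue set.
#' @return One of \code{"forward"}, \code{"inverted"}, \code{"none"}.
#' @examples
#' classifyMotif("AVKSE")   # forward
#' classifyMotif("AEAKA")   # inverted
#' @export
classifyMotif <- function(window, psi = .PSI_DEFAULT) {
  n <- nchar(window)
  if (n %% 2L == 0L) stop("window length must be odd")
  flank <- (n - 1L) %/% 2L
  if (flank < 2L) stop("flank must be >= 2 for motif classification")
  c0 <- flank + 1L
  at <- function(off) substring(window, c0 + off, c0 + off)
  if (at(0) != "K")
    warning("window center is ", at(0), ", not K")
  if (at(-1) %in% psi && at(2) %in% c("E", "D")) return("forward")
  if (at(-2) %in% c("E", "D")) return("inverted")
  "none"
}

#' Motif class fractions and positional residue composition
#'
#' Classifies every window and tallies class fractions (exact rational
#' counts over n, so the three fractions sum to 1) plus a per-position
#' residue count matrix for logo/enrichment displays.
#'
#' @param windows Character vector of equal-length, odd-length windows.
#' @param psi Hydrophobic residue set (see \code{\link{classifyMotif}}).
#' @return List: \code{counts} (named integer: forward/inverted/none),
#'   \code{fractions} (same names, sums to 1), \code{n},
#'   \code{classes} (per-window class), \code{composition} (residues x
#'   positions count matrix; positions labelled by offset from center).
#' @export
motifSummary <- function(windows, psi = .PSI_DEFAULT) {
  if (!length(windows)) stop("no windows supplied")
  if (length(unique(nchar(windows))) != 1L)
    stop("windows must all have the same length")
  classes <- vapply(windows, classifyMotif, character(1), psi = psi,
                    USE.NAMES = FALSE)
  counts <- c(forward = sum(classes == "forward"),
              inverted = sum(classes == "inverted"),
              none = sum(classes == "none"))
  flank <- (nchar(windows[1]) - 1L) %/% 2L
  offs <- seq(-flank, flank)
  alphabet <- c(names(.RESIDUE_MASS), "-")
  comp <- matrix(0L, nrow = length(alphabet), ncol = length(offs),
                 dimnames = list(alphabet, as.character(offs)))
  mat <- do.call(rbind, strsplit(windows, ""))
  for (j in seq_along(offs)) {
    t_ <- table(factor(mat[, j], levels = alphabet))
    comp[, j] <- as.integer(t_)
  }
  list(counts = counts, fractions = counts / length(windows),
       n = length(windows), classes = classes, composition = comp)
}
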