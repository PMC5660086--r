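## Post-search PSM processing: SILAC heavy/light modification merging,
## target-decoy FDR, site localization, collapsing to unique sites, and
## comparison against known-site tables.

## ---- mod-string helpers -----------------------------------------------

# mod_string dialect: comma-separated "pos:name" or "pos:+mass" tokens,
# e.g. "8:GlyGly" or "8:+122.0571". Empty string = unmodified.
.parse_mods <- function(mod_string) {
  if (is.na(mod_string) || !nzchar(mod_string))
    return(data.frame(position = integer(), name = character(),
                      mass = numeric(), stringsAsFactors = FALSE))
  toks <- strsplit(mod_string, ",", fixed = TRUE)[[1]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  pos <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  val <- vapply(parts, function(p) p[2], character(1))
  isMass <- startsWith(val, "+") | startsWith(val, "-")
  data.frame(position = pos,
             name = ifelse(isMass, NA_character_, val),
             mass = ifelse(isMass, suppressWarnings(as.numeric(val)), NA_real_),
             stringsAsFactors = FALSE)
}

.format_mods <- function(mods) {
  if (!nrow(mods)) return("")
  tok <- ifelse(is.na(mods$name),
                sprintf("%d:%+.5f", mods$position, mods$mass),
                sprintf("%d:%s", mods$position, mods$name))
  paste(tok, collapse = ",")
}

#' Merge heavy- and light-search PSMs
#'
#' SILAC data searched twice (fixed light vs fixed heavy lysine) report the
#' heavy remnant-bearing lysine as one composite modification whose delta
#' is heavy-label + remnant. This decomposes those composites into explicit
#' label + remnant annotations so downstream site logic sees one remnant
#' vocabulary: a K modification of mass \code{labelDelta + remnantDelta}
#' (within \code{tol}) becomes \code{HeavyK} + \code{GlyGly}; a plain
#' \code{labelDelta} K modification becomes \code{HeavyK}; light records
#' pass through. Composite masses matching neither are flagged
#' (\code{flagged = TRUE}), never silently merged.
#'
#' @param psms PSM data.frame (columns \code{mod_string}, \code{label};
#'   see \code{\link{readPSMTable}}).
#' @param labelDelta Heavy-label delta mass, Da (default \code{HeavyK}).
#' @param remnantDelta Remnant delta mass, Da (default \code{GlyGly}).
#' @param tol Mass-match tolerance, Da.
#' @return The PSM data.frame with normalized \code{mod_string}, a
#'   \code{label} column in \{H, L\} and a logical \code{flagged} column.
#' @export
mergeHeavyLight <- function(psms, labelDelta = modMass("HeavyK"),
                            remnantDelta = modMass("GlyGly"), tol = 1e-3) {
  stopifnot(all(c("mod_string", "label") %in% names(psms)))
  psms$flagged <- FALSE
  heavy <- which(psms$label == "H")
  for (i in heavy) {
    mods <- .parse_mods(psms$mod_string[i])
    if (!nrow(mods)) next
    out <- list()
    for (j in seq_len(nrow(mods))) {
      if (is.na(mods$mass[j])) {            # already named
        out[[length(out) + 1L]] <- mods[j, ]
        next
      }
      m <- mods$mass[j]; pos <- mods$position[j]
      if (abs(m - (labelDelta + remnantDelta)) <= tol) {
        out[[length(out) + 1L]] <- data.frame(position = pos, name = "HeavyK",
                                              mass = NA_real_)
        out[[length(out) + 1L]] <- data.frame(position = pos, name = "GlyGly",
                                              mass = NA_real_)
      } else if (abs(m - labelDelta) <= tol) {
        out[[length(out) + 1L]] <- data.frame(position = pos, name = "HeavyK",
                                              mass = NA_real_)
      } else if (abs(m - remnantDelta) <= tol) {
        out[[length(out) + 1L]] <- data.frame(position = pos, name = "GlyGly",
                                              mass = NA_real_)
      } else {
        psms$flagged[i] <- TRUE
        out[[length(out) + 1L]] <- mods[j, ]
      }
    }
    psms$mod_string[i] <- .format_mods(do.call(rbind, out))
  }
  psms
}

## ---- target-decoy FDR -------------------------------------------------

#' Target-decoy FDR filtering
#'
#' Estimates, for every score threshold \eqn{s}, FDR(s) = #decoys with
#' score >= s / max(1, #targets with score >= s); q-values are the running
#' minimum of FDR over decreasing thresholds (most permissive first), so
#' they are monotone non-increasing in score. Thresholds are evaluated at
#' distinct score values, so records tied in score share a q-value and all
#' decoys at a tied score count against the targets there (conservative
#' tie handling); the result is invariant to input order.
#'
#' @param psms PSM data.frame with numeric \code{score} and 0/1 or logical
#'   \code{decoy} columns.
#' @param threshold FDR threshold (default 0.01, i.e. 1\%).
#' @return List: \code{psms} (retained target records, with a
#'   \code{qvalue} column; decoys never returned) and \code{qvalues}
#'   (numeric, one per input row, NA for decoys).
#' @export
fdrFilter <- function(psms, threshold = 0.01) {
  stopifnot(all(c("score", "decoy") %in% names(psms)))
  if (!all(is.finite(psms$score))) stop("non-finite PSM scores")
  decoy <- as.logical(as.integer(psms$decoy))
  if (all(decoy)) {
    warning("all input PSMs are decoys; returning empty result")
    return(list(psms = psms[decoy & FALSE, , drop = FALSE],
                qvalues = rep(NA_real_, nrow(psms))))
  }
  s <- sort(unique(psms$score), decreasing = TRUE)
  nDecoy <- vapply(s, function(th) sum(decoy & psms$score >= th), integer(1))
  nTarget <- vapply(s, function(th) sum(!decoy & psms$score >= th), integer(1))
  fdr <- nDecoy / pmax(1L, nTarget)
  q <- rev(cummin(rev(fdr)))           # min over thresholds <= s
  qAt <- function(score) q[match(score, s)]
  qvalues <- ifelse(decoy, NA_real_, qAt(psms$score))
  keep <- !decoy & qvalues <= threshold
  out <- psms[keep, , drop = FALSE]
  out$qvalue <- qvalues[keep]
  rownames(out) <- NULL
  list(psms = out, qvalues = qvalues)
}

## ---- spectra and localization -----------------------------------------

#' Centroided spectrum peak list
#'
#' @param mz Numeric m/z values, strictly ascending.
#' @param intensity Non-negative intensities, same length.
#' @param precursorMz,precursorCharge Optional precursor annotation.
#' @param title Optional spectrum title/identifier.
#' @return A list of class \code{"SpectrumPeaks"}.
#' @export
spectrumPeaks <- function(mz, intensity, precursorMz = NA_real_,
                          precursorCharge = NA_integer_, title = "") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && any(diff(mz) <= 0)) stop("m/z values must be strictly ascending")
  if (any(intensity < 0)) stop("negative intensities")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursorMz = precursorMz,
                 precursorCharge = as.integer(precursorCharge),
                 title = title),
            class = "SpectrumPeaks")
}

# Top-n-per-100-m/z peak filter (Ascore-style "peak depth").
.filter_peaks <- function(spec, depth) {
  if (!length(spec$mz)) return(spec)
  win <- floor(spec$mz / 100)
  keep <- unlist(lapply(split(seq_along(spec$mz), win), function(idx) {
    idx[order(spec$intensity[idx], decreasing = TRUE)][seq_len(min(depth, length(idx)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  spectrumPeaks(spec$mz[keep], spec$intensity[keep],
                spec$precursorMz, spec$precursorCharge, spec$title)
}

.count_matches <- function(theo, obs, tol) {
  if (!length(theo) || !length(obs)) return(0L)
  sum(vapply(theo, function(m) any(abs(obs - m) <= tol), logical(1)))
}

#' Binomial remnant-site localization
#'
#' An Ascore-like scheme assigning a remnant to one lysine among the
#' candidates in a peptide. For every candidate placement the theoretical
#' fragment ions are computed; site-determining ions (those whose m/z is
#' not shared by every placement) are matched against the top
#' \code{peakDepth} peaks per 100 m/z of the spectrum within
#' \code{tolerance}. The chance probability of observing at least the
#' matched count is the binomial tail \eqn{P(X \ge k)} with per-ion match
#' probability \eqn{p = (peakDepth/100) \cdot 2 \cdot tolerance};
#' placements are scored by how unlikely their match count is by chance,
#' and site probabilities are the normalized inverse tail probabilities,
#' summing to 1. With no site-determining evidence all placements are
#' equally likely.
#'
#' @param spectrum A \code{\link{spectrumPeaks}} object.
#' @param peptide A \code{Peptide} (its remnant mods, if any, define the
#'   remnant count) or residue string.
#' @param modName Remnant modification name (default \code{"GlyGly"}).
#' @param nMods Number of remnants to place (default: count of
#'   \code{modName} on the peptide, minimum 1).
#' @param tolerance Fragment match tolerance, Da (default 0.5, ion trap).
#' @param peakDepth Peaks retained per 100 m/z (default 10).
#' @param series Ion series used (default b and y; add c/z for ETD).
#' @param maxCharge Highest fragment charge considered.
#' @return List: \code{placements} (data.frame of candidate position sets
#'   and their probabilities, summing to 1), \code{positionProbability}
#'   (named vector: marginal probability each candidate K carries a
#'   remnant), \code{nCandidates}.
#' @export
localizeSite <- function(spectrum, peptide, modName = "GlyGly",
                         nMods = NULL, tolerance = 0.5, peakDepth = 10L,
                         series = c("b", "y"), maxCharge = 1L) {
  if (is.character(peptide)) peptide <- Peptide(peptide)
  if (!length(spectrum$mz)) stop("empty spectrum")
  res <- strsplit(peptide@sequence, "")[[1]]
  targets <- getModification(modName)$targets
  cand <- which(res %in% targets)
  if (!length(cand)) stop("peptide contains no candidate residue for ", modName)
  if (is.null(nMods)) nMods <- max(1L, sum(peptide@mods$name == modName))
  if (nMods > length(cand)) stop("more remnants than candidate residues")
  fixed <- peptide@mods[peptide@mods$name != modName, , drop = FALSE]
  placements <- if (length(cand) == 1L) list(cand)
                else utils::combn(cand, nMods, simplify = FALSE)
  theo <- lapply(placements, function(pp) {
    p <- Peptide(peptide@sequence,
                 mods = rbind(fixed, data.frame(position = pp, name = modName)))
    fragmentIons(p, series = series, maxCharge = maxCharge)$mz
  })
  if (length(placements) == 1L) {
    pos <- stats::setNames(1, as.character(placements[[1]]))
    return(list(placements = data.frame(placement = paste(placements[[1]],
                                                          collapse = "+"),
                                        probability = 1),
                positionProbability = pos, nCandidates = length(cand)))
  }
  # site-determining = not present in every placement's ion list
  eps <- 1e-6
  inAll <- function(m) all(vapply(theo, function(t) any(abs(t - m) <= eps),
                                  logical(1)))
  sd_ions <- lapply(theo, function(t) t[!vapply(t, inAll, logical(1))])
  filtered <- .filter_peaks(spectrum, peakDepth)
  p <- min(1, max(1e-12, (peakDepth / 100) * 2 * tolerance))
  tailp <- vapply(seq_along(placements), function(i) {
    n <- length(sd_ions[[i]])
    if (n == 0L) return(1)
    k <- .count_matches(sd_ions[[i]], filtered$mz, tolerance)
    stats::pbinom(k - 1L, n, p, lower.tail = FALSE)   # P(X >= k)
  }, numeric(1))
  w <- 1 / tailp
  prob <- w / sum(w)
  marg <- stats::setNames(numeric(length(cand)), as.character(cand))
  for (i in seq_along(placements))
    marg[as.character(placements[[i]])] <-
      marg[as.character(placements[[i]])] + prob[i]
  list(placements = data.frame(
         placement = vapply(placements, paste, character(1), collapse = "+"),
         probability = prob),
       positionProbability = marg, nCandidates = length(cand))
}

## ---- collapsing to sites ----------------------------------------------

#' Collapse localized PSMs to unique modification sites
#'
#' One record per (accession, absolute residue position): PSM rows whose
#' localization probability passes \code{threshold} are grouped on
#' accession and protein position (\code{start + modPosition - 1});
#' supporting-PSM counts, best probability and best score are aggregated.
#' Rows without a span mapping (\code{start} missing) are skipped with a
#' warning. Peptides mapping to several accessions yield one site per
#' accession, flagged ambiguous (shared spectrum identifier).
#'
#' @param psms data.frame with columns \code{accession}, \code{start}
#'   (peptide start in protein, 1-based), \code{modPosition} (remnant
#'   position within peptide), \code{probability}, and optionally
#'   \code{score}, \code{spectrum_id}, \code{modification}.
#' @param threshold Localization probability cut (default 0.9).
#' @return data.frame: \code{accession}, \code{position},
#'   \code{modification}, \code{probability} (best), \code{psmCount},
#'   \code{bestScore}, \code{ambiguous}.
#' @export
collapseToSites <- function(psms, threshold = 0.9) {
  req <- c("accession", "start", "modPosition", "probability")
  miss <- setdiff(req, names(psms))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(psms$start)
  if (any(bad)) {
    warning(sum(bad), " PSM(s) without span mapping skipped")
    psms <- psms[!bad, , drop = FALSE]
  }
  psms <- psms[psms$probability >= threshold, , drop = FALSE]
  if (!nrow(psms))
    return(data.frame(accession = character(), position = integer(),
                      modification = character(), probability = numeric(),
                      psmCount = integer(), bestScore = numeric(),
                      ambiguous = logical()))
  psms$position <- psms$start + psms$modPosition - 1L
  if (is.null(psms$modification)) psms$modification <- "GlyGly"
  if (is.null(psms$score)) psms$score <- NA_real_
  ambig_ids <- character()
  if (!is.null(psms$spectrum_id)) {
    tab <- tapply(psms$accession, psms$spectrum_id,
                  function(a) length(unique(a)))
    ambig_ids <- names(tab)[tab > 1]
  }
  key <- interaction(psms$accession, psms$position, psms$modification,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(psms)), key), function(idx) {
    g <- psms[idx, , drop = FALSE]
    data.frame(accession = g$accession[1], position = g$position[1],
               modification = g$modification[1],
               probability = max(g$probability),
               psmCount = nrow(g),
               bestScore = if (all(is.na(g$score))) NA_real_
                           else max(g$score, na.rm = TRUE),
               ambiguous = !is.null(g$spectrum_id) &&
                           any(g$spectrum_id %in% ambig_ids))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$position), ]
  rownames(out) <- NULL
  out
}

#' Compare identified sites against known-site tables
#'
#' Set algebra on site identity (accession, position): per-source
#' intersection counts, the union of known sites, and the novel count.
#'
#' @param sites data.frame with \code{accession}, \code{position}.
#' @param known Either a data.frame with \code{accession}, \code{position},
#'   \code{source}, or a named list of such data.frames (one per source).
#' @return List: \code{perSource} (data.frame source/knownSites/overlap),
#'   \code{nSites}, \code{knownUnion}, \code{novel} (count),
#'   \code{novelSites} (data.frame), \code{skipped} (malformed known rows).
#' @export
compareKnown <- function(sites, known) {
  keyOf <- function(df) paste(df$accession, df$position, sep = "@")
  if (is.data.frame(known)) {
    stopifnot("source" %in% names(known))
    known <- split(known[c("accession", "position")], known$source)
  }
  skipped <- 0L
  known <- lapply(known, function(df) {
    ok <- !is.na(df$accession) & nzchar(as.character(df$accession)) &
          !is.na(suppressWarnings(as.integer(df$position)))
    skipped <<- skipped + sum(!ok)
    df[ok, , drop = FALSE]
  })
  mykeys <- unique(keyOf(sites))
  per <- do.call(rbind, lapply(names(known), function(src) {
    kk <- unique(keyOf(known[[src]]))
    data.frame(source = src, knownSites = length(kk),
               overlap = length(intersect(mykeys, kk)))
  }))
  allKnown <- unique(unlist(lapply(known, keyOf), use.names = FALSE))
  novelKeys <- setdiff(mykeys, allKnown)
  parts <- strsplit(novelKeys, "@", fixed = TRUE)
  novelSites <- data.frame(
    accession = vapply(parts, `[`, character(1), 1),
    position = as.integer(vapply(parts, `[`, character(1), 2)))
  list(perSource = per, nSites = length(mykeys),
       knownUnion = length(allKnown), novel = length(novelKeys),
       novelSites = novelSites, skipped = skipped)
}
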