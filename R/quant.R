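## SILAC heavy/light ratio computation, median normalization, site-level
## weighted aggregation, change flagging, condition comparison, and dual
## SUMO/Ub per-lysine tables.

#' Weighted site-level SILAC log2 ratio
#'
#' Combines the peptide-level heavy/light measurements supporting one site
#' into a weighted average ratio. Averaging happens in log2 space by
#' default (symmetric for up- and down-regulation); weights are the summed
#' heavy+light intensity of each measurement, renormalized to 1, as a
#' proxy for measurement precision. Measurements with zero light intensity
#' have no defined ratio and are excluded (a site supported only by such
#' measurements is "heavy-only" and has no ratio).
#'
#' @param heavy,light Non-negative intensity vectors (one entry per
#'   supporting peptide measurement).
#' @param mode \code{"log2"} (average the log2 ratios) or \code{"linear"}
#'   (average the linear ratios, then take log2).
#' @return List: \code{log2Ratio}, \code{nPeptides} (measurements used),
#'   \code{heavyOnly} (all light intensities zero).
#' @examples
#' siteRatio(c(2, 4) * 1e6, c(1, 1) * 1e6)
#' @export
siteRatio <- function(heavy, light, mode = c("log2", "linear")) {
  mode <- match.arg(mode)
  stopifnot(length(heavy) == length(light))
  if (any(heavy < 0) || any(light < 0)) stop("negative intensities")
  ok <- light > 0 & heavy > 0
  if (!any(ok))
    return(list(log2Ratio = NA_real_, nPeptides = 0L, heavyOnly = all(light == 0)))
  h <- heavy[ok]; l <- light[ok]
  w <- h + l
  w <- w / sum(w)
  r <- if (mode == "log2") sum(w * log2(h / l)) else log2(sum(w * (h / l)))
  list(log2Ratio = r, nPeptides = sum(ok), heavyOnly = FALSE)
}

#' Median-center log2 ratios
#'
#' Subtracts the experiment-wide median so the output median is 0,
#' removing global mixing-ratio offsets between the heavy and light
#' channels.
#'
#' @param x Numeric log2 ratios (NA entries preserved).
#' @return Centered vector (median 0 over non-NA entries).
#' @export
normalizeRatios <- function(x) {
  if (!length(x) || all(is.na(x))) stop("no ratios to normalize")
  x - stats::median(x, na.rm = TRUE)
}

#' Flag changing and twofold-changing sites
#'
#' A site is \emph{changing} when its log2 ratio lies outside
#' \code{sdMult} standard deviations from the median of all site ratios;
#' independently, \emph{twofold} flags mark ratios at or beyond
#' \code{+/-foldCut} log2 units (1 log2 unit = twofold).
#'
#' @param x Numeric site-level log2 ratios (normalized or not; median and
#'   s.d. are taken over \code{x} itself).
#' @param sdMult Multiplier on the standard deviation (default 1).
#' @param foldCut Log2 cut for the fold flags (default 1 = twofold).
#' @return data.frame: \code{log2Ratio}, \code{changing} (\code{"up"},
#'   \code{"down"}, \code{"unchanged"}; NA when fewer than 2 ratios),
#'   \code{twofold} (\code{"up"}, \code{"down"}, \code{"neither"}).
#' @export
flagChanging <- function(x, sdMult = 1.0, foldCut = 1.0) {
  ok <- !is.na(x)
  med <- stats::median(x[ok])
  s <- if (sum(ok) >= 2L) stats::sd(x[ok]) else NA_real_
  changing <- rep(NA_character_, length(x))
  if (!is.na(s)) {
    changing[ok] <- ifelse(abs(x[ok] - med) > sdMult * s,
                           ifelse(x[ok] > med, "up", "down"), "unchanged")
  }
  twofold <- rep(NA_character_, length(x))
  twofold[ok] <- ifelse(x[ok] >= foldCut, "up",
                        ifelse(x[ok] <= -foldCut, "down", "neither"))
  data.frame(log2Ratio = x, changing = changing, twofold = twofold)
}

#' Two-condition comparison of site ratios
#'
#' Two-tailed two-sample t-test (Welch unequal-variance form) between two
#' groups of site-level log2 ratios, e.g. protease-treated vs untreated.
#'
#' @param a,b Numeric vectors (at least 2 values each).
#' @return List: \code{statistic}, \code{p.value}, \code{df},
#'   \code{computed} (FALSE with NA fields when either group has n < 2 or
#'   zero variance in both groups).
#' @export
compareConditions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(statistic = NA_real_, p.value = NA_real_, df = NA_real_,
                computed = FALSE))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constants compare equal, otherwise untestable
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1.0 else NA_real_
    return(list(statistic = 0, p.value = p, df = NA_real_,
                computed = !is.na(p)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), computed = TRUE)
}

#' Site-level quantitation table from peptide measurements
#'
#' Pipeline convenience: groups a measurement table by site, computes the
#' weighted log2 ratio per site (\code{\link{siteRatio}}), median-centers
#' the site ratios (\code{\link{normalizeRatios}}) and attaches
#' changing/twofold flags (\code{\link{flagChanging}}).
#'
#' @param measurements data.frame with columns \code{accession},
#'   \code{position}, \code{heavy_intensity}, \code{light_intensity} (one
#'   row per supporting peptide measurement).
#' @param mode Averaging mode, see \code{\link{siteRatio}}.
#' @param normalize Median-center before flagging?
#' @param sdMult,foldCut Flag thresholds, see \code{\link{flagChanging}}.
#' @return data.frame: \code{accession}, \code{position},
#'   \code{log2Ratio} (normalized when \code{normalize}),
#'   \code{rawLog2Ratio}, \code{nPeptides}, \code{changing},
#'   \code{twofold}. Heavy-only / ratio-less sites are dropped with a
#'   warning.
#' @export
siteQuantTable <- function(measurements, mode = "log2", normalize = TRUE,
                           sdMult = 1.0, foldCut = 1.0) {
  req <- c("accession", "position", "heavy_intensity", "light_intensity")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(measurements$accession, measurements$position, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(measurements)), key), function(idx) {
    g <- measurements[idx, , drop = FALSE]
    r <- siteRatio(g$heavy_intensity, g$light_intensity, mode = mode)
    data.frame(accession = g$accession[1], position = g$position[1],
               rawLog2Ratio = r$log2Ratio, nPeptides = r$nPeptides)
  })
  out <- do.call(rbind, rows)
  drop <- is.na(out$rawLog2Ratio)
  if (any(drop)) {
    warning(sum(drop), " site(s) without a defined ratio dropped")
    out <- out[!drop, , drop = FALSE]
  }
  if (!nrow(out)) stop("no quantifiable sites")
  out$log2Ratio <- if (normalize) normalizeRatios(out$rawLog2Ratio)
                   else out$rawLog2Ratio
  fl <- flagChanging(out$log2Ratio, sdMult = sdMult, foldCut = foldCut)
  out$changing <- fl$changing
  out$twofold <- fl$twofold
  out <- out[order(out$accession, out$position),
             c("accession", "position", "log2Ratio", "rawLog2Ratio",
               "nPeptides", "changing", "twofold")]
  rownames(out) <- NULL
  out
}

#' Dual SUMO/ubiquitin modification table
#'
#' Joins SUMO-site and Ub-site quantitation tables on lysine identity
#' (accession, position) and summarizes how the two modification systems
#' share proteins and individual lysines.
#'
#' @param sumoSites,ubSites data.frames with \code{accession},
#'   \code{position} and optionally \code{log2Ratio}.
#' @return List: \code{table} (per-lysine records: accession, position,
#'   sumoLog2Ratio, ubLog2Ratio, both) and \code{counts} (proteins
#'   SUMO-only / Ub-only / both; lysines both-modified).
#' @export
dualModificationTable <- function(sumoSites, ubSites) {
  keyOf <- function(df) paste(df$accession, df$position, sep = "@")
  getRatio <- function(df) {
    if ("log2Ratio" %in% names(df)) df$log2Ratio else rep(NA_real_, nrow(df))
  }
  s <- data.frame(key = keyOf(sumoSites), accession = sumoSites$accession,
                  position = sumoSites$position,
                  sumoLog2Ratio = getRatio(sumoSites))
  u <- data.frame(key = keyOf(ubSites), accession = ubSites$accession,
                  position = ubSites$position,
                  ubLog2Ratio = getRatio(ubSites))
  s <- s[!duplicated(s$key), ]; u <- u[!duplicated(u$key), ]
  tab <- merge(s, u[c("key", "ubLog2Ratio")], by = "key", all = TRUE)
  only_u <- is.na(tab$accession)
  if (any(only_u)) {
    parts <- strsplit(tab$key[only_u], "@", fixed = TRUE)
    tab$accession[only_u] <- vapply(parts, `[`, character(1), 1)
    tab$position[only_u] <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  tab$both <- tab$key %in% intersect(s$key, u$key)
  tab <- tab[order(tab$accession, tab$position),
             c("accession", "position", "sumoLog2Ratio", "ubLog2Ratio", "both")]
  rownames(tab) <- NULL
  sp <- unique(sumoSites$accession); up <- unique(ubSites$accession)
  counts <- list(
    proteinsSumoOnly = length(setdiff(sp, up)),
    proteinsUbOnly = length(setdiff(up, sp)),
    proteinsBoth = length(intersect(sp, up)),
    lysinesBoth = sum(tab$both),
    lysinesTotal = nrow(tab))
  list(table = tab, counts = counts)
}
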