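# PSM post-processing: heavy/light merging, target-decoy FDR, binomial
# localization, collapsing to sites, known-site comparison.

make_psms <- function(score, decoy) {
  data.frame(spectrum_id = sprintf("s%03d", seq_along(score)),
             accession = "P1", peptide = "AKAAR", mod_string = "2:GlyGly",
             score = score, decoy = decoy, label = "L", charge = 2L)
}

test_that("heavy composite K modifications decompose into label + remnant", {
  comp <- modMass("HeavyK") + modMass("GlyGly")
  psms <- data.frame(
    spectrum_id = c("a", "b", "c", "d"),
    mod_string = c(sprintf("3:%+.5f", comp),          # composite
                   "2:GlyGly",                        # light, named
                   sprintf("1:%+.5f", modMass("HeavyK")),  # label only
                   "4:+99.99999"),                    # matches nothing
    label = c("H", "L", "H", "H"))
  out <- mergeHeavyLight(psms)
  expect_identical(out$mod_string[1], "3:HeavyK,3:GlyGly")
  expect_identical(out$mod_string[2], "2:GlyGly")     # light untouched
  expect_identical(out$mod_string[3], "1:HeavyK")
  expect_true(out$flagged[4])                         # flagged, not merged
  expect_false(any(out$flagged[1:3]))
})

test_that("FDR at a cut equals decoys over targets above it", {
  # 100 targets with 1 decoy above the best threshold -> FDR 1.0%
  psms <- make_psms(score = c(6, rep(5, 100), rep(1, 50)),
                    decoy = c(1, rep(0, 100), rep(1, 50)))
  res <- fdrFilter(psms, threshold = 0.01)
  expect_equal(res$qvalues[2], 0.01)
  expect_identical(nrow(res$psms), 100L)
  expect_true(all(res$psms$decoy == 0))
})

test_that("zero decoys give q = 0 everywhere; all-decoys give empty result", {
  psms <- make_psms(score = rnorm(20), decoy = 0)
  res <- fdrFilter(psms)
  expect_identical(nrow(res$psms), 20L)
  expect_true(all(res$qvalues == 0))
  psms2 <- make_psms(score = rnorm(5), decoy = 1)
  expect_warning(res2 <- fdrFilter(psms2), "all input PSMs are decoys")
  expect_identical(nrow(res2$psms), 0L)
})

test_that("q-values match the brute-force all-thresholds scan", {
  set.seed(41)
  for (rep_i in 1:8) {
    n <- 60
    decoy <- rbinom(n, 1, 0.3)
    score <- ifelse(decoy == 1, rnorm(n, 0), rnorm(n, 2))
    # inject ties
    score[sample(n, 10)] <- sample(score, 10, replace = TRUE)
    psms <- make_psms(score, decoy)
    res <- fdrFilter(psms)
    expect_equal(res$qvalues, bf_qvalues(score, decoy), tolerance = 1e-12)
  }
})

test_that("q-values are order-invariant and monotone in score", {
  set.seed(42)
  decoy <- rbinom(80, 1, 0.25)
  score <- ifelse(decoy == 1, rnorm(80, 0), rnorm(80, 2.5))
  psms <- make_psms(score, decoy)
  res <- fdrFilter(psms)
  perm <- sample(nrow(psms))
  res_p <- fdrFilter(psms[perm, ])
  expect_equal(res_p$qvalues, res$qvalues[perm])
  # monotone non-increasing in score over targets
  t_idx <- which(decoy == 0)
  o <- t_idx[order(score[t_idx])]
  expect_true(all(diff(res$qvalues[o]) <= 1e-12))
  # retained set shrinks as the threshold tightens
  n_loose <- nrow(fdrFilter(psms, threshold = 0.05)$psms)
  n_tight <- nrow(fdrFilter(psms, threshold = 0.01)$psms)
  expect_lte(n_tight, n_loose)
})

test_that("single-candidate peptides localize with certainty", {
  spec <- spectrumPeaks(c(100, 200), c(10, 10))
  loc <- localizeSite(spec, "AKGGA")
  expect_equal(unname(loc$positionProbability["2"]), 1.0)
  expect_error(localizeSite(spec, "AGGGA"), "no candidate residue")
  expect_error(localizeSite(spectrumPeaks(numeric(), numeric()), "AKGGA"),
               "empty spectrum")
})

test_that("site-determining evidence for one placement wins it > 0.9", {
  pepseq <- "AKGGKA"
  pA <- Peptide(pepseq, mods = data.frame(position = 2, name = "GlyGly"))
  pB <- Peptide(pepseq, mods = data.frame(position = 5, name = "GlyGly"))
  mzA <- fragmentIons(pA)$mz
  mzB <- fragmentIons(pB)$mz
  sdA <- mzA[!vapply(mzA, function(m) any(abs(mzB - m) <= 1e-6), logical(1))]
  spec <- spectrumPeaks(sort(sdA), rep(100, length(sdA)))
  loc <- localizeSite(spec, pepseq)
  expect_gt(loc$positionProbability[["2"]], 0.9)
  expect_equal(sum(loc$placements$probability), 1, tolerance = 1e-9)
  # brute-force binomial oracle over both placements
  n <- length(sdA)
  want <- bf_localize2(k1 = n, n1 = n, k2 = 0, n2 = n, p = 0.1)
  expect_equal(unname(loc$positionProbability[c("2", "5")]), want,
               tolerance = 1e-9)
})

test_that("no site-determining matches give the symmetric 0.5/0.5 answer", {
  spec <- spectrumPeaks(c(1500.1, 1600.2), c(5, 5))   # matches nothing
  loc <- localizeSite(spec, "AKGGKA")
  expect_equal(unname(loc$positionProbability[c("2", "5")]), c(0.5, 0.5))
})

test_that("localization probabilities sum to 1 over placements", {
  set.seed(43)
  for (rep_i in 1:10) {
    s <- paste0("A", random_seq(6, alphabet = c("K", "G", "A", "S")), "K")
    if (sum(strsplit(s, "")[[1]] == "K") < 1) next
    mz <- sort(runif(25, 100, 900))
    spec <- spectrumPeaks(mz, runif(25, 1, 100))
    loc <- localizeSite(spec, s)
    expect_equal(sum(loc$placements$probability), 1, tolerance = 1e-9)
    expect_equal(sum(loc$positionProbability), 1, tolerance = 1e-9)
  }
})

test_that("two remnants on a poly-modified peptide localize jointly", {
  pepseq <- "AKGKGKA"
  p2 <- Peptide(pepseq, mods = data.frame(position = c(2, 4),
                                          name = "GlyGly"))
  ions <- fragmentIons(p2)$mz
  spec <- spectrumPeaks(sort(unique(round(ions, 5))),
                        rep(100, length(unique(round(ions, 5)))))
  loc <- localizeSite(spec, pepseq, nMods = 2)
  expect_identical(nrow(loc$placements), 3L)          # C(3,2)
  expect_equal(sum(loc$placements$probability), 1, tolerance = 1e-9)
  best <- loc$placements$placement[which.max(loc$placements$probability)]
  expect_identical(best, "2+4")
})

test_that("PSMs collapse to unique localized sites", {
  psms <- data.frame(
    spectrum_id = c("s1", "s2", "s3", "s4"),
    accession = c("P1", "P1", "P1", "P2"),
    start = c(10L, 8L, 10L, NA),
    modPosition = c(3L, 5L, 3L, 1L),
    probability = c(0.99, 0.95, 0.8, 0.99),
    score = c(5, 4, 3, 2))
  expect_warning(sites <- collapseToSites(psms, threshold = 0.9),
                 "without span mapping")
  # s1 and s2 hit P1 position 12; s3 is sub-threshold; s4 has no span
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$position, 12L)
  expect_identical(sites$psmCount, 2L)
  expect_equal(sites$probability, 0.99)
})

test_that("multi-mapping spectra yield one flagged site per accession", {
  psms <- data.frame(
    spectrum_id = c("s1", "s1"),
    accession = c("P1", "P2"),
    start = c(5L, 50L), modPosition = c(2L, 2L),
    probability = c(0.95, 0.95), score = c(1, 1))
  sites <- collapseToSites(psms)
  expect_identical(nrow(sites), 2L)
  expect_true(all(sites$ambiguous))
})

test_that("known-site comparison equals brute-force set algebra", {
  sites <- data.frame(accession = c("P1", "P2"), position = c(10L, 5L))
  known <- data.frame(accession = "P1", position = 10L, source = "db1")
  cmp <- compareKnown(sites, known)
  expect_identical(cmp$perSource$overlap, 1L)
  expect_identical(cmp$novel, 1L)
  cmp0 <- compareKnown(sites, data.frame(accession = character(),
                                         position = integer(),
                                         source = character()))
  expect_identical(cmp0$novel, 2L)
  set.seed(44)
  for (rep_i in 1:5) {
    mine <- data.frame(accession = sample(paste0("P", 1:6), 30, TRUE),
                       position = sample(1:10, 30, TRUE))
    kn <- data.frame(accession = sample(paste0("P", 1:6), 40, TRUE),
                     position = sample(1:10, 40, TRUE),
                     source = sample(c("a", "b"), 40, TRUE))
    cmp <- compareKnown(mine, kn)
    mk <- unique(paste(mine$accession, mine$position))
    kk <- unique(paste(kn$accession, kn$position))
    expect_identical(cmp$novel, length(setdiff(mk, kk)))
    for (src in cmp$perSource$source) {
      kks <- unique(paste(kn$accession[kn$source == src],
                          kn$position[kn$source == src]))
      expect_identical(cmp$perSource$overlap[cmp$perSource$source == src],
                       length(intersect(mk, kks)))
    }
  }
})
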