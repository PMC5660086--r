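# Synthetic-data generator: determinism, planted ground truth, and
# consistency with the digestion and quantitation modules.

test_that("simulated proteomes are reproducible and well-formed", {
  cfg <- simConfig(seed = 7, nProteins = 5, lengthRange = c(50, 50))
  prot <- simulateProteome(cfg)
  expect_identical(nrow(prot), 5L)
  expect_true(all(nchar(prot$sequence) == 50))
  expect_true(all(grepl("K", prot$sequence)))
  prot2 <- simulateProteome(cfg)
  expect_identical(prot, prot2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(simulateProteome(cfg), f1)
  writeFasta(simulateProteome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))    # byte-identical
  prot3 <- simulateProteome(simConfig(seed = 8, nProteins = 5,
                                      lengthRange = c(50, 50)))
  expect_false(identical(prot$sequence, prot3$sequence))
  expect_error(simulateProteome(simConfig(nProteins = 0)), "nProteins")
})

test_that("planted site classes follow largest-remainder rounding", {
  cfg <- simConfig(seed = 3, nProteins = 60, nSites = 100)
  planted <- plantSites(simulateProteome(cfg), cfg)
  tab <- table(planted$sites$class)
  expect_identical(as.integer(tab[c("forward", "inverted", "none")]),
                   c(31L, 9L, 60L))
  cfg2 <- simConfig(seed = 3, nProteins = 60, nSites = 50,
                    motifFractions = c(1, 0, 0))
  planted2 <- plantSites(simulateProteome(cfg2), cfg2)
  expect_true(all(planted2$sites$class == "forward"))
})

test_that("planted sites re-classify to their assigned class exactly", {
  cfg <- simConfig(seed = 5, nProteins = 50, nSites = 80)
  planted <- plantSites(simulateProteome(cfg), cfg)
  seqOf <- setNames(planted$proteome$sequence, planted$proteome$id)
  got <- vapply(seq_len(nrow(planted$sites)), function(i) {
    w <- extractWindow(seqOf[[planted$sites$accession[i]]],
                       planted$sites$position[i], flank = 5)
    classifyMotif(w)
  }, character(1))
  expect_identical(got, planted$sites$class)        # 100% round-trip
})

test_that("insufficient lysines raise an error", {
  cfg <- simConfig(seed = 1, nProteins = 2, lengthRange = c(30, 30),
                   nSites = 500)
  expect_error(plantSites(simulateProteome(cfg), cfg), "insufficient")
})

test_that("simulated PSMs are digest-consistent and carry ground truth", {
  cfg <- simConfig(seed = 9, nProteins = 30, nSites = 40,
                   peptidesPerSite = 2, decoyFraction = 0.1)
  planted <- plantSites(simulateProteome(cfg), cfg)
  sim <- simulatePSMs(planted$proteome, planted$sites, cfg)
  psms <- sim$psms
  targets <- psms[psms$decoy == 0, ]
  expect_identical(nrow(targets), 80L)              # nSites * peptidesPerSite
  # decoy fraction of the combined table (up to rounding)
  expect_equal(mean(psms$decoy), 0.1, tolerance = 0.05)
  expect_true(all(startsWith(psms$accession[psms$decoy == 1], "decoy_")))
  # every true PSM peptide matches its protein span and the digest rules
  seqOf <- setNames(planted$proteome$sequence, planted$proteome$id)
  spec <- protease(cfg$protease)
  params <- DigestParams(missedCleavages = cfg$missedCleavages,
                         minLength = 1, maxLength = 10000)
  truthPos <- setNames(sim$psmTruth$position, sim$psmTruth$spectrum_id)
  for (i in seq_len(nrow(targets))) {
    s <- seqOf[[targets$accession[i]]]
    sp_ <- targets$start[i]
    pep <- targets$peptide[i]
    expect_identical(substring(s, sp_, sp_ + nchar(pep) - 1L), pep)
    site <- unname(truthPos[targets$spectrum_id[i]])
    d <- digest(s, spec, params, blocked = site)
    expect_true(any(d$start == sp_ & d$peptide == pep))
  }
  # determinism of the full simulation
  sim2 <- simulatePSMs(planted$proteome, planted$sites, cfg)
  expect_identical(sim$psms, sim2$psms)
  expect_identical(sim$measurements, sim2$measurements)
})

test_that("noise-free intensities recover the planted ratio exactly", {
  cfg <- simConfig(seed = 13, nProteins = 30, nSites = 20,
                   log2Ratios = 1.0, intensitySigma = 0,
                   falseTargetFraction = 0)
  planted <- plantSites(simulateProteome(cfg), cfg)
  sim <- simulatePSMs(planted$proteome, planted$sites, cfg)
  q <- siteQuantTable(sim$measurements, normalize = FALSE)
  expect_equal(q$rawLog2Ratio, rep(1.0, nrow(q)), tolerance = 1e-9)
})

test_that("simulated spectra localize to the planted lysine", {
  cfg <- simConfig(seed = 17, nProteins = 20, nSites = 10,
                   peptidesPerSite = 1, makeSpectra = TRUE,
                   ionObservedFraction = 1.0, decoyFraction = 0)
  planted <- plantSites(simulateProteome(cfg), cfg)
  sim <- simulatePSMs(planted$proteome, planted$sites, cfg)
  expect_identical(length(sim$spectra), nrow(sim$psms))
  multiK <- which(vapply(sim$psms$peptide, function(p)
    sum(strsplit(p, "")[[1]] == "K") > 1, logical(1)))
  for (i in multiK) {
    loc <- localizeSite(sim$spectra[[sim$psms$spectrum_id[i]]],
                        sim$psms$peptide[i])
    best <- names(which.max(loc$positionProbability))
    expect_identical(best, as.character(sim$psms$modPosition[i]))
  }
})

test_that("sim configs round-trip through key-value files", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("seed = 4", "nProteins = 12", "nSites = 9",
               "motifFractions = 0.5,0.2,0.3", "protease = walp"), path)
  cfg <- readSimConfig(path)
  expect_identical(cfg$seed, 4L)
  expect_identical(cfg$nProteins, 12L)
  expect_equal(unname(cfg$motifFractions), c(0.5, 0.2, 0.3))
  expect_identical(cfg$protease, "walp")
  writeLines("bogus_key = 1", path)
  expect_error(readSimConfig(path), "unknown config key")
})
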