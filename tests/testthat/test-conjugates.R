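# Remnant prediction from modifier C-termini and distinguishability laws.

TOL <- 1e-4

test_that("remnant is the suffix past the C-terminal-most cleavage site", {
  expect_warning(m <- ModifierProtein("noGG", "MQKART"), "diglycine")
  toy <- toy_sumo()                                   # MQKARTGG
  r_tryp <- remnant(toy, protease("trypsin"))
  expect_identical(r_tryp$sequence, "TGG")
  expect_equal(r_tryp$mass, 215.09061, tolerance = TOL)
  r_walp <- remnant(toy, protease("walp"))
  expect_identical(r_walp$sequence, "GG")
  expect_equal(r_walp$mass, 114.04293, tolerance = TOL)
  r_ub <- remnant(toy_ub(), protease("trypsin"))      # MRGG
  expect_identical(r_ub$sequence, "GG")
  expect_equal(r_ub$mass, 114.04293, tolerance = TOL)
  # no cleavage site at all: the whole modifier stays attached
  r_none <- remnant(ModifierProtein("stub", "GGGG", requireGG = FALSE),
                    protease("trypsin"))
  expect_identical(r_none$sequence, "GGGG")
})

test_that("remnant is always a suffix and GG under the diglycine law", {
  set.seed(31)
  for (rep_i in 1:20) {
    body <- random_seq(sample(5:20, 1))
    m <- ModifierProtein("rand", paste0(body, "GG"), requireGG = FALSE)
    sp <- ProteaseSpec("rand", sample(setdiff(AA20, "G"), sample(1:5, 1)))
    r <- remnant(m, sp)
    expect_true(endsWith(modifierSequence(m), r$sequence))
    # when the antepenultimate residue cleaves and G never does -> "GG"
    ante <- substring(modifierSequence(m), nchar(body), nchar(body))
    if (ante %in% sp@cleaveAfter) expect_identical(r$sequence, "GG")
  }
})

test_that("remnant peptides cover the site and carry the remnant mass", {
  peps <- remnantPeptides("MARHAADKGGSAAKR", 8, toy_ub(),
                          protease("trypsin"), DigestParams())
  expect_identical(nrow(peps), 1L)
  expect_identical(peps$peptide, "HAADKGGSAAK")
  expect_identical(peps$modPosition, 5L)
  expect_equal(peps$peptideMass,
               peptideMass("HAADKGGSAAK") + 114.04293, tolerance = TOL)
  peps1 <- remnantPeptides("MARHAADKGGSAAKR", 8, toy_ub(),
                           protease("trypsin"),
                           DigestParams(missedCleavages = 1))
  expect_gt(nrow(peps1), nrow(peps))
  expect_true(all(peps1$start <= 8 & peps1$end >= 8))
  expect_true(all(abs(peps1$remnantMass - 114.04293) < TOL))
  expect_error(remnantPeptides("MARHAADKGGSAAKR", 3, toy_ub(),
                               protease("trypsin"), DigestParams()),
               "not K")
})

test_that("random remnant peptides always span their site", {
  set.seed(32)
  for (rep_i in 1:10) {
    s <- random_seq(80)
    kpos <- which(strsplit(s, "")[[1]] == "K")
    if (!length(kpos)) next
    site <- kpos[sample.int(length(kpos), 1)]
    peps <- remnantPeptides(s, site, toy_ub(), protease("trypsin"),
                            DigestParams(missedCleavages = 2,
                                         maxLength = 1000))
    expect_true(nrow(peps) >= 1)
    expect_true(all(peps$start <= site & peps$end >= site))
    expect_true(all(substring(peps$peptide, peps$modPosition,
                              peps$modPosition) == "K"))
  }
})

test_that("indistinguishable modifiers group by identical remnants", {
  tryp <- protease("trypsin")
  ub <- ModifierProtein("toyUb2", "MKTALRGG")
  nedd8 <- ModifierProtein("toyNedd8", "MQSVLRGG")
  sumo <- toy_sumo()
  g <- remnantGroups(list(ub, nedd8), tryp)
  expect_length(g, 1L)                       # Ub = Nedd8 under trypsin
  g2 <- remnantGroups(list(sumo, ub), tryp)
  expect_length(g2, 2L)                      # SUMO-like remnant differs
  walpTL <- ProteaseSpec("walp-TL", c("T", "L"))
  fat10 <- ModifierProtein("toyFat10", "MQKARLGG")
  g3 <- remnantGroups(list(sumo, fat10), walpTL)
  expect_length(g3, 1L)                      # both leave GG under WaLP
  expect_setequal(g3[["GG"]], c("toySUMO", "toyFat10"))
  expect_error(remnantGroups(list(), tryp), "empty")
})

test_that("grouping is an equivalence partition covering all modifiers", {
  set.seed(33)
  mods <- lapply(1:8, function(i)
    ModifierProtein(paste0("m", i), paste0(random_seq(6), "GG"),
                    requireGG = FALSE))
  g <- remnantGroups(mods, protease("walp"))
  members <- unlist(g, use.names = FALSE)
  expect_setequal(members, paste0("m", 1:8))
  expect_identical(length(members), 8L)      # disjoint cover
})

test_that("mass-mode grouping merges Leu/Ile isobaric remnants", {
  sp <- ProteaseSpec("K-only", "K")
  m1 <- ModifierProtein("mL", "MAKLGG", requireGG = FALSE)
  m2 <- ModifierProtein("mI", "MAKIGG", requireGG = FALSE)
  expect_length(remnantGroups(list(m1, m2), sp, by = "sequence"), 2L)
  expect_length(remnantGroups(list(m1, m2), sp, by = "mass"), 1L)
})

test_that("packaged modifier snapshot gives GG remnants under WaLP", {
  mods <- builtinModifiers()
  expect_true(all(c("SUMO1", "SUMO2", "Ub", "Nedd8") %in% names(mods)))
  walp <- protease("walp")
  for (nm in c("SUMO1", "SUMO2", "SUMO3", "SUMO4"))
    expect_identical(remnant(mods[[nm]], walp)$sequence, "GG")
  # Ub and Nedd8 leave GG under trypsin (arginine precedes the diglycine)
  tryp <- protease("trypsin")
  expect_identical(remnant(mods$Ub, tryp)$sequence, "GG")
  expect_identical(remnant(mods$Nedd8, tryp)$sequence, "GG")
  # SUMO1 has no tryptic site near the C terminus: long tryptic remnant
  expect_gt(nchar(remnant(mods$SUMO1, tryp)$sequence), 10)
})

test_that("remnant report tabulates modifier x protease combinations", {
  rep_ <- remnantReport(list(toy_ub(), toy_sumo()),
                        list(protease("trypsin"), protease("walp")))
  expect_identical(nrow(rep_), 4L)
  expect_setequal(names(rep_), c("modifier", "protease", "remnant",
                                 "remnantMass"))
})
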