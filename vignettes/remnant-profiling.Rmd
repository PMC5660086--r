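---
title: "Remnant-based profiling of SUMO and ubiquitin modification sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remnant-based profiling of SUMO and ubiquitin modification sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumoKGG)
```

## The problem and the model

Ubiquitin and the ubiquitin-like modifiers (SUMO1-4, Nedd8, Fat10, Fub1)
are attached to substrate lysines through an isopeptide bond between the
modifier's C-terminal glycine carboxyl and the lysine side-chain amine.
When a conjugated proteome is digested with a protease, the modifier
itself is cleaved too, and whatever suffix of the modifier lies
C-terminal to its last cleavage site stays attached to the substrate
lysine. Mature ubiquitin ends in ...LRGG, so trypsin (cleaving after K/R)
leaves a diglycyl stub — the K-ε-GG or "KGG" remnant, +114.0429 Da on the
modified lysine — which is the handle used by remnant immuno-affinity
workflows to map ubiquitylation sites. Mature SUMO paralogs instead end
in ...TGG with no tryptic site near the C terminus, so trypsin leaves an
unwieldy multi-kilodalton remnant and SUMO sites are invisible to the
standard workflow. Wild-type α-lytic protease (WaLP) cleaves preferentially
after threonine (and after A/S/V/L and to some extent I, rarely after
arginine), so WaLP digestion of a SUMO-conjugated proteome produces the
same KGG remnant from the SUMO ...TGG terminus. Swapping the protease
thereby turns the ubiquitylation-site workflow into an endogenous
SUMOylation-site workflow, with no mutant SUMO constructs.

This package implements the computational side of that design:

* `remnant()` predicts the remnant any modifier leaves under any cleavage
  specificity, and `remnantGroups()` reports which modifiers become
  indistinguishable (ubiquitin and Nedd8 both leave GG under trypsin;
  SUMO- and Fat10-like ...TGG/...LGG termini both leave GG under WaLP).
* `digest()`, `cleavageSites()` and `peptideCoveringSite()` perform
  in-silico proteolysis with missed cleavages and modification-blocked
  cleavage (a remnant-bearing lysine is not cleaved by trypsin).
* `peptideMass()` and `fragmentIons()` do monoisotopic bookkeeping for
  branched remnant peptides.
* `mergeHeavyLight()`, `fdrFilter()`, `localizeSite()` and
  `collapseToSites()` post-process peptide-spectrum matches into unique,
  localized, FDR-controlled sites.
* `siteRatio()`, `siteQuantTable()`, `flagChanging()`,
  `compareConditions()` and `dualModificationTable()` handle SILAC
  site-level quantitation.
* `extractWindow()`, `classifyMotif()` and `motifSummary()` classify
  sites against the SUMO consensus motifs.
* `simConfig()`, `simulateProteome()`, `plantSites()` and
  `simulatePSMs()` generate seeded synthetic data with complete ground
  truth.

## Protease specificity

A `ProteaseSpec` is a cleave-after residue set, an optional suppression
set ("not before P"), and a blocked-by-modification switch. The built-in
trypsin is cleave after K/R, not before P, blocked by modification. The
built-in WaLP set is {A, S, T, V, L, I}: threonine is the preferred P1
residue, leucine and (to some extent) isoleucine are also cleaved, and
A/S/V come from the enzyme's published substrate characterization;
arginine is deliberately excluded because WaLP rarely cleaves after it.
No full cleavage-preference distribution has been published for WaLP, so
this set is a documented judgment call and is user-configurable, either
in code or through a plain-text spec file (`readProteaseSpec()`).
Searches run with "no enzyme specificity" are emulated here by digesting
with a permissive specificity rather than enumerating all substrings,
which avoids a combinatorial blow-up at the cost of not producing truly
nonspecific termini; `specificity = "semi"` covers the intermediate case.

Cleavage coordinates are 1-based and inclusive everywhere: "cleavage
after position i" cuts between residues i and i+1. The protein
N-terminal methionine is never removed implicitly.

Blocked cleavage is what makes two published worked examples computable:
a remnant-bearing lysine does not cleave, so the fully-tryptic peptide
covering a SUMO site runs between the nearest unblocked tryptic sites.
For a site buried in an arginine/lysine-poor stretch that peptide is far
too long to observe (57 residues in the DNA-PK example this package
reproduces on a synthetic stand-in sequence), and for a site crowded by
tryptic sites it is too short (6 residues in the Sp100-like example);
WaLP recovers both in ordinary-length peptides.

## Mass conventions

All masses are monoisotopic; average masses are not provided. The
remnant's delta mass is the sum of its residue masses with no extra
water, because the isopeptide linkage condenses out the water a free
peptide would carry: GG is 2 × 57.02146 = 114.04293 Da. The SILAC heavy
lysine (13C6 15N2) is +8.01420 Da, and the fixed-heavy-lysine search
convention of reporting label + remnant as one composite K modification
(+122.05713 Da) is undone by `mergeHeavyLight()`, with a 1 mDa match
tolerance; composites matching neither the label, the remnant, nor their
sum are flagged rather than silently merged.

Fragment ions follow the Biemann conventions: neutral b~i~ is the sum of
the first i residue masses, y~j~ adds one water, and the ETD series use
c = b + NH~3~ and z (the z-dot radical) = y − NH~3~ + H; these are stated
explicitly because z-ion nomenclature varies between instruments and
software. m/z at charge z is (neutral + z protons)/z. Mass comparisons in
the test suite use an absolute tolerance of 1e-4 Da, matching the
four-decimal precision at which the remnant mass is conventionally
quoted.

## FDR and site localization

`fdrFilter()` implements classical target-decoy estimation: at a score
threshold s, FDR(s) = #decoys ≥ s / max(1, #targets ≥ s), and the
q-value is the running minimum of FDR over decreasing thresholds.
Thresholds are evaluated at distinct score values, so records tied in
score share a q-value and every decoy in a tie block counts against the
targets there — the conservative direction — and the output is invariant
to input order. Decoys are never returned. The package's decoy
convention is whole-protein sequence reversal with a `decoy_` accession
prefix.

`localizeSite()` is an Ascore-like binomial scheme, not a reimplementation
of any specific localization engine: for each candidate placement of the
remnant among the peptide's lysines, the theoretical ions that differ
between placements (site-determining ions) are matched against the top
`peakDepth` peaks per 100 m/z at the fragment tolerance, and the chance
probability of at least that many matches is the binomial tail
P(X ≥ k | n, p) with p = (peakDepth/100) × 2 × tolerance. Site
probabilities are the normalized inverse tail probabilities, so a
placement whose evidence is harder to explain by chance receives
proportionally more weight, probabilities always sum to 1, a single
candidate gets probability 1, and a spectrum with no site-determining
matches splits evenly. The defaults (peak depth 10 per 100 m/z,
tolerance 0.5 Da, b/y ions) describe ion-trap CID spectra; add c/z for
ETD data. Multiple remnants per peptide (poly-SUMO peptides) are placed
jointly over lysine combinations and reported as per-position marginals.

Sites are then collapsed by `collapseToSites()` on the identity
(accession, absolute residue position, modification), keeping the best
probability and counting supporting PSMs; records under the 0.9
localization cut are dropped first, matching the conventional
PTM-confidence threshold. Peptides shared between accessions produce one
site per accession with an ambiguity flag — a policy, deliberately
simpler than protein-group inference, which is out of scope.

## SILAC quantitation

Site ratios are weighted means of peptide-level log2(H/L) values with
weights proportional to summed heavy+light intensity. Two choices here
are genuinely open and are made explicit:

* Averaging happens in **log2 space** by default (symmetric treatment of
  up- and down-regulation); `mode = "linear"` averages linear ratios
  instead, for workflows that defined the weighted average that way.
* Weights are the **summed channel intensities**, a proxy for
  measurement precision in the absence of per-peptide variance
  estimates. The estimator is invariant to rescaling all weights.

Ratios are median-centered across the experiment
(`normalizeRatios()`), removing the global mixing offset; the
"changing" flag marks sites more than `sdMult` (default 1) standard
deviations from the median, with the s.d. computed over the full
experiment's normalized site ratios, and independent twofold flags mark
|log2 ratio| ≥ 1. Measurements with a zero light intensity have no
defined ratio: they are reported as heavy-only and excluded from ratio
statistics rather than imputed. Condition comparisons use the two-tailed
Welch t-test, marked not-computed below two values per group. Because
the labeling is lysine-only, every remnant peptide necessarily contains
a lysine and is quantifiable by design; the simulator enforces the same.

## Motif classification

The forward SUMO consensus ΨKX[E|D] is checked at offsets −1 (Ψ,
hydrophobic) and +2 (acidic); the inverted motif [E|D]XK at offset −2.
Ψ defaults to {A, I, L, M, P, F, V}, the common convention where the
consensus literature leaves Ψ undefined, and is configurable. Forward
takes precedence when a window satisfies both patterns, because it is
the canonical, better-characterized motif; with that precedence the
classifier is a total function and summaries are permutation-invariant.
Windows default to ±5 residues for logos, though classification needs
only ±2; terminus padding (`-`) never matches any residue class.

## The synthetic-data generator

The generator exists so that every stage has a test oracle without any
raw mass-spectrometry downloads. `simulateProteome()` draws uniform-
composition sequences (a configurable background table can replace
this); `plantSites()` picks lysines at least 6 residues apart, edits the
±2 context to realize an assigned motif class, and apportions classes by
largest-remainder rounding — the defaults (31% forward, 9% inverted, 60%
neither) reproduce the class fractions reported by large SUMO-site
surveys, so a simulated site list is a faithful stand-in for a real one
at the level of motif statistics. `simulatePSMs()` digests each site's
protein with the configured protease (site blocked), attaches the
modifier's remnant, and emits:

* PSM records with Gaussian scores (true mean 3, decoy/false mean 0,
  s.d. 1 — arbitrary but fixed, and the basis of the FDR calibration
  tests), reversed-sequence decoys at a configured fraction of the
  table, a configured fraction of planted false targets (the ground
  truth for realized-FDP checks), and heavy-search records carrying the
  composite K modification;
* SILAC intensity pairs, log-normal around each site's planted log2
  ratio with per-channel sigma 0.2 log2 units by default;
* optionally, synthetic peak lists containing all placement-independent
  ions and a configured fraction (default 0.9) of the true placement's
  site-determining ions.

Everything is a deterministic function of the config seed;
byte-identical outputs are asserted in the tests. What the simulator
does **not** model — chromatography, charge-state and isotope-envelope
structure, intensity-dependent scoring, real amino-acid composition,
shared peptides between paralogs — bounds what passing tests show: they
validate the algorithms and their statistical calibration, not
instrument realism.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen once: 1209 planted sites (matching the size of the SUMO
site inventory whose motif fractions the defaults mirror) for motif
recovery, 150 sites × 2 peptides for FDR calibration (~300 targets, ~33
decoys), 100 sites × 3 peptides at sigma 0.2 for change-flag
sensitivity, and 120 sites at 1/2/4/8 peptides per site for the
RMSE-vs-support curve. Degenerate inputs fail loudly: empty peptides,
non-standard residues, out-of-range sites, all-decoy PSM tables and
ratio-less sites raise errors or warnings rather than returning silent
defaults.

## Known limitations

* The packaged modifier FASTA is a synthetic snapshot of mature
  C-terminal segments, sufficient for remnant prediction (which depends
  only on the suffix past the last cleavage site) but not a curated
  sequence database; likewise the two worked-example proteins ship as
  synthetic stand-ins reproducing the published local tryptic-site
  context. Users with database access should supply real FASTA files.
* Remnant identity is compared by sequence by default; `by = "mass"`
  merges Leu/Ile-isobaric remnants as a mass spectrometer would see
  them.
* Database search scoring, mixture-model rescoring, protein inference
  and raw-file peak integration are out of scope; the package consumes
  search-engine-style PSM tables and intensity tables.
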