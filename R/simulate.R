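## Seeded synthetic-data generator: proteomes, planted remnant sites with
## known motif classes, PSM tables with decoys and heavy/light states,
## SILAC intensity pairs with planted log2 ratios, and synthetic MGF-style
## spectra with a controlled fraction of site-determining ions. Ground
## truth is returned alongside everything, so every downstream module can
## be validated by round-trip.

#' Simulation configuration
#'
#' All randomness in the generator is fixed by \code{seed}; identical
#' configurations give byte-identical outputs. Defaults describe a small
#' but realistic remnant-profiling experiment: uniform-composition
#' proteins, planted sites following the consensus-motif fractions
#' observed in large SUMO surveys (31\% forward, 9\% inverted, 60\%
#' neither), Gaussian search scores separating true matches (mean 3) from
#' decoy/false matches (mean 0), a 13C6 15N2 lysine SILAC design with
#' log-normal intensity noise of sigma 0.2 (log2 units) per channel, and
#' 90\% of site-determining fragment ions observed.
#'
#' @param seed Integer random seed.
#' @param nProteins Number of proteins.
#' @param lengthRange Protein length bounds (uniform).
#' @param nSites Number of planted modification sites.
#' @param motifFractions Length-3 numeric (forward, inverted, none),
#'   summing to 1; planted counts follow largest-remainder rounding.
#' @param minSiteSpacing Minimum residue separation between planted sites
#'   in one protein (keeps motif edits independent).
#' @param protease \code{"trypsin"} or \code{"walp"}: digestion used to
#'   build remnant peptides (the matching toy modifier is chosen so the
#'   remnant is the diglycine).
#' @param missedCleavages,minLength,maxLength Digestion parameters for the
#'   simulated peptides.
#' @param peptidesPerSite Peptide measurements generated per site.
#' @param decoyFraction Fraction of the emitted PSM table that is decoy
#'   records (reversed sequences).
#' @param falseTargetFraction Fraction of target PSMs that are planted
#'   false matches (scores drawn from the decoy distribution; recorded in
#'   the ground truth for FDR calibration).
#' @param heavyFraction Fraction of true PSMs reported from the
#'   fixed-heavy-lysine search (composite K modification).
#' @param scoreTrue,scoreDecoy Mean/sd pairs of the Gaussian score models.
#' @param log2Ratios Planted site log2(H/L) values, recycled over sites;
#'   or \code{NULL} to draw from Normal(\code{ratioMean},
#'   \code{ratioSd}).
#' @param ratioMean,ratioSd Ratio-drawing parameters when
#'   \code{log2Ratios} is NULL.
#' @param intensitySigma Log-normal noise sigma (log2 units) per channel.
#' @param baseIntensity Median channel intensity (arbitrary units).
#' @param ionObservedFraction Fraction of site-determining ions of the
#'   true placement present in synthetic spectra.
#' @param makeSpectra Generate synthetic spectra?
#' @return A classed list (\code{"SimConfig"}).
#' @export
simConfig <- function(seed = 1L,
                      nProteins = 40L,
                      lengthRange = c(120L, 300L),
                      nSites = 100L,
                      motifFractions = c(forward = 0.31, inverted = 0.09,
                                         none = 0.60),
                      minSiteSpacing = 6L,
                      protease = "trypsin",
                      missedCleavages = 1L,
                      minLength = 5L,
                      maxLength = 45L,
                      peptidesPerSite = 2L,
                      decoyFraction = 0.1,
                      falseTargetFraction = 0.1,
                      heavyFraction = 0.5,
                      scoreTrue = c(mean = 3, sd = 1),
                      scoreDecoy = c(mean = 0, sd = 1),
                      log2Ratios = NULL,
                      ratioMean = 0, ratioSd = 0.5,
                      intensitySigma = 0.2,
                      baseIntensity = 1e6,
                      ionObservedFraction = 0.9,
                      makeSpectra = FALSE) {
  motifFractions <- stats::setNames(as.numeric(motifFractions),
                                    c("forward", "inverted", "none"))
  if (any(motifFractions < 0) || abs(sum(motifFractions) - 1) > 1e-9)
    stop("motifFractions must be non-negative and sum to 1")
  if (decoyFraction < 0 || decoyFraction >= 1)
    stop("decoyFraction must be in [0, 1)")
  cfg <- list(seed = as.integer(seed), nProteins = as.integer(nProteins),
              lengthRange = as.integer(lengthRange),
              nSites = as.integer(nSites), motifFractions = motifFractions,
              minSiteSpacing = as.integer(minSiteSpacing),
              protease = protease,
              missedCleavages = as.integer(missedCleavages),
              minLength = as.integer(minLength),
              maxLength = as.integer(maxLength),
              peptidesPerSite = as.integer(peptidesPerSite),
              decoyFraction = decoyFraction,
              falseTargetFraction = falseTargetFraction,
              heavyFraction = heavyFraction,
              scoreTrue = scoreTrue, scoreDecoy = scoreDecoy,
              log2Ratios = log2Ratios,
              ratioMean = ratioMean, ratioSd = ratioSd,
              intensitySigma = intensitySigma,
              baseIntensity = baseIntensity,
              ionObservedFraction = ionObservedFraction,
              makeSpectra = isTRUE(makeSpectra))
  class(cfg) <- "SimConfig"
  cfg
}

#' Read a simulation config from a key-value file
#'
#' Plain-text \code{key = value} lines; vector values comma-separated.
#' Unknown keys are rejected.
#'
#' @param path File path.
#' @return A \code{SimConfig}.
#' @export
readSimConfig <- function(path) {
  kv <- .read_keyvalue(path)
  defaults <- simConfig()
  bad <- setdiff(names(kv), names(unclass(defaults)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  num <- function(x) as.numeric(strsplit(x, ",")[[1]])
  args <- lapply(names(kv), function(k) {
    v <- kv[[k]]
    if (k %in% c("protease")) v
    else if (k %in% c("makeSpectra")) tolower(v) %in% c("true", "yes", "1")
    else num(v)
  })
  names(args) <- names(kv)
  do.call(simConfig, args)
}

#' Simulate a proteome
#'
#' Random protein sequences with residues drawn uniformly from the 20
#' standard amino acids; every protein is guaranteed at least one lysine.
#' Reproducible from the config seed.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return data.frame: \code{id}, \code{description}, \code{sequence}.
#' @export
simulateProteome <- function(cfg) {
  if (cfg$nProteins < 1L) stop("nProteins must be >= 1")
  set.seed(cfg$seed)
  aa <- names(.RESIDUE_MASS)
  seqs <- vapply(seq_len(cfg$nProteins), function(i) {
    len <- cfg$lengthRange[1] +
      sample.int(cfg$lengthRange[2] - cfg$lengthRange[1] + 1L, 1L) - 1L
    s <- sample(aa, len, replace = TRUE)
    if (!any(s == "K")) s[sample(len, 1L)] <- "K"
    paste(s, collapse = "")
  }, character(1))
  data.frame(id = sprintf("SIMP%04d", seq_len(cfg$nProteins)),
             description = "simulated protein",
             sequence = seqs, stringsAsFactors = FALSE)
}

# Largest-remainder apportionment of n into parts proportional to fractions.
.largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plant modification sites with known motif classes
#'
#' Chooses lysines (separated by at least \code{minSiteSpacing} residues,
#' away from the termini) and edits the +/-2 context so each site's window
#' classifies exactly as its assigned class: forward sites get a
#' hydrophobic residue at -1 and E/D at +2; inverted sites get E/D at -2
#' with a non-hydrophobic -1; "none" sites get glycines at -2, -1 and +2.
#' Class counts follow largest-remainder rounding of the configured
#' fractions. Planted log2 ratios are attached per site.
#'
#' @param proteome Output of \code{\link{simulateProteome}}.
#' @param cfg The \code{\link{simConfig}} used to build it.
#' @return List: \code{proteome} (edited sequences) and \code{sites}
#'   (data.frame: accession, position, class, log2Ratio).
#' @export
plantSites <- function(proteome, cfg) {
  set.seed(cfg$seed + 1L)
  cand <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    s <- strsplit(proteome$sequence[i], "")[[1]]
    pos <- which(s == "K")
    pos <- pos[pos > 2L & pos < length(s) - 2L]
    if (!length(pos)) return(NULL)
    data.frame(idx = i, position = pos)
  }))
  if (is.null(cand) || !nrow(cand)) stop("proteome has no usable lysines")
  cand <- cand[sample(nrow(cand)), ]
  chosen_by_prot <- vector("list", nrow(proteome))
  keep <- logical(nrow(cand))
  nPicked <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand$idx[r]; p <- cand$position[r]
    prev <- chosen_by_prot[[i]]
    if (is.null(prev) || all(abs(prev - p) >= cfg$minSiteSpacing)) {
      chosen_by_prot[[i]] <- c(prev, p)
      keep[r] <- TRUE
      nPicked <- nPicked + 1L
      if (nPicked == cfg$nSites) break
    }
  }
  if (nPicked < cfg$nSites)
    stop("insufficient lysines to plant ", cfg$nSites, " sites (found ",
         nPicked, ")")
  sites <- cand[keep, , drop = FALSE]
  counts <- .largest_remainder(cfg$nSites, cfg$motifFractions)
  cls <- rep(c("forward", "inverted", "none"), counts)
  sites$class <- sample(cls)       # shuffle class-to-site assignment
  seqs <- strsplit(proteome$sequence, "")
  ed <- c("E", "D")
  for (r in seq_len(nrow(sites))) {
    i <- sites$idx[r]; p <- sites$position[r]
    s <- seqs[[i]]
    switch(sites$class[r],
      forward = {
        s[p - 1L] <- sample(.PSI_DEFAULT, 1L)
        s[p + 2L] <- sample(ed, 1L)
      },
      inverted = {
        s[p - 2L] <- sample(ed, 1L)
        s[p - 1L] <- "G"            # not hydrophobic: kills forward
      },
      none = {
        s[p - 2L] <- "G"; s[p - 1L] <- "G"; s[p + 2L] <- "G"
      })
    seqs[[i]] <- s
  }
  proteome$sequence <- vapply(seqs, paste, character(1), collapse = "")
  ratios <- if (!is.null(cfg$log2Ratios))
    rep_len(cfg$log2Ratios, cfg$nSites)
  else stats::rnorm(cfg$nSites, cfg$ratioMean, cfg$ratioSd)
  out <- data.frame(accession = proteome$id[sites$idx],
                    position = sites$position,
                    class = sites$class,
                    log2Ratio = ratios,
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$position), ]
  rownames(out) <- NULL
  list(proteome = proteome, sites = out)
}

# Toy modifier whose remnant under the configured protease is "GG".
.sim_modifier <- function(protease_name) {
  if (protease_name == "walp")
    ModifierProtein("simSUMO", "MQKARTGG")    # WaLP cuts after T -> GG
  else
    ModifierProtein("simUb", "MQKATLRGG")     # trypsin cuts after R -> GG
}

#' Simulate PSM, measurement and spectrum tables from planted sites
#'
#' True PSMs are remnant peptides obtained by digesting each site's
#' protein (site cleavage-blocked) with the configured protease; scores
#' come from the true-score Gaussian, except a planted
#' \code{falseTargetFraction} whose scores come from the decoy
#' distribution (recorded in \code{psmTruth} — the handle for FDR
#' calibration). Decoy PSMs are peptides from reversed sequences with
#' \code{decoy_}-prefixed accessions, making up \code{decoyFraction} of
#' the table. A configured fraction of true PSMs is emitted as
#' fixed-heavy-lysine search records carrying the composite
#' label+remnant K modification. SILAC measurements draw per-channel
#' log-normal intensities around each site's planted log2 ratio. When
#' \code{makeSpectra}, each true PSM gets a synthetic peak list containing
#' all non-determining ions and the configured fraction of the true
#' placement's site-determining ions.
#'
#' @param proteome Edited proteome from \code{\link{plantSites}}.
#' @param sites Ground-truth site table from \code{\link{plantSites}}.
#' @param cfg The \code{\link{simConfig}}.
#' @return List: \code{psms} (PSM table), \code{measurements}
#'   (SILAC intensity table), \code{spectra} (list of
#'   \code{\link{spectrumPeaks}}, or NULL), \code{psmTruth} (data.frame
#'   spectrum_id / correct), \code{sites} (the ground truth, passed
#'   through).
#' @export
simulatePSMs <- function(proteome, sites, cfg) {
  set.seed(cfg$seed + 2L)
  spec <- protease(cfg$protease)
  modifier <- .sim_modifier(cfg$protease)
  params <- DigestParams(missedCleavages = cfg$missedCleavages,
                         minLength = cfg$minLength,
                         maxLength = cfg$maxLength)
  seqOf <- stats::setNames(proteome$sequence, proteome$id)

  psm_rows <- list(); meas_rows <- list(); truth <- list()
  spectra <- if (cfg$makeSpectra) list() else NULL
  sid <- 0L
  for (r in seq_len(nrow(sites))) {
    acc <- sites$accession[r]; pos <- sites$position[r]
    peps <- remnantPeptides(seqOf[[acc]], pos, modifier, spec, params)
    if (!nrow(peps)) {
      # length bounds excluded every covering peptide; fall back to the
      # fully-specific covering peptide so the site is represented
      cover <- peptideCoveringSite(seqOf[[acc]], spec, pos)
      peps <- data.frame(start = cover$start, end = cover$end,
                         peptide = cover$peptide, missed = NA_integer_,
                         modPosition = pos - cover$start + 1L,
                         remnant = remnant(modifier, spec)$sequence,
                         remnantMass = remnant(modifier, spec)$mass,
                         peptideMass = NA_real_)
    }
    take <- seq_len(min(cfg$peptidesPerSite, nrow(peps)))
    # recycle peptides when fewer forms than requested measurements
    take <- rep_len(take, cfg$peptidesPerSite)
    for (t_ in take) {
      sid <- sid + 1L
      pep <- peps[t_, ]
      isFalse <- stats::runif(1) < cfg$falseTargetFraction
      score <- if (isFalse)
        stats::rnorm(1, cfg$scoreDecoy["mean"], cfg$scoreDecoy["sd"])
      else stats::rnorm(1, cfg$scoreTrue["mean"], cfg$scoreTrue["sd"])
      heavy <- stats::runif(1) < cfg$heavyFraction
      mod_string <- if (heavy)
        sprintf("%d:%+.5f", pep$modPosition,
                modMass("HeavyK") + modMass("GlyGly"))
      else sprintf("%d:GlyGly", pep$modPosition)
      id <- sprintf("sim%06d", sid)
      psm_rows[[sid]] <- data.frame(
        spectrum_id = id, accession = acc, peptide = pep$peptide,
        mod_string = mod_string, score = score, decoy = 0L,
        label = if (heavy) "H" else "L", charge = 2L,
        start = pep$start, modPosition = pep$modPosition,
        stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(spectrum_id = id, correct = !isFalse,
                                 accession = acc, position = pos)
      # SILAC measurement for this peptide observation
      noise <- stats::rnorm(2, 0, cfg$intensitySigma)
      light <- cfg$baseIntensity * 2^(-sites$log2Ratio[r] / 2 + noise[1])
      heavyI <- cfg$baseIntensity * 2^(sites$log2Ratio[r] / 2 + noise[2])
      meas_rows[[sid]] <- data.frame(
        peptide = pep$peptide, accession = acc, position = pos,
        heavy_intensity = heavyI, light_intensity = light,
        stringsAsFactors = FALSE)
      if (cfg$makeSpectra) {
        spectra[[id]] <- .sim_spectrum(pep$peptide, pep$modPosition, cfg)
      }
    }
  }
  psms <- do.call(rbind, psm_rows)
  # decoys: decoyFraction of the combined table
  nTrue <- nrow(psms)
  nDecoy <- round(cfg$decoyFraction * nTrue / (1 - cfg$decoyFraction))
  if (nDecoy > 0L) {
    rev_idx <- sample(nrow(proteome), nDecoy, replace = TRUE)
    dec_rows <- lapply(seq_len(nDecoy), function(i) {
      sid_d <- sprintf("simD%05d", i)
      rseq <- paste(rev(strsplit(proteome$sequence[rev_idx[i]], "")[[1]]),
                    collapse = "")
      len <- sample(cfg$minLength:min(cfg$maxLength, 20L), 1L)
      startp <- sample(max(1L, nchar(rseq) - len), 1L)
      pepseq <- substring(rseq, startp, startp + len - 1L)
      kpos <- which(strsplit(pepseq, "")[[1]] == "K")
      mod_string <- if (length(kpos)) sprintf("%d:GlyGly", kpos[1]) else ""
      data.frame(
        spectrum_id = sid_d,
        accession = paste0("decoy_", proteome$id[rev_idx[i]]),
        peptide = pepseq, mod_string = mod_string,
        score = stats::rnorm(1, cfg$scoreDecoy["mean"], cfg$scoreDecoy["sd"]),
        decoy = 1L, label = "L", charge = 2L,
        start = NA_integer_,
        modPosition = if (length(kpos)) kpos[1] else NA_integer_,
        stringsAsFactors = FALSE)
    })
    psms <- rbind(psms, do.call(rbind, dec_rows))
  }
  rownames(psms) <- NULL
  list(psms = psms,
       measurements = do.call(rbind, meas_rows),
       spectra = spectra,
       psmTruth = do.call(rbind, truth),
       sites = sites)
}

# Synthetic spectrum for one remnant peptide: every placement-independent
# ion plus the observed fraction of the true placement's site-determining
# ions; flat intensities with mild jitter for peak-depth realism.
.sim_spectrum <- function(pepseq, modPosition, cfg) {
  res <- strsplit(pepseq, "")[[1]]
  cand <- which(res == "K")
  p_true <- Peptide(pepseq, mods = data.frame(position = modPosition,
                                              name = "GlyGly"))
  ions_true <- fragmentIons(p_true, series = c("b", "y"))$mz
  if (length(cand) > 1L) {
    all_theo <- lapply(cand, function(k) {
      fragmentIons(Peptide(pepseq, mods = data.frame(position = k,
                                                     name = "GlyGly")),
                   series = c("b", "y"))$mz
    })
    inAll <- vapply(ions_true, function(m)
      all(vapply(all_theo, function(t) any(abs(t - m) <= 1e-6), logical(1))),
      logical(1))
    common <- ions_true[inAll]
    det <- ions_true[!inAll]
    det <- det[stats::runif(length(det)) < cfg$ionObservedFraction]
    mzs <- c(common, det)
  } else {
    mzs <- ions_true
  }
  mzs <- sort(unique(round(mzs, 5)))
  intens <- 100 + stats::runif(length(mzs), 0, 50)
  spectrumPeaks(mzs, intens,
                precursorMz = (peptideMass(p_true) + 2 * .MASS_PROTON) / 2,
                precursorCharge = 2L,
                title = pepseq)
}
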