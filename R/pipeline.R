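## End-to-end convenience pipeline over the simulator and the processing
## modules; also the engine behind the command-line `pipeline` subcommand.

#' Run the remnant-profiling pipeline on simulated data
#'
#' Generates a seeded synthetic experiment and pushes it through the full
#' post-search stack: heavy/light merging, target-decoy FDR filtering,
#' localization (spectrum-based when spectra were simulated, otherwise
#' single-candidate certainty), collapsing to unique sites, site-level
#' SILAC quantitation with change flagging, and motif classification of
#' the identified sites.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param fdrThreshold PSM-level FDR cut (default 0.01).
#' @param locThreshold Localization probability cut (default 0.9).
#' @param outDir Optional directory: writes proteome FASTA, PSM /
#'   measurement / site / quant TSVs (and MGF when spectra exist).
#' @return List: \code{truth} (planted sites + PSM truth), \code{psms}
#'   (merged, FDR-filtered), \code{qvalues}, \code{sites} (collapsed
#'   identifications), \code{quant} (site quant table), \code{motifs}
#'   (summary over identified sites), \code{proteome}.
#' @export
runPipeline <- function(cfg, fdrThreshold = 0.01, locThreshold = 0.9,
                        outDir = NULL) {
  prot <- simulateProteome(cfg)
  planted <- plantSites(prot, cfg)
  sim <- simulatePSMs(planted$proteome, planted$sites, cfg)

  merged <- mergeHeavyLight(sim$psms)
  filt <- fdrFilter(merged, threshold = fdrThreshold)
  psms <- filt$psms

  # localization probability per retained PSM
  psms$probability <- vapply(seq_len(nrow(psms)), function(i) {
    pepseq <- psms$peptide[i]
    kpos <- which(strsplit(pepseq, "")[[1]] == "K")
    if (length(kpos) <= 1L) return(1.0)
    id <- psms$spectrum_id[i]
    if (!is.null(sim$spectra) && !is.null(sim$spectra[[id]])) {
      loc <- localizeSite(sim$spectra[[id]], pepseq)
      mp <- as.character(psms$modPosition[i])
      if (mp %in% names(loc$positionProbability))
        return(unname(loc$positionProbability[mp]))
    }
    1 / length(kpos)     # no spectrum: uniform over candidates
  }, numeric(1))

  sites <- collapseToSites(psms, threshold = locThreshold)
  quant <- siteQuantTable(sim$measurements)
  seqOf <- stats::setNames(planted$proteome$sequence, planted$proteome$id)
  idx <- sites$accession %in% names(seqOf)
  windows <- vapply(which(idx), function(i)
    extractWindow(seqOf[[sites$accession[i]]], sites$position[i], flank = 5L),
    character(1))
  motifs <- if (length(windows)) motifSummary(windows) else NULL

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(planted$proteome, file.path(outDir, "proteome.fasta"))
    writePSMTable(sim$psms, file.path(outDir, "psms.tsv"))
    writeMeasurementTable(sim$measurements,
                          file.path(outDir, "measurements.tsv"))
    writeSiteTable(sites, file.path(outDir, "sites.tsv"))
    writeSiteTable(quant, file.path(outDir, "site_quant.tsv"))
    writeSiteTable(planted$sites, file.path(outDir, "ground_truth_sites.tsv"))
    if (!is.null(sim$spectra))
      writeMGF(sim$spectra, file.path(outDir, "spectra.mgf"))
  }

  list(truth = list(sites = planted$sites, psmTruth = sim$psmTruth),
       psms = psms, qvalues = filt$qvalues, sites = sites, quant = quant,
       motifs = motifs, proteome = planted$proteome,
       measurements = sim$measurements)
}
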