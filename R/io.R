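## Readers and writers for the external formats: FASTA (via Biostrings),
## MGF peak lists, tab-separated PSM / measurement / site / known-site
## tables, and plain-text key-value configuration files.
##
## TSV dialect: tab-separated, UTF-8, '#'-prefixed comment lines allowed,
## header required.

.read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Read protein records from FASTA
#'
#' Wraps \code{Biostrings::readAAStringSet}: identifiers are the first
#' whitespace-delimited token of each header, the rest is the description.
#' Sequences are upper-cased and stop characters (\code{*}) stripped.
#' Duplicate identifiers and empty files are errors.
#'
#' @param path FASTA file path.
#' @return data.frame: \code{id}, \code{description}, \code{sequence}
#'   (order preserved).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame with \code{id}, \code{sequence} and optional
#'   \code{description}, or a named character vector of sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records))
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records))
  set <- Biostrings::AAStringSet(records$sequence)
  desc <- if (!is.null(records$description)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## ---- TSV tables -------------------------------------------------------

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  df
}

#' Write a table as TSV
#'
#' Tab-separated, header, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param comment Optional comment line(s) written with a \code{#} prefix.
#' @return \code{path}, invisibly.
#' @export
writeTSV <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSM table
#'
#' Required columns: \code{spectrum_id}, \code{accession}, \code{peptide},
#' \code{mod_string} (comma-separated \code{pos:name} or \code{pos:+mass}
#' tokens), \code{score}, \code{decoy} (0/1), \code{label} (H/L/.),
#' \code{charge}. Optional: \code{start}, \code{modPosition}. Rows with a
#' non-numeric score or decoy flag are collected into a rejects report
#' (attribute \code{"rejects"}), not silently dropped.
#'
#' @param path TSV path.
#' @return Typed PSM data.frame; \code{attr(x, "rejects")} holds the
#'   rejected rows (possibly empty).
#' @export
readPSMTable <- function(path) {
  req <- c("spectrum_id", "accession", "peptide", "mod_string", "score",
           "decoy", "label", "charge")
  df <- .read_tsv(path, req)
  if (!nrow(df)) {
    warning("PSM table has no rows: ", path)
    attr(df, "rejects") <- df
    return(df)
  }
  score <- suppressWarnings(as.numeric(df$score))
  decoy <- suppressWarnings(as.integer(df$decoy))
  bad <- is.na(score) | is.na(decoy) | !decoy %in% c(0L, 1L) |
         is.na(df$peptide) | !nzchar(df$peptide)
  rejects <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  df$score <- score[!bad]
  df$decoy <- decoy[!bad]
  df$charge <- suppressWarnings(as.integer(df$charge))
  df$mod_string[is.na(df$mod_string)] <- ""
  if ("start" %in% names(df)) df$start <- suppressWarnings(as.integer(df$start))
  if ("modPosition" %in% names(df))
    df$modPosition <- suppressWarnings(as.integer(df$modPosition))
  rownames(df) <- NULL
  attr(df, "rejects") <- rejects
  df
}

#' @rdname readPSMTable
#' @param psms PSM data.frame.
#' @export
writePSMTable <- function(psms, path) {
  writeTSV(psms, path)
}

#' Read / write SILAC measurement tables
#'
#' Columns: \code{peptide}, \code{accession}, \code{position},
#' \code{heavy_intensity}, \code{light_intensity}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readMeasurementTable <- function(path) {
  df <- .read_tsv(path, c("peptide", "accession", "position",
                          "heavy_intensity", "light_intensity"))
  df$position <- as.integer(df$position)
  df$heavy_intensity <- as.numeric(df$heavy_intensity)
  df$light_intensity <- as.numeric(df$light_intensity)
  df
}

#' @rdname readMeasurementTable
#' @param measurements data.frame.
#' @export
writeMeasurementTable <- function(measurements, path) {
  writeTSV(measurements, path)
}

#' Read a known-site table
#'
#' Columns: \code{accession}, \code{position}, \code{source}. Malformed
#' rows (empty accession or non-integer position) are skipped; the count
#' is reported in attribute \code{"skipped"}.
#'
#' @param path TSV path.
#' @return data.frame with attribute \code{"skipped"}.
#' @export
readKnownSites <- function(path) {
  df <- .read_tsv(path, c("accession", "position", "source"))
  pos <- suppressWarnings(as.integer(df$position))
  ok <- !is.na(pos) & !is.na(df$accession) & nzchar(as.character(df$accession))
  out <- df[ok, , drop = FALSE]
  out$position <- pos[ok]
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Read / write site tables
#'
#' Site tables carry \code{accession}, \code{position} and whatever
#' additional columns the producing step attached (probability, psmCount,
#' log2Ratio, flags, ...).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSiteTable <- function(path) {
  df <- .read_tsv(path, c("accession", "position"))
  df$position <- as.integer(df$position)
  df
}

#' @rdname readSiteTable
#' @param sites data.frame.
#' @export
writeSiteTable <- function(sites, path) {
  writeTSV(sites, path)
}

## ---- MGF --------------------------------------------------------------

#' Read an MGF peak list
#'
#' Minimal Mascot generic format support: BEGIN IONS / END IONS blocks
#' with TITLE, PEPMASS, CHARGE headers and "m/z intensity" peak lines.
#'
#' @param path MGF file path.
#' @return Named list of \code{\link{spectrumPeaks}} (named by TITLE, or
#'   \code{spectrum<N>} when untitled).
#' @export
readMGF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L; n <- length(lines); count <- 0L
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      count <- count + 1L
      title <- sprintf("spectrum%d", count)
      pepmass <- NA_real_; charge <- NA_integer_
      mz <- numeric(); intensity <- numeric()
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) title <- sub("^TITLE=", "", ln)
        else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(gsub("[^0-9]", "", ln))
        } else if (grepl("^[0-9]", ln)) {
          f <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mz <- c(mz, f[1]); intensity <- c(intensity, f[2])
        }
        i <- i + 1L
      }
      o <- order(mz)
      out[[title]] <- spectrumPeaks(mz[o], intensity[o], pepmass, charge, title)
    }
    i <- i + 1L
  }
  out
}

#' @rdname readMGF
#' @param spectra Named list of \code{\link{spectrumPeaks}}.
#' @export
writeMGF <- function(spectra, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  nms <- names(spectra)
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    title <- if (!is.null(nms) && nzchar(nms[i])) nms[i]
             else if (nzchar(sp$title)) sp$title else sprintf("spectrum%d", i)
    writeLines(paste0("TITLE=", title), con)
    if (!is.na(sp$precursorMz))
      writeLines(sprintf("PEPMASS=%.6f", sp$precursorMz), con)
    if (!is.na(sp$precursorCharge))
      writeLines(sprintf("CHARGE=%d+", sp$precursorCharge), con)
    writeLines(sprintf("%.6f %.2f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
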