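# Brute-force oracles and tiny fixture builders shared across tests.

# Residue alphabet for random sequences
AA20 <- c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P","S",
          "T","V","W","Y")

random_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force digestion: find cleavage positions by direct rule scan, then
# enumerate all adjacent-fragment concatenations up to mc missed cleavages.
bf_cleavage_sites <- function(sequence, cleave_after, not_before = character(),
                              blocked = integer()) {
  res <- strsplit(sequence, "")[[1]]
  out <- integer()
  for (i in seq_along(res)) {
    if (!(res[i] %in% cleave_after)) next
    if (i < length(res) && res[i + 1] %in% not_before) next
    if (i %in% blocked) next
    out <- c(out, i)
  }
  out
}

bf_digest <- function(sequence, cleave_after, not_before = character(),
                      mc = 0, minLen = 1, maxLen = Inf, blocked = integer()) {
  n <- nchar(sequence)
  cuts <- bf_cleavage_sites(sequence, cleave_after, not_before, blocked)
  cuts <- cuts[cuts < n]
  bounds <- c(0, cuts, n)           # fragment i spans (bounds[i]+1, bounds[i+1])
  peps <- list()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(length(bounds) - 1, i + mc)) {
      s <- bounds[i] + 1; e <- bounds[j + 1]
      if (e - s + 1 >= minLen && e - s + 1 <= maxLen)
        peps[[length(peps) + 1]] <- c(s, e)
    }
  }
  if (!length(peps)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, peps)
  data.frame(start = m[, 1], end = m[, 2])
}

# Brute-force target-decoy q-values: for each target score s, FDR(s) over
# the >= s threshold, q = min FDR over all thresholds at least as permissive.
bf_qvalues <- function(score, decoy) {
  decoy <- as.logical(decoy)
  vapply(seq_along(score), function(i) {
    if (decoy[i]) return(NA_real_)
    ths <- unique(score[score <= score[i]])
    min(vapply(ths, function(s) {
      sum(decoy & score >= s) / max(1, sum(!decoy & score >= s))
    }, numeric(1)))
  }, numeric(1))
}

# Brute-force binomial localization for a 2-candidate peptide: inverse
# binomial-tail weighting over both placements.
bf_localize2 <- function(k1, n1, k2, n2, p) {
  t1 <- if (n1 == 0) 1 else sum(dbinom(k1:n1, n1, p))
  t2 <- if (n2 == 0) 1 else sum(dbinom(k2:n2, n2, p))
  w <- c(1 / t1, 1 / t2)
  w / sum(w)
}

toy_ub   <- function() ModifierProtein("toyUb", "MRGG")
toy_sumo <- function() ModifierProtein("toySUMO", "MQKARTGG")
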