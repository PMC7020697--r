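# Independent oracles and small fixture builders shared across tests.
# These deliberately use straight-line / brute-force logic, not the
# package's vectorized implementations.

# Brute-force maximal-run peak oracle: enumerate every contiguous run of
# above-cutoff probes (in candidate-subsequence order), check the gap and
# chromosome rules pairwise, keep maximal qualifying runs.
oracle_find_runs <- function(chrom, position, score, cutoff, max_gap, min_probes) {
  cand <- which(score >= cutoff)
  runs <- list()
  if (length(cand) == 0L) return(runs)
  n <- length(cand)
  linked <- function(a, b) {  # candidate indices a, b adjacent in subsequence
    chrom[cand[a]] == chrom[cand[b]] &&
      abs(position[cand[b]] - position[cand[a]]) <= max_gap
  }
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && linked(j, j + 1L)) j <- j + 1L
    if (j - i + 1L >= min_probes) runs[[length(runs) + 1L]] <- cand[i:j]
    i <- j + 1L
  }
  runs
}

# Straight-line re-implementation of the two DEP filter criteria, written
# plainly: per-group member medians, in-direction median M', per-group CV
# pass fractions.
oracle_filter_verdict <- function(member_idx, direction, value_mat_by_group,
                                  m_prime, median_ratio_min = 0.3,
                                  cv_max = 0.8, cv_pass_fraction_min = 0.5) {
  groups <- names(value_mat_by_group)
  med_ok <- FALSE
  for (g in groups) {
    vals <- value_mat_by_group[[g]][member_idx, , drop = FALSE]
    probe_means <- apply(vals, 1L, mean, na.rm = TRUE)
    if (median(probe_means, na.rm = TRUE) >= median_ratio_min) med_ok <- TRUE
  }
  med_m <- median(m_prime[member_idx])
  dir_ok <- if (direction == "hyper") med_m > 0 else -med_m > 0
  crit1 <- med_ok && dir_ok
  crit2 <- TRUE
  for (g in groups) {
    vals <- 2^value_mat_by_group[[g]][member_idx, , drop = FALSE]
    cvs <- apply(vals, 1L, function(v) sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
    if (mean(cvs <= cv_max, na.rm = TRUE) < cv_pass_fraction_min) crit2 <- FALSE
  }
  c(crit1 = crit1, crit2 = crit2, pass = crit1 && crit2)
}

# Exact hypergeometric upper tail by enumeration of the sampling
# distribution (valid for small N).
oracle_hypergeom_tail <- function(k, K, n, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Tiny probe table: one chromosome, evenly spaced probes, explicit values.
make_probe_table <- function(values_by_sample, spacing = 100L, probe_len = 60L,
                             chrom = "chr1") {
  np <- length(values_by_sample[[1L]])
  starts <- seq(1000L, by = spacing, length.out = np)
  df <- data.frame(probe_id = sprintf("p%03d", seq_len(np)),
                   chrom = chrom, start = starts, end = starts + probe_len,
                   stringsAsFactors = FALSE)
  for (s in names(values_by_sample)) df[[s]] <- values_by_sample[[s]]
  probe_table(df, names(values_by_sample))
}

# Standard 3+3 design over samples t1..t3 (treatment T) and c1..c3 (control C).
make_design <- function() {
  group_design(c("t1", "t2", "t3", "c1", "c2", "c3"),
               rep(c("T", "C"), each = 3L))
}

# Probe table with constant group means plus optional per-probe shifts.
make_two_group_table <- function(n_probes, mean_t = 0, mean_c = 0, noise_sd = 0,
                                 seed = 1L, spacing = 100L) {
  set.seed(seed)
  vals <- list()
  for (s in c("t1", "t2", "t3")) {
    vals[[s]] <- mean_t + rnorm(n_probes, 0, noise_sd)
  }
  for (s in c("c1", "c2", "c3")) {
    vals[[s]] <- mean_c + rnorm(n_probes, 0, noise_sd)
  }
  make_probe_table(vals, spacing = spacing)
}
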