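#' Peak-calling parameters
#'
#' Defaults follow the published procedure for NimbleGen-style promoter
#' tiling arrays: a peak needs at least two probes above a -log10 p-value
#' cutoff of 2 with at most 500 bp spacing between member probes. The probe
#' score is computed from a centered scoring window (750 bp by default)
#' compared against the whole-array distribution.
#'
#' @param min_probes minimum member probes per peak (>= 2).
#' @param score_cutoff probe score cutoff on the -log10 p scale; a probe
#'   with score >= cutoff counts as above (inclusive tie rule).
#' @param max_gap maximum midpoint-to-midpoint spacing (bp) between
#'   consecutive member probes.
#' @param scoring_window width (bp) of the centered window used to score
#'   each probe.
#' @param min_occupancy minimum number of probes the scoring window must
#'   contain for a score to be computed; sparser windows score 0.
#' @param test windowed test statistic: Mann-Whitney (rank-sum) or
#'   Kolmogorov-Smirnov, both one-sided against the array-wide distribution.
#' @return A `peak_call_params` list.
#' @export
peak_call_params <- function(min_probes = 2L, score_cutoff = 2, max_gap = 500,
                             scoring_window = 750, min_occupancy = 4L,
                             test = c("mwu", "ks")) {
  test <- match.arg(test)
  if (min_probes < 2L) stop("min_probes must be >= 2")
  if (max_gap <= 0) stop("max_gap must be positive")
  if (scoring_window <= 0) stop("scoring_window must be positive")
  structure(list(min_probes = as.integer(min_probes), score_cutoff = score_cutoff,
                 max_gap = max_gap, scoring_window = scoring_window,
                 min_occupancy = as.integer(min_occupancy), test = test),
            class = "peak_call_params")
}

#' Median-center log2 ratios per sample
#'
#' Normalizes each sample column of a probe table to median zero, the
#' scale-preserving robust centering applied before peak finding.
#'
#' @param table a [probe_table()].
#' @return The probe table with each sample column median-centered.
#' @export
normalize_log2_ratios <- function(table) {
  ids <- sample_ids(table)
  for (s in ids) {
    v <- table[[s]]
    if (all(is.na(v))) stop("sample '", s, "' has no non-missing values")
    table[[s]] <- v - stats::median(v, na.rm = TRUE)
  }
  table
}

# One-sided windowed score track. For each probe, the values of the probes
# whose midpoints fall within +/- window/2 on the same chromosome are
# compared against the all-array distribution, alternative "greater";
# the score is -log10 of that p-value. Windows holding fewer than
# `min_occupancy` probes (or a missing focal value) score 0.
#
# The rank-sum path is a rolling form of the two-sample normal
# approximation with tie correction and continuity correction, numerically
# identical to stats::wilcox.test(window, rest, alternative = "greater",
# exact = FALSE, correct = TRUE) but O(n log n) overall.
score_track <- function(chrom, pos, values, params) {
  n <- length(values)
  stopifnot(length(chrom) == n, length(pos) == n)
  scores <- numeric(n)
  ok <- is.finite(values)
  N <- sum(ok)
  if (N < 2L) return(scores)
  r <- rep(0, n)
  r[ok] <- rank(values[ok])
  tie_tab <- table(values[ok])
  tie_sum <- sum(tie_tab^3 - tie_tab)
  half <- params$scoring_window / 2
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(pos[idx])]
    p <- pos[idx]
    lo <- findInterval(p - half, p, left.open = TRUE) + 1L
    hi <- findInterval(p + half, p)
    cum_r <- c(0, cumsum(r[idx]))
    cum_n <- c(0, cumsum(as.numeric(ok[idx])))
    n1 <- cum_n[hi + 1L] - cum_n[lo]
    R1 <- cum_r[hi + 1L] - cum_r[lo]
    n2 <- N - n1
    if (params$test == "mwu") {
      mu <- n1 * n2 / 2
      sig2 <- n1 * n2 / 12 * ((N + 1) - tie_sum / (N * (N - 1)))
      U <- R1 - n1 * (n1 + 1) / 2
      z <- ifelse(sig2 > 0, (U - mu - 0.5) / sqrt(sig2), 0)
      logp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
      sc <- -logp / log(10)
    } else {
      sc <- vapply(seq_along(idx), function(j) {
        if (n1[j] < 1 || n2[j] < 1) return(0)
        win <- idx[lo[j]:hi[j]]
        x <- values[win][is.finite(values[win])]
        y <- values[setdiff(which(ok), win)]
        if (length(x) < 1L || length(y) < 1L) return(0)
        pv <- suppressWarnings(stats::ks.test(x, y, alternative = "less")$p.value)
        -log10(max(pv, .Machine$double.xmin))
      }, numeric(1L))
    }
    sc[n1 < params$min_occupancy | !ok[idx] | !is.finite(sc)] <- 0
    scores[idx] <- pmax(sc, 0)
  }
  scores
}

#' Score probes against the array-wide distribution
#'
#' Computes a per-probe enrichment score: -log10 of a one-sided test
#' comparing the probe's local scoring window (values averaged across the
#' selected samples) against the distribution over the whole array. Windows
#' with fewer than `params$min_occupancy` probes score 0.
#'
#' @param table a [probe_table()].
#' @param samples sample ids to average over (e.g. one group's replicates).
#' @param params a [peak_call_params()].
#' @return A score track: data.frame with `probe_id`, `chrom`, `position`
#'   (probe midpoint) and `score` (-log10 p, >= 0), aligned 1:1 with the
#'   probe table rows.
#' @export
score_probes <- function(table, samples = NULL, params = peak_call_params()) {
  if (!is.null(samples) && length(samples) == 0L) stop("empty sample subset")
  vals <- probe_values(table, samples)
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  pos <- probe_midpoints(table)
  data.frame(probe_id = table$probe_id, chrom = table$chrom, position = pos,
             score = score_track(table$chrom, pos, avg, params),
             stringsAsFactors = FALSE)
}

#' Sliding-window peak finding
#'
#' Identifies maximal runs of probes whose score meets the cutoff
#' (inclusive), where consecutive member probes lie on the same chromosome
#' at most `max_gap` apart (midpoint distance); runs with fewer than
#' `min_probes` members are discarded. A peak spans from the first member
#' probe's start to the last member probe's end and its score is the median
#' member score.
#'
#' @param track score track from [score_probes()]; needs `chrom`,
#'   `position`, `score` and optionally `probe_id`, `start`, `end` columns.
#'   If `start`/`end` are absent the probe position is used for both ends.
#' @param params a [peak_call_params()].
#' @return data.frame of peaks: `chrom`, `start`, `end`, `name`, `score`,
#'   `n_probes` and a list column `probe_idx` of member row indices into
#'   `track`.
#' @export
find_peaks <- function(track, params = peak_call_params()) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), n_probes = integer(),
                      stringsAsFactors = FALSE)
  empty$probe_idx <- list()
  if (nrow(track) == 0L) return(empty)
  if (is.null(track$start)) track$start <- track$position
  if (is.null(track$end)) track$end <- track$position
  cand <- which(track$score >= params$score_cutoff)
  if (length(cand) == 0L) return(empty)
  new_run <- c(TRUE, track$chrom[cand[-1L]] != track$chrom[cand[-length(cand)]] |
                 diff(track$position[cand]) > params$max_gap)
  run_id <- cumsum(new_run)
  runs <- split(cand, run_id)
  runs <- runs[vapply(runs, length, 1L) >= params$min_probes]
  if (length(runs) == 0L) return(empty)
  out <- data.frame(
    chrom = vapply(runs, function(i) track$chrom[i[1L]], ""),
    start = vapply(runs, function(i) min(track$start[i]), 0),
    end = vapply(runs, function(i) max(track$end[i]), 0),
    score = vapply(runs, function(i) stats::median(track$score[i]), 0),
    n_probes = vapply(runs, length, 1L),
    stringsAsFactors = FALSE)
  out$probe_idx <- unname(runs)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$name <- paste0("peak_", seq_len(nrow(out)))
  out[c("chrom", "start", "end", "name", "score", "n_probes", "probe_idx")]
}
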