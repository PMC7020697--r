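#' CpG classification thresholds
#'
#' The windowed CpG-island criteria used to split promoters into
#' high/intermediate/low CpG-density classes: a promoter is HCP when some
#' 500-bp window has CpG observed/expected ratio above `hcp_ratio` and GC
#' fraction above `hcp_gc`; LCP when no 500-bp window exceeds `lcp_ratio`;
#' ICP otherwise.
#'
#' @param hcp_ratio HCP observed/expected CpG ratio threshold (0.75).
#' @param hcp_gc HCP GC-fraction threshold (0.55).
#' @param lcp_ratio LCP observed/expected CpG ceiling (0.48).
#' @param window_len window length in bp (500).
#' @param step window step in bp (5).
#' @return A `cpg_class_thresholds` list.
#' @export
cpg_class_thresholds <- function(hcp_ratio = 0.75, hcp_gc = 0.55,
                                 lcp_ratio = 0.48, window_len = 500L, step = 5L) {
  structure(list(hcp_ratio = hcp_ratio, hcp_gc = hcp_gc, lcp_ratio = lcp_ratio,
                 window_len = as.integer(window_len), step = as.integer(step)),
            class = "cpg_class_thresholds")
}

#' Windowed GC and CpG observed/expected statistics
#'
#' Slides a window of `window_len` bp along the sequence at the given step
#' and reports, per window, the GC fraction and the CpG observed/expected
#' ratio (#CpG x L) / (#C x #G), defined as 0 when the denominator is 0.
#' CpG dinucleotides are counted at every position (standard dinucleotide
#' count). A sequence shorter than the window yields a single
#' whole-sequence window with a warning.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param window_len window length in bp (default 500).
#' @param step step between window starts in bp (default 5).
#' @return data.frame with `start` (0-based offset into the sequence),
#'   `gc_fraction` and `cpg_obs_exp`.
#' @export
window_stats <- function(sequence, window_len = 500L, step = 5L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence")
  if (n < window_len) {
    warning("sequence shorter than window (", n, " < ", window_len,
            "); using a single whole-sequence window")
    window_len <- n
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_cg <- c(is_c[-n] & is_g[-1L], FALSE)  # CG starting at each position
  cum_c <- c(0L, cumsum(is_c))
  cum_g <- c(0L, cumsum(is_g))
  cum_cg <- c(0L, cumsum(is_cg))
  starts <- seq.int(1L, n - window_len + 1L, by = step)
  ends <- starts + window_len - 1L
  rng <- function(cum, a, b) cum[b + 1L] - cum[a]
  n_c <- rng(cum_c, starts, ends)
  n_g <- rng(cum_g, starts, ends)
  # a CG straddling the window end is not inside the window
  n_cg <- rng(cum_cg, starts, pmax(starts, ends - 1L))
  denom <- n_c * n_g
  ratio <- ifelse(denom > 0, n_cg * window_len / denom, 0)
  data.frame(start = starts - 1L,
             gc_fraction = (n_c + n_g) / window_len,
             cpg_obs_exp = ratio)
}

#' Classify a promoter by windowed CpG density
#'
#' @param record a promoter record (needs a `sequence` field), or a plain
#'   DNA string.
#' @param thresholds a [cpg_class_thresholds()].
#' @return `"HCP"`, `"ICP"` or `"LCP"`; `NA` when the sequence is missing
#'   (such promoters are excluded from class shares).
#' @export
classify_promoter <- function(record, thresholds = cpg_class_thresholds()) {
  sequence <- if (is.character(record) && length(record) == 1L && is.null(names(record)))
    record else record[["sequence"]]
  if (is.null(sequence) || is.na(sequence) || !nzchar(sequence)) return(NA_character_)
  ws <- window_stats(sequence, thresholds$window_len, thresholds$step)
  if (any(ws$cpg_obs_exp > thresholds$hcp_ratio & ws$gc_fraction > thresholds$hcp_gc)) {
    "HCP"
  } else if (all(ws$cpg_obs_exp <= thresholds$lcp_ratio)) {
    "LCP"
  } else {
    "ICP"
  }
}

#' Classify many promoters
#'
#' @param promoters data.frame with `gene_id` and `sequence` columns (as
#'   from [read_fasta_promoters()]).
#' @param thresholds a [cpg_class_thresholds()].
#' @return The input with a `cpg_class` column added.
#' @export
classify_promoters <- function(promoters, thresholds = cpg_class_thresholds()) {
  promoters$cpg_class <- vapply(promoters$sequence, function(s) {
    classify_promoter(s, thresholds)
  }, character(1L), USE.NAMES = FALSE)
  promoters
}

#' HCP/ICP/LCP class shares
#'
#' @param assignments character vector of class labels (NA = unassigned,
#'   excluded).
#' @return data.frame with `cpg_class`, `count` and `percent` (2 decimals)
#'   over the classes HCP, ICP, LCP.
#' @export
class_shares <- function(assignments) {
  assignments <- assignments[!is.na(assignments)]
  if (length(assignments) == 0L) stop("no class assignments")
  bad <- setdiff(unique(assignments), c("HCP", "ICP", "LCP"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(c("HCP", "ICP", "LCP"), function(k) sum(assignments == k), 0L)
  data.frame(cpg_class = names(counts), count = as.integer(counts),
             percent = round(100 * counts / sum(counts), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
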