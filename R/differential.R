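#' Per-probe M' differential statistic
#'
#' For each probe, M' is the mean log2(MeDIP/Input) over the treatment
#' replicates minus the mean over the control replicates, so M' > 0 marks
#' hypermethylation in the treatment group. Probes with fewer than two
#' non-missing replicate values in either group get `NA` and are excluded
#' from differential peak membership downstream.
#'
#' @param table a [probe_table()].
#' @param design a [group_design()].
#' @param treatment treatment group label.
#' @param control control group label.
#' @return data.frame `probe_id`, `chrom`, `position`, `m_prime`, plus the
#'   per-group probe means `mean_<group>`.
#' @export
compute_m_prime <- function(table, design, treatment, control) {
  for (g in c(treatment, control)) {
    if (length(design_samples(design, g)) < 2L) {
      stop("group '", g, "' has fewer than 2 samples")
    }
  }
  vt <- probe_values(table, design_samples(design, treatment))
  vc <- probe_values(table, design_samples(design, control))
  nt <- rowSums(is.finite(vt))
  nc <- rowSums(is.finite(vc))
  mt <- rowMeans(vt, na.rm = TRUE)
  mc <- rowMeans(vc, na.rm = TRUE)
  m <- mt - mc
  m[nt < 2L | nc < 2L] <- NA_real_
  out <- data.frame(probe_id = table$probe_id, chrom = table$chrom,
                    position = probe_midpoints(table), m_prime = m,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", treatment)]] <- mt
  out[[paste0("mean_", control)]] <- mc
  out
}

#' Find differential enrichment peaks on the M' track
#'
#' Applies the windowed probe scoring and sliding-window peak finding to
#' the M' track (hyper direction) or its negation (hypo direction); probes
#' with missing M' never become members.
#'
#' @param mprime output of [compute_m_prime()].
#' @param table the [probe_table()] the track was computed on (supplies
#'   probe intervals for the peak span).
#' @param params a [peak_call_params()].
#' @param direction `"hyper"` (M' > 0 in treatment) or `"hypo"`.
#' @return Peaks as from [find_peaks()], with a `direction` column.
#' @export
find_differential_peaks <- function(mprime, table, params = peak_call_params(),
                                    direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  vals <- if (direction == "hyper") mprime$m_prime else -mprime$m_prime
  track <- data.frame(probe_id = mprime$probe_id, chrom = mprime$chrom,
                      position = mprime$position,
                      start = table$start, end = table$end,
                      score = score_track(mprime$chrom, mprime$position, vals, params),
                      stringsAsFactors = FALSE)
  peaks <- find_peaks(track, params)
  if (nrow(peaks)) peaks$direction <- direction else peaks$direction <- character()
  peaks
}

#' DEP filter parameters
#'
#' The two published criteria applied to candidate differential enrichment
#' peaks: (1) at least one group's median log2 MeDIP/Input over member
#' probes must reach `median_ratio_min` and the median M' over member
#' probes must exceed zero in the peak's own direction; (2) in both groups
#' at least `cv_pass_fraction_min` of member probes must have a replicate
#' coefficient of variation (on the linear ratio scale) at most `cv_max`.
#'
#' @param median_ratio_min minimum per-group median log2 MeDIP/Input (0.3).
#' @param cv_max maximum probe CV (0.8), CV = sd/mean of 2^(log2 ratio)
#'   across a group's replicates.
#' @param cv_pass_fraction_min fraction of member probes that must pass the
#'   CV rule in each group (0.5).
#' @return A `dep_filter_params` list.
#' @export
dep_filter_params <- function(median_ratio_min = 0.3, cv_max = 0.8,
                              cv_pass_fraction_min = 0.5) {
  if (!is.finite(median_ratio_min) || !is.finite(cv_max)) stop("thresholds must be finite")
  if (cv_pass_fraction_min < 0 || cv_pass_fraction_min > 1) {
    stop("cv_pass_fraction_min must be in [0, 1]")
  }
  structure(list(median_ratio_min = median_ratio_min, cv_max = cv_max,
                 cv_pass_fraction_min = cv_pass_fraction_min),
            class = "dep_filter_params")
}

# Per-probe per-group CV on the linear ratio scale across replicates.
probe_cv <- function(table, samples) {
  lin <- 2^probe_values(table, samples)
  m <- rowMeans(lin, na.rm = TRUE)
  s <- apply(lin, 1L, stats::sd, na.rm = TRUE)
  cv <- s / m
  cv[!is.finite(cv)] <- NA_real_
  cv
}

#' Filter candidate DEPs by the two-criterion rule
#'
#' Evaluates both filter criteria on every candidate peak and keeps the
#' peaks passing both; all summary quantities and per-criterion verdicts
#' are recorded so the verdict is reproducible from the returned table.
#'
#' @param peaks candidate peaks from [find_differential_peaks()] (their
#'   `probe_idx` indexes rows of `table`/`mprime`).
#' @param table the [probe_table()].
#' @param mprime output of [compute_m_prime()] on the same table.
#' @param design the [group_design()].
#' @param params a [dep_filter_params()].
#' @param keep_all if TRUE, return all candidates with verdict columns
#'   instead of only the passing ones.
#' @return data.frame of differential peaks with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `n_probes`, `direction`, `median_m`,
#'   `median_ratio_<group>`, `cv_pass_<group>`, `crit1`, `crit2`, `pass`,
#'   and the `probe_idx` list column.
#' @export
filter_deps <- function(peaks, table, mprime, design,
                        params = dep_filter_params(), keep_all = FALSE) {
  groups <- sort(unique(design$group))
  group_means <- lapply(groups, function(g) {
    rowMeans(probe_values(table, design_samples(design, g)), na.rm = TRUE)
  })
  names(group_means) <- groups
  group_cvs <- lapply(groups, function(g) probe_cv(table, design_samples(design, g)))
  names(group_cvs) <- groups
  n <- nrow(peaks)
  med_ratio <- matrix(NA_real_, n, length(groups), dimnames = list(NULL, groups))
  cv_pass <- matrix(NA_real_, n, length(groups), dimnames = list(NULL, groups))
  median_m <- numeric(n)
  crit1 <- logical(n)
  crit2 <- logical(n)
  for (i in seq_len(n)) {
    idx <- peaks$probe_idx[[i]]
    idx <- idx[is.finite(mprime$m_prime[idx])]
    if (length(idx) == 0L) {
      stop("peak '", peaks$name[i], "' has no resolvable member probes")
    }
    for (g in groups) {
      med_ratio[i, g] <- stats::median(group_means[[g]][idx], na.rm = TRUE)
      cv <- group_cvs[[g]][idx]
      cv_pass[i, g] <- if (all(is.na(cv))) 0 else mean(cv <= params$cv_max, na.rm = TRUE)
    }
    med_m <- stats::median(mprime$m_prime[idx])
    median_m[i] <- med_m
    dir_m <- if (peaks$direction[i] == "hyper") med_m else -med_m
    crit1[i] <- any(med_ratio[i, ] >= params$median_ratio_min) && dir_m > 0
    crit2[i] <- all(cv_pass[i, ] >= params$cv_pass_fraction_min)
  }
  out <- peaks
  out$median_m <- median_m
  for (g in groups) out[[paste0("median_ratio_", g)]] <- med_ratio[, g]
  for (g in groups) out[[paste0("cv_pass_", g)]] <- cv_pass[, g]
  out$crit1 <- crit1
  out$crit2 <- crit2
  out$pass <- crit1 & crit2
  if (!keep_all) {
    out <- out[out$pass, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out)) out$name <- paste0("dep_", seq_len(nrow(out)))
  }
  out
}

#' Hyper/hypo direction breakdown
#'
#' @param deps data.frame with a `direction` column, or a `medip_dmr` fit.
#' @return data.frame with `direction`, `count` and `percent` (percent of
#'   total, rounded to 2 decimals).
#' @export
summarize_directions <- function(deps) {
  if (inherits(deps, "medip_dmr")) deps <- deps$deps
  if (is.null(nrow(deps)) || nrow(deps) == 0L) stop("no differential peaks to summarize")
  counts <- c(hyper = sum(deps$direction == "hyper"),
              hypo = sum(deps$direction == "hypo"))
  data.frame(direction = names(counts), count = as.integer(counts),
             percent = round(100 * counts / sum(counts), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the differential-methylation model to a MeDIP tiling array
#'
#' The package's central fitting function. Starting from probe-level
#' log2(MeDIP/Input) ratios it (i) median-centers each sample,
#' (ii) computes the per-probe M' statistic (treatment mean minus control
#' mean), (iii) scores the M' track with the windowed one-sided rank test
#' in each direction and finds candidate peaks with the sliding-window
#' rule, and (iv) applies the two-criterion DEP filter. The result holds
#' the filtered differential peaks together with everything needed to
#' reproduce the verdicts.
#'
#' @param table a [probe_table()].
#' @param design a [group_design()].
#' @param treatment treatment group label (default "HF-inulin").
#' @param control control group label (default "HF").
#' @param peak_params a [peak_call_params()].
#' @param filter_params a [dep_filter_params()].
#' @param normalize median-center samples first (default TRUE).
#' @return An object of class `medip_dmr`: a list with elements `deps`
#'   (filtered differential peaks), `candidates` (all candidate peaks with
#'   verdicts), `mprime` (the M' track), `design`, `treatment`, `control`,
#'   `peak_params`, `filter_params`, `n_probes` and `call`.
#' @seealso [summary.medip_dmr()], [plot.medip_dmr()]
#' @export
medip_dmr <- function(table, design, treatment = "HF-inulin", control = "HF",
                      peak_params = peak_call_params(),
                      filter_params = dep_filter_params(),
                      normalize = TRUE) {
  cl <- match.call()
  if (normalize) table <- normalize_log2_ratios(table)
  mp <- compute_m_prime(table, design, treatment, control)
  cands <- lapply(c("hyper", "hypo"), function(d) {
    pk <- find_differential_peaks(mp, table, peak_params, d)
    if (nrow(pk) == 0L) return(NULL)
    filter_deps(pk, table, mp, design, filter_params, keep_all = TRUE)
  })
  cands <- do.call(rbind, cands[!vapply(cands, is.null, TRUE)])
  if (is.null(cands)) {
    cands <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        name = character(), score = numeric(),
                        n_probes = integer(), direction = character(),
                        median_m = numeric(), crit1 = logical(),
                        crit2 = logical(), pass = logical(),
                        stringsAsFactors = FALSE)
    cands$probe_idx <- list()
  }
  deps <- cands[cands$pass, , drop = FALSE]
  deps <- deps[order(deps$chrom, deps$start), , drop = FALSE]
  rownames(deps) <- NULL
  if (nrow(deps)) deps$name <- paste0("dep_", seq_len(nrow(deps)))
  structure(list(deps = deps, candidates = cands, mprime = mp, design = design,
                 treatment = treatment, control = control,
                 peak_params = peak_params, filter_params = filter_params,
                 n_probes = nrow(table), call = cl),
            class = "medip_dmr")
}

#' @export
print.medip_dmr <- function(x, ...) {
  cat("MeDIP differential methylation fit\n")
  cat("  contrast: ", x$treatment, " vs ", x$control, "\n", sep = "")
  cat("  probes:   ", x$n_probes, "\n", sep = "")
  cat("  candidate peaks: ", nrow(x$candidates),
      "; DEPs after filtering: ", nrow(x$deps), "\n", sep = "")
  if (nrow(x$deps)) {
    print(summarize_directions(x))
  }
  invisible(x)
}

#' Summarize a differential-methylation fit
#'
#' @param object a `medip_dmr` fit.
#' @param ... unused.
#' @return A `summary.medip_dmr` list with the direction breakdown,
#'   chromosome distribution and filter parameters.
#' @export
summary.medip_dmr <- function(object, ...) {
  s <- list(contrast = c(treatment = object$treatment, control = object$control),
            n_probes = object$n_probes,
            n_candidates = nrow(object$candidates),
            n_deps = nrow(object$deps),
            directions = if (nrow(object$deps)) summarize_directions(object) else NULL,
            chromosomes = if (nrow(object$deps)) chromosome_distribution(object$deps) else NULL,
            filter_params = object$filter_params)
  class(s) <- "summary.medip_dmr"
  s
}

#' @export
print.summary.medip_dmr <- function(x, ...) {
  cat("Contrast:", x$contrast[["treatment"]], "vs", x$contrast[["control"]], "\n")
  cat("Probes:", x$n_probes, " Candidates:", x$n_candidates,
      " DEPs:", x$n_deps, "\n")
  if (!is.null(x$directions)) {
    cat("\nDirection breakdown:\n"); print(x$directions)
  }
  if (!is.null(x$chromosomes)) {
    cat("\nChromosome distribution:\n"); print(x$chromosomes)
  }
  invisible(x)
}

#' @export
as.data.frame.medip_dmr <- function(x, ...) {
  df <- x$deps
  df$probe_idx <- NULL
  df
}

#' Plot the M' track of a fit
#'
#' Draws per-probe M' along one chromosome with the filtered DEP intervals
#' shaded (hyper above, hypo below the zero line).
#'
#' @param x a `medip_dmr` fit.
#' @param chrom chromosome to draw (default: first with a DEP, else first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.medip_dmr <- function(x, chrom = NULL, ...) {
  if (is.null(chrom)) {
    chrom <- if (nrow(x$deps)) x$deps$chrom[1L] else x$mprime$chrom[1L]
  }
  mp <- x$mprime[x$mprime$chrom == chrom, ]
  graphics::plot(mp$position, mp$m_prime, pch = 16, cex = 0.4,
                 xlab = paste0("position on ", chrom, " (bp)"),
                 ylab = "M' (log2)", ...)
  graphics::abline(h = 0, col = "grey60")
  d <- x$deps[x$deps$chrom == chrom, ]
  if (nrow(d)) {
    cols <- ifelse(d$direction == "hyper", "#d73027", "#1a9850")
    graphics::rect(d$start, ifelse(d$direction == "hyper", 0, -10),
                   d$end, ifelse(d$direction == "hyper", 10, 0),
                   col = grDevices::adjustcolor(cols, alpha.f = 0.2), border = NA)
  }
  invisible(x)
}

#' Evaluate DMR calls against a planted truth set
#'
#' Matches called differential peaks to planted truth intervals by >= 1 bp
#' overlap on the same chromosome with the same direction. Sensitivity is
#' the fraction of truth intervals hit by at least one call; precision is
#' the fraction of calls hitting at least one truth interval.
#'
#' @param deps data.frame of calls (`chrom`, `start`, `end`, `direction`)
#'   or a `medip_dmr` fit.
#' @param truth data.frame of planted intervals with the same columns.
#' @return list with `sensitivity`, `precision`, `n_called`, `n_truth`,
#'   `n_true_positive_calls`, `n_truth_recovered`.
#' @export
evaluate_dmr_calls <- function(deps, truth) {
  if (inherits(deps, "medip_dmr")) deps <- deps$deps
  overlap_any <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & b$direction == a$direction[i] &
            b$start < a$end[i] & b$end > a$start[i])
    }, logical(1L))
  }
  hit_truth <- if (nrow(truth)) overlap_any(truth, deps) else logical(0)
  hit_call <- if (nrow(deps)) overlap_any(deps, truth) else logical(0)
  list(sensitivity = if (nrow(truth)) mean(hit_truth) else NA_real_,
       precision = if (nrow(deps)) mean(hit_call) else NA_real_,
       n_called = nrow(deps), n_truth = nrow(truth),
       n_true_positive_calls = sum(hit_call),
       n_truth_recovered = sum(hit_truth))
}
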