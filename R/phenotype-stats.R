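#' Oral glucose tolerance test AUC
#'
#' Trapezoidal area under the glucose-time curve over the full measured
#' span (mmol/L x min). The incremental area above the fasting baseline is
#' also returned; the total area is the conventional default.
#'
#' @param times sampling times in minutes, strictly increasing from 0.
#' @param glucose glucose concentrations (mmol/L), same length as `times`.
#' @return list with `auc` (total trapezoidal area), `auc_incremental`
#'   (area above the minute-0 baseline, negative excursions clipped per
#'   interval endpoint), `times` and `glucose` echoes.
#' @export
ogtt_auc <- function(times, glucose) {
  if (length(times) != length(glucose)) stop("times and glucose lengths differ")
  if (length(times) < 2L) stop("need at least two time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(glucose < 0)) stop("glucose must be >= 0")
  dt <- diff(times)
  auc <- sum(dt * (glucose[-1L] + glucose[-length(glucose)]) / 2)
  above <- pmax(glucose - glucose[1L], 0)
  auc_inc <- sum(dt * (above[-1L] + above[-length(above)]) / 2)
  list(auc = auc, auc_incremental = auc_inc, times = times, glucose = glucose)
}

#' HOMA-IR insulin-resistance index
#'
#' (fasting insulin x fasting glucose) / 22.5. Units are taken as given;
#' the index is symmetric in its two arguments and scales linearly in each.
#'
#' @param fasting_insulin fasting insulin (>= 0).
#' @param fasting_glucose fasting glucose (>= 0).
#' @return Numeric HOMA-IR value(s).
#' @export
homa_ir <- function(fasting_insulin, fasting_glucose) {
  if (any(fasting_insulin < 0) || any(fasting_glucose < 0)) {
    stop("HOMA-IR inputs must be >= 0")
  }
  fasting_insulin * fasting_glucose / 22.5
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change per sample relative to a calibrator group, normalized to a
#' reference gene: dCt = Ct_target - Ct_reference, ddCt = dCt - mean dCt of
#' the calibrator group, fold = 2^(-ddCt). Amplification efficiency is
#' assumed 100% (doubling per cycle); `base` makes it configurable.
#'
#' @param ct_target target-gene Ct values.
#' @param ct_reference reference-gene (e.g. Gapdh) Ct values, parallel.
#' @param group group label per sample.
#' @param calibrator_group label of the calibrator group (default "CON").
#' @param base amplification base (default 2).
#' @return data.frame with `group`, `d_ct`, `dd_ct`, `fold_change`.
#' @export
relative_expression <- function(ct_target, ct_reference, group,
                                calibrator_group = "CON", base = 2) {
  if (length(ct_target) != length(ct_reference) ||
      length(ct_target) != length(group)) stop("input lengths differ")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  if (!calibrator_group %in% group) {
    stop("calibrator group '", calibrator_group, "' not present")
  }
  d_ct <- ct_target - ct_reference
  dd_ct <- d_ct - mean(d_ct[group == calibrator_group])
  data.frame(group = group, d_ct = d_ct, dd_ct = dd_ct,
             fold_change = base^(-dd_ct), stringsAsFactors = FALSE)
}

#' Compare an endpoint across groups
#'
#' Two groups are compared with Student's t-test; three or more with
#' one-way ANOVA followed by Tukey's HSD post hoc test. Group summaries are
#' reported as mean +/- SEM.
#'
#' @param values numeric endpoint per animal.
#' @param group group label per animal (>= 2 animals per group).
#' @param var_equal for the two-group case, assume equal variances
#'   (classic Student's t-test; default TRUE).
#' @return list with `method`, `group_means` (group, n, mean, sem),
#'   `statistic`, `p_value`, and for >= 3 groups a `tukey` data.frame of
#'   pairwise adjusted p-values.
#' @export
group_compare <- function(values, group, var_equal = TRUE) {
  if (length(values) != length(group)) stop("values and group lengths differ")
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group)[keep]
  tab <- table(group)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("group '", names(tab)[which.min(tab)], "' has fewer than 2 values")
  }
  gm <- do.call(rbind, lapply(names(tab), function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  if (length(tab) == 2L) {
    tt <- stats::t.test(values ~ group, var.equal = var_equal)
    list(method = "t-test", group_means = gm,
         statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    df <- data.frame(values = values, group = factor(group))
    fit <- stats::aov(values ~ group, data = df)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$group
    list(method = "anova+tukey", group_means = gm,
         statistic = an[["F value"]][1L], p_value = an[["Pr(>F)"]][1L],
         tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                            lwr = tk[, "lwr"], upr = tk[, "upr"],
                            p_adjusted = tk[, "p adj"], row.names = NULL,
                            stringsAsFactors = FALSE))
  }
}

#' Metabolic endpoint summary of a phenotype table
#'
#' Computes per-animal OGTT AUC and HOMA-IR and compares body weight,
#' fasting glucose, fasting insulin, AUC and HOMA-IR across groups with
#' [group_compare()].
#'
#' @param phenotypes a table from [read_phenotypes()] or
#'   [simulate_phenotypes()].
#' @return list with `per_animal` (the table plus `ogtt_auc` and `homa_ir`
#'   columns) and `comparisons` (named list of [group_compare()] results).
#' @export
phenotype_summary <- function(phenotypes) {
  times <- attr(phenotypes, "glucose_times")
  gcols <- attr(phenotypes, "glucose_cols")
  if (is.null(times) || is.null(gcols)) stop("phenotype table lacks glucose metadata")
  g <- as.matrix(phenotypes[gcols])
  phenotypes$ogtt_auc <- vapply(seq_len(nrow(g)), function(i) {
    ogtt_auc(times, g[i, ])$auc
  }, numeric(1L))
  phenotypes$homa_ir <- homa_ir(phenotypes$fasting_insulin, g[, 1L])
  endpoints <- c(body_weight = "body_weight", fasting_glucose = gcols[1L],
                 fasting_insulin = "fasting_insulin",
                 ogtt_auc = "ogtt_auc", homa_ir = "homa_ir")
  comparisons <- lapply(endpoints, function(col) {
    group_compare(phenotypes[[col]], phenotypes$group)
  })
  list(per_animal = phenotypes, comparisons = comparisons)
}
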