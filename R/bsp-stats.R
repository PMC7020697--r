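#' Methylation ratios of a bisulfite clone matrix
#'
#' The overall methylation ratio is methylated calls / total non-missing
#' calls over the whole clones x CpG-sites matrix; per-site ratios use the
#' non-missing calls of each CpG column. The overall ratio equals the mean
#' of the per-site ratios weighted by their non-missing call counts.
#'
#' @param matrix a [bisulfite_clone_matrix()].
#' @return list with `animal_id`, `group`, `amplicon_id`, `n_clones`,
#'   `n_sites`, `per_site` (named numeric) and `overall`.
#' @export
methylation_ratio <- function(matrix) {
  calls <- matrix$calls
  if (all(is.na(calls))) stop("clone matrix for animal '", matrix$animal_id,
                              "' has no non-missing calls")
  per_site <- colMeans(calls, na.rm = TRUE)
  list(animal_id = matrix$animal_id, group = matrix$group,
       amplicon_id = matrix$amplicon_id,
       n_clones = nrow(calls), n_sites = ncol(calls),
       per_site = per_site,
       overall = mean(calls, na.rm = TRUE))
}

#' Summarize clone matrices to a per-animal table
#'
#' @param matrices list of [bisulfite_clone_matrix()] objects.
#' @return data.frame with one row per matrix: `animal_id`, `group`,
#'   `amplicon_id`, `n_clones`, `n_sites`, `overall_ratio`.
#' @export
summarize_clone_matrices <- function(matrices) {
  rows <- lapply(matrices, function(m) {
    r <- methylation_ratio(m)
    data.frame(animal_id = r$animal_id, group = r$group,
               amplicon_id = r$amplicon_id, n_clones = r$n_clones,
               n_sites = r$n_sites, overall_ratio = r$overall,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare group methylation by one-way ANOVA with Tukey's post hoc test
#'
#' The unit of analysis is the animal (its overall clone-level ratio), not
#' the clone, avoiding pseudoreplication. Each amplicon is tested
#' separately: one-way ANOVA across the groups followed by Tukey's HSD for
#' the pairwise contrasts with family-wise adjusted p-values.
#'
#' @param summaries per-animal table from [summarize_clone_matrices()] (or
#'   any data.frame with `amplicon_id`, `group`, `overall_ratio`).
#' @return list, one element per amplicon, each with `f_statistic`,
#'   `p_value`, `group_means` (mean, sem, n per group) and `tukey`
#'   (data.frame of pairwise comparisons with adjusted p).
#' @export
compare_groups_methylation <- function(summaries) {
  lapply(split(summaries, summaries$amplicon_id), function(df) {
    tab <- table(df$group)
    if (any(tab < 2L)) {
      stop("group '", names(tab)[which.min(tab)], "' has fewer than 2 animals")
    }
    df$group <- factor(df$group)
    fit <- stats::aov(overall_ratio ~ group, data = df)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$group
    means <- do.call(rbind, lapply(levels(df$group), function(g) {
      v <- df$overall_ratio[df$group == g]
      data.frame(group = g, n = length(v), mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
    }))
    list(amplicon_id = df$amplicon_id[1L],
         f_statistic = an[["F value"]][1L],
         p_value = an[["Pr(>F)"]][1L],
         group_means = means,
         tukey = data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adjusted = tk[, "p adj"],
                            row.names = NULL, stringsAsFactors = FALSE))
  })
}
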