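#' Map differential peaks to promoters and genes
#'
#' Assigns each DEP to every promoter whose window it overlaps by at least
#' 1 bp (0-based half-open intervals on the same chromosome); a DEP
#' spanning two divergent promoters gets both genes. Unmapped DEPs are
#' retained and flagged.
#'
#' @param deps data.frame of differential peaks (`chrom`, `start`, `end`)
#'   or a `medip_dmr` fit.
#' @param promoters promoter annotation with `gene_id`, `chrom`,
#'   `win_start`, `win_end`.
#' @return list with `deps` (input plus `gene_ids` list column and `mapped`
#'   flag), `genes` (deduplicated gene ids), and `counts` (n_deps,
#'   n_annotated_genes, n_chromosomes).
#' @export
map_deps_to_genes <- function(deps, promoters) {
  if (inherits(deps, "medip_dmr")) deps <- deps$deps
  if (nrow(deps) == 0L) {
    deps$gene_ids <- list()
    deps$mapped <- logical(0)
    return(list(deps = deps, genes = character(0),
                counts = c(n_deps = 0L, n_annotated_genes = 0L, n_chromosomes = 0L)))
  }
  chroms <- union(unique(deps$chrom), unique(promoters$chrom))
  dep_gr <- GenomicRanges::GRanges(
    factor(deps$chrom, levels = chroms),
    IRanges::IRanges(start = deps$start + 1L, end = deps$end))
  prom_gr <- GenomicRanges::GRanges(
    factor(promoters$chrom, levels = chroms),
    IRanges::IRanges(start = promoters$win_start + 1L, end = promoters$win_end))
  hits <- GenomicRanges::findOverlaps(dep_gr, prom_gr)
  gene_ids <- rep(list(character(0)), nrow(deps))
  by_dep <- split(promoters$gene_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
  for (k in names(by_dep)) gene_ids[[as.integer(k)]] <- sort(unique(by_dep[[k]]))
  deps$gene_ids <- gene_ids
  deps$mapped <- lengths(gene_ids) > 0L
  genes <- sort(unique(unlist(gene_ids, use.names = FALSE)))
  list(deps = deps, genes = genes,
       counts = c(n_deps = nrow(deps),
                  n_annotated_genes = length(genes),
                  n_chromosomes = length(unique(deps$chrom))))
}

#' Chromosome distribution of differential peaks
#'
#' @param deps data.frame with `chrom` and `direction` columns, or a
#'   `medip_dmr` fit.
#' @return data.frame with `chrom`, `hyper`, `hypo` and `total` counts;
#'   totals sum to the number of peaks. Empty input gives an empty table.
#' @export
chromosome_distribution <- function(deps) {
  if (inherits(deps, "medip_dmr")) deps <- deps$deps
  if (nrow(deps) == 0L) {
    return(data.frame(chrom = character(), hyper = integer(), hypo = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  chroms <- unique(deps$chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", chroms)))
  chroms <- chroms[order(is.na(num), num, chroms)]
  hyper <- vapply(chroms, function(c) sum(deps$chrom == c & deps$direction == "hyper"), 0L)
  hypo <- vapply(chroms, function(c) sum(deps$chrom == c & deps$direction == "hypo"), 0L)
  data.frame(chrom = chroms, hyper = as.integer(hyper), hypo = as.integer(hypo),
             total = as.integer(hyper + hypo), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure: with p-values sorted ascending,
#' q_i = min over j >= i of (p_j * m / j), capped at 1 and returned in the
#' input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues, decreasing = TRUE)   # largest first
  ranked <- pvalues[ord] * m / seq.int(m, 1L)
  adj <- pmin(1, cummin(ranked))
  adj[order(ord)]
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the study genes over-represent the set
#' relative to the universe using the upper-tail hypergeometric p-value
#' P(X >= k), then adjusts across sets with [bh_adjust()]. Significance is
#' flagged at adjusted p < 0.01 (the GO-style cutoff) and < 0.05 (the
#' KEGG-style cutoff).
#'
#' @param study_genes character vector of study (e.g. differentially
#'   methylated) gene ids; genes outside the universe are dropped with a
#'   warning.
#' @param sets a [gene_set_collection()].
#' @return data.frame sorted by adjusted p: `set_id`, `description`, `k`
#'   (overlap), `K` (set size), `n` (study size), `N` (universe size),
#'   `p_value`, `p_adjusted`, `sig_0.01`, `sig_0.05`.
#' @export
hypergeom_ora <- function(study_genes, sets) {
  study_genes <- unique(as.character(study_genes))
  if (length(study_genes) == 0L) stop("empty study gene list")
  outside <- setdiff(study_genes, sets$universe)
  if (length(outside)) {
    warning(length(outside), " study gene(s) outside the universe dropped")
    study_genes <- intersect(study_genes, sets$universe)
    if (length(study_genes) == 0L) stop("no study genes left after restriction")
  }
  N <- length(sets$universe)
  n <- length(study_genes)
  res <- lapply(names(sets$sets), function(id) {
    members <- sets$sets[[id]]
    K <- length(members)
    k <- length(intersect(study_genes, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, description = unname(sets$descriptions[id]),
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$sig_0.01 <- out$p_adjusted < 0.01
  out$sig_0.05 <- out$p_adjusted < 0.05
  out <- out[order(out$p_adjusted, out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
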