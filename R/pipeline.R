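#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain inputs (simulated from a seeded
#' config, or read from files), fit the differential-methylation model,
#' classify host promoters by CpG density, annotate DEPs to genes, run the
#' gene-set over-representation, and compute the bisulfite-clone and
#' phenotype validation statistics. Writes per-stage outputs (BED/TSV) and
#' a JSON report whose numbers are all recomputable from those outputs.
#' All referenced input files are checked before any stage runs.
#'
#' @param config a named list or a path to a JSON file with (all optional):
#'   `seed` (integer, default 1), `simulation` (overrides for
#'   [simulation_config()]), `peak_params` / `filter_params` overrides,
#'   `inputs` (paths: `probes`, `design`, `promoters_fasta`,
#'   `promoters_annotation`, `gmt`, `clones`, `phenotypes` — any missing
#'   input is simulated instead), `treatment`, `control`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the report list (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (missing(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # validation-first: every referenced input must exist before any stage runs
  inputs <- config$inputs
  for (nm in names(inputs)) {
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      stop("input file for '", nm, "' not found: ", inputs[[nm]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim_args <- config$simulation
  if (is.null(sim_args)) sim_args <- list()
  sim_args$seed <- seed
  sim_cfg <- do.call(simulation_config, sim_args)
  treatment <- if (!is.null(config$treatment)) config$treatment else sim_cfg$treatment
  control <- if (!is.null(config$control)) config$control else sim_cfg$control

  # --- stage: array data ---------------------------------------------------
  truth <- NULL
  if (!is.null(inputs$probes)) {
    probes <- read_probe_table(inputs$probes)
    if (is.null(inputs$design)) stop("inputs$design is required with inputs$probes")
    ddf <- utils::read.delim(inputs$design, stringsAsFactors = FALSE)
    design <- group_design(ddf$sample_id, ddf$group)
  } else {
    arr <- simulate_probe_array(sim_cfg)
    probes <- arr$probes
    design <- arr$design
    truth <- arr$truth
    write_probe_table(probes, file.path(out_dir, "probes.tsv"))
    write_bed(data.frame(chrom = truth$chrom, start = truth$start,
                         end = truth$end,
                         name = paste0(truth$gene_id, "_", truth$direction),
                         score = 0, stringsAsFactors = FALSE),
              file.path(out_dir, "truth_dmrs.bed"))
  }

  # --- stage: promoter sequences and classes -------------------------------
  if (!is.null(inputs$promoters_fasta)) {
    if (is.null(inputs$promoters_annotation)) {
      stop("inputs$promoters_annotation is required with inputs$promoters_fasta")
    }
    promoters <- read_fasta_promoters(inputs$promoters_fasta,
                                      inputs$promoters_annotation)
  } else {
    promoters <- simulate_promoter_sequences(sim_cfg)$promoters
  }
  promoters <- classify_promoters(promoters)
  utils::write.table(promoters[setdiff(names(promoters), "sequence")],
                     file.path(out_dir, "promoter_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: differential methylation -------------------------------------
  fit <- medip_dmr(probes, design, treatment, control,
                   peak_params = do.call(peak_call_params,
                                         as.list(config$peak_params)),
                   filter_params = do.call(dep_filter_params,
                                           as.list(config$filter_params)))
  deps <- fit$deps
  write_bed(deps, file.path(out_dir, "deps.bed"))

  # --- stage: annotation ---------------------------------------------------
  ann <- map_deps_to_genes(fit, promoters)
  dir_summary <- if (nrow(deps)) summarize_directions(fit) else NULL
  chrom_dist <- chromosome_distribution(deps)
  dep_classes <- if (nrow(deps)) {
    cls <- promoters$cpg_class[match(
      vapply(ann$deps$gene_ids, function(g) if (length(g)) g[1L] else NA_character_,
             character(1L)),
      promoters$gene_id)]
    cls
  } else character(0)
  class_summary <- if (length(dep_classes[!is.na(dep_classes)])) {
    class_shares(dep_classes)
  } else NULL
  utils::write.table(chrom_dist, file.path(out_dir, "chromosome_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: enrichment ---------------------------------------------------
  universe <- promoters$gene_id
  gsc <- if (!is.null(inputs$gmt)) {
    read_gmt(inputs$gmt, universe = universe)
  } else {
    simulate_gene_sets(universe, study = ann$genes, seed = seed)
  }
  enrichment <- if (length(ann$genes)) hypergeom_ora(ann$genes, gsc) else NULL
  if (!is.null(enrichment)) {
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: bisulfite validation -----------------------------------------
  clones <- if (!is.null(inputs$clones)) {
    read_clone_tsv(inputs$clones)
  } else {
    amplicons <- list(Wnt5a = list(n_cpgs = 6L,
                                   p = c(CON = 0.6, HF = 0.25, `HF-inulin` = 0.5)),
                      Pik3c2a = list(n_cpgs = 22L,
                                     p = c(CON = 0.2, HF = 0.6, `HF-inulin` = 0.3)),
                      Pik3c2b = list(n_cpgs = 9L,
                                     p = c(CON = 0.2, HF = 0.6, `HF-inulin` = 0.3)),
                      Pik3r2 = list(n_cpgs = 31L,
                                    p = c(CON = 0.2, HF = 0.6, `HF-inulin` = 0.3)))
    sims <- lapply(seq_along(amplicons), function(i) {
      simulate_clone_matrices(amplicons[[i]]$p, n_cpgs = amplicons[[i]]$n_cpgs,
                              amplicon_id = names(amplicons)[i],
                              seed = seed + i)$matrices
    })
    unlist(sims, recursive = FALSE)
  }
  bsp_table <- summarize_clone_matrices(clones)
  utils::write.table(bsp_table, file.path(out_dir, "bsp_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bsp_tests <- compare_groups_methylation(bsp_table)

  # --- stage: phenotypes ---------------------------------------------------
  phen <- if (!is.null(inputs$phenotypes)) {
    read_phenotypes(inputs$phenotypes)
  } else {
    simulate_phenotypes(seed = seed + 100L)
  }
  phen_summary <- phenotype_summary(phen)
  utils::write.table(phen_summary$per_animal,
                     file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- report --------------------------------------------------------------
  report <- list(
    dmrs = list(n_deps = unname(ann$counts["n_deps"]),
                n_annotated_genes = unname(ann$counts["n_annotated_genes"]),
                n_chromosomes = unname(ann$counts["n_chromosomes"])),
    directions = dir_summary,
    cpg_classes = class_summary,
    chromosomes = chrom_dist,
    enrichment = if (!is.null(enrichment)) {
      utils::head(enrichment[c("set_id", "k", "K", "p_value", "p_adjusted",
                               "sig_0.05")], 10L)
    } else NULL,
    bsp = lapply(bsp_tests, function(x) {
      list(amplicon = x$amplicon_id, f = x$f_statistic, p = x$p_value,
           means = x$group_means)
    }),
    phenotypes = lapply(phen_summary$comparisons, function(x) {
      list(method = x$method, p = x$p_value, means = x$group_means)
    }),
    parameters = list(seed = seed, treatment = treatment, control = control,
                      n_probes = nrow(probes),
                      simulated_array = is.null(inputs$probes))
  )
  if (!is.null(truth)) {
    report$recovery <- evaluate_dmr_calls(fit, truth)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
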