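#' Simulation configuration for a promoter tiling array
#'
#' Defines the study conditions the generator emulates: a promoter tiling
#' array at desk scale (default 500 promoters vs the tens of thousands on a
#' commercial design), two groups of three biological replicates
#' (treatment "HF-inulin" vs control "HF"), 60-bp probes at 100-bp
#' center-to-center spacing across a \[-1300, +500) window around each TSS,
#' i.i.d. Gaussian probe noise on the log2 scale, and planted hyper- and
#' hypomethylated DMRs as contiguous blocks of probes. Promoter CpG class
#' is drawn from `cpg_class_mix`; LCP promoters carry the constitutively
#' methylated baseline and HCP/ICP the unmethylated baseline, so
#' hypomethylation is planted in methylated (LCP) promoters and
#' hypermethylation in unmethylated ones.
#'
#' @param n_promoters number of promoters on the simulated array.
#' @param promoter_window c(upstream, downstream) window around the TSS in
#'   bp, 0-based half-open relative interval.
#' @param probe_spacing center-to-center probe spacing (bp).
#' @param probe_length probe length (bp).
#' @param n_replicates_per_group biological replicates per group.
#' @param baseline_log2ratio_mean named c(unmethylated=, methylated=)
#'   baseline mean log2(MeDIP/Input) per promoter methylation state.
#' @param effect_size log2 units added (hyper) or subtracted (hypo) in the
#'   treatment group over planted DMR probes.
#' @param probe_noise_sd Gaussian noise sd on log2 ratios, per probe per
#'   sample.
#' @param probe_cv_range optional c(lo, hi): instead of a common noise sd,
#'   draw each probe a target replicate CV on the linear ratio scale
#'   uniformly from this range and use the corresponding per-probe log2
#'   noise sd (sd = sqrt(log(1 + CV^2)) / log 2).
#' @param fraction_hyper,fraction_hypo fractions of promoters carrying a
#'   planted hyper-/hypomethylated DMR.
#' @param dmr_probes number of consecutive probes in a planted DMR block.
#' @param cpg_class_mix named proportions of HCP/ICP/LCP promoters.
#' @param treatment,control group labels.
#' @param seed integer seed; mandatory for reproducibility.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_promoters = 500L,
                              promoter_window = c(-1300L, 500L),
                              probe_spacing = 100L,
                              probe_length = 60L,
                              n_replicates_per_group = 3L,
                              baseline_log2ratio_mean = c(unmethylated = 0,
                                                          methylated = 1),
                              effect_size = 1,
                              probe_noise_sd = 0.3,
                              probe_cv_range = NULL,
                              fraction_hyper = 0.04,
                              fraction_hypo = 0.04,
                              dmr_probes = 8L,
                              cpg_class_mix = c(HCP = 0.5, ICP = 0.25, LCP = 0.25),
                              treatment = "HF-inulin",
                              control = "HF",
                              seed = 1L) {
  if (is.null(seed) || !is.finite(seed)) stop("seed is mandatory")
  if (probe_spacing < 1L) stop("probe_spacing must be >= 1")
  win_len <- promoter_window[2L] - promoter_window[1L]
  n_probes <- (win_len - probe_length) %/% probe_spacing + 1L
  if (win_len < probe_length || n_probes < 1L) {
    stop("promoter window admits zero probes")
  }
  fr <- c(fraction_hyper, fraction_hypo)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("fraction_hyper/fraction_hypo must be in [0,1] and sum to <= 1")
  }
  if (any(cpg_class_mix < 0) || abs(sum(cpg_class_mix) - 1) > 1e-8) {
    stop("cpg_class_mix must be nonnegative proportions summing to 1")
  }
  if (!all(c("HCP", "ICP", "LCP") %in% names(cpg_class_mix))) {
    stop("cpg_class_mix needs HCP, ICP and LCP entries")
  }
  if (!all(c("unmethylated", "methylated") %in% names(baseline_log2ratio_mean))) {
    stop("baseline_log2ratio_mean needs 'unmethylated' and 'methylated'")
  }
  structure(list(n_promoters = as.integer(n_promoters),
                 promoter_window = as.integer(promoter_window),
                 probe_spacing = as.integer(probe_spacing),
                 probe_length = as.integer(probe_length),
                 n_probes_per_promoter = as.integer(n_probes),
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 baseline_log2ratio_mean = baseline_log2ratio_mean,
                 effect_size = effect_size,
                 probe_noise_sd = probe_noise_sd,
                 probe_cv_range = probe_cv_range,
                 fraction_hyper = fraction_hyper,
                 fraction_hypo = fraction_hypo,
                 dmr_probes = as.integer(dmr_probes),
                 cpg_class_mix = cpg_class_mix,
                 treatment = treatment, control = control,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Largest-remainder apportionment of n into proportions p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic promoter layout plus seeded class/state/DMR assignment.
# Both the array and the sequence generators call this, so their views of
# promoter classes, methylation states and planted DMR hosts agree for a
# given config.
assign_promoters <- function(config) {
  n <- config$n_promoters
  n_chrom <- 19L
  idx <- seq_len(n) - 1L
  chrom <- paste0("chr", idx %% n_chrom + 1L)
  slot <- idx %/% n_chrom
  tss <- 100000L + slot * 10000L
  strand <- ifelse(idx %% 2L == 0L, "+", "-")
  win <- config$promoter_window
  win_start <- ifelse(strand == "+", tss + win[1L], tss - win[2L] + 1L)
  win_end <- win_start + (win[2L] - win[1L])
  gene_id <- sprintf("g%04d", seq_len(n))

  set.seed(config$seed)
  counts <- apportion(n, config$cpg_class_mix[c("HCP", "ICP", "LCP")])
  cpg_class <- sample(rep(c("HCP", "ICP", "LCP"), counts))
  state <- ifelse(cpg_class == "LCP", "methylated", "unmethylated")
  n_hyper <- round(config$fraction_hyper * n)
  n_hypo <- round(config$fraction_hypo * n)
  if (n_hyper > sum(state == "unmethylated")) stop("too few unmethylated promoters for hyper DMRs")
  if (n_hypo > sum(state == "methylated")) stop("too few methylated promoters for hypo DMRs")
  dmr <- rep("none", n)
  dmr[sample(which(state == "unmethylated"), n_hyper)] <- "hyper"
  dmr[sample(which(state == "methylated"), n_hypo)] <- "hypo"

  data.frame(gene_id = gene_id, chrom = chrom, tss = tss, strand = strand,
             win_start = win_start, win_end = win_end,
             cpg_class = cpg_class, state = state, dmr = dmr,
             stringsAsFactors = FALSE)
}

#' Simulate a MeDIP promoter tiling array with planted DMRs
#'
#' Generates probe-level log2(MeDIP/Input) values as
#' baseline(promoter methylation state) + group effect over planted DMR
#' probes (+`effect_size` in the treatment group for hyper, -`effect_size`
#' for hypo) + i.i.d. Gaussian noise. The planted DMR is a centered block
#' of `dmr_probes` consecutive probes in its host promoter. Every planted
#' DMR appears exactly once in the returned truth table. Deterministic
#' given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `probes` (a [probe_table()]), `design` (a
#'   [group_design()]), `truth` (data.frame `chrom`, `start`, `end`,
#'   `gene_id`, `direction` of planted DMRs) and `promoters` (layout with
#'   class/state/DMR assignment).
#' @export
simulate_probe_array <- function(config = simulation_config()) {
  prom <- assign_promoters(config)
  k <- config$n_probes_per_promoter
  n <- config$n_promoters
  starts <- rep(prom$win_start, each = k) +
    rep(seq_len(k) - 1L, times = n) * config$probe_spacing
  probes <- data.frame(
    probe_id = paste0(rep(prom$gene_id, each = k), "_p",
                      sprintf("%02d", rep(seq_len(k), times = n))),
    chrom = rep(prom$chrom, each = k),
    start = starts,
    end = starts + config$probe_length,
    stringsAsFactors = FALSE)

  # centered planted block of dmr_probes consecutive probes
  block <- min(config$dmr_probes, k)
  b0 <- (k - block) %/% 2L + 1L
  in_block <- rep(seq_len(k), times = n) %in% (b0:(b0 + block - 1L))
  dmr_dir <- rep(prom$dmr, each = k)
  planted <- in_block & dmr_dir != "none"

  base <- config$baseline_log2ratio_mean[
    ifelse(rep(prom$state, each = k) == "methylated", "methylated", "unmethylated")]
  effect <- ifelse(planted, ifelse(dmr_dir == "hyper", config$effect_size,
                                   -config$effect_size), 0)

  reps <- config$n_replicates_per_group
  samples_t <- paste0(gsub("[^A-Za-z0-9]", "", config$treatment), "_", seq_len(reps))
  samples_c <- paste0(gsub("[^A-Za-z0-9]", "", config$control), "_", seq_len(reps))
  np <- nrow(probes)
  set.seed(config$seed + 1L)
  if (!is.null(config$probe_cv_range)) {
    cv <- stats::runif(np, config$probe_cv_range[1L], config$probe_cv_range[2L])
    noise_sd <- sqrt(log1p(cv^2)) / log(2)
  } else {
    noise_sd <- rep(config$probe_noise_sd, np)
  }
  for (s in samples_t) {
    probes[[s]] <- base + effect + stats::rnorm(np, 0, noise_sd)
  }
  for (s in samples_c) {
    probes[[s]] <- base + stats::rnorm(np, 0, noise_sd)
  }

  design <- group_design(c(samples_t, samples_c),
                         rep(c(config$treatment, config$control), each = reps))

  truth_rows <- which(prom$dmr != "none")
  truth <- data.frame(
    chrom = prom$chrom[truth_rows],
    start = prom$win_start[truth_rows] + (b0 - 1L) * config$probe_spacing,
    end = prom$win_start[truth_rows] + (b0 + block - 2L) * config$probe_spacing +
      config$probe_length,
    gene_id = prom$gene_id[truth_rows],
    direction = prom$dmr[truth_rows],
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  pt <- probe_table(probes, c(samples_t, samples_c))
  list(probes = pt, design = design, truth = truth, promoters = prom)
}

# Deterministic CG-free background with GC fraction 1/2: "AGCT" repeated
# contains AG/GC/CT/TA dinucleotides only.
cg_free_background <- function(len) {
  paste(rep_len(c("A", "G", "C", "T"), len), collapse = "")
}

# 500-bp ICP core: CG-free gc=0.5 background with evenly spaced GC -> CG
# swaps giving obs/exp ~ 0.58 (above the LCP ceiling, below the HCP
# threshold) at GC 0.5 (below the HCP GC threshold).
icp_core <- function(core_len = 500L, n_cpg = 18L) {
  chars <- strsplit(cg_free_background(core_len), "", fixed = TRUE)[[1L]]
  gc_starts <- which(chars == "G" & c(chars[-1L], "") == "C")
  pick <- gc_starts[round(seq(1L, length(gc_starts), length.out = n_cpg))]
  chars[pick] <- "C"
  chars[pick + 1L] <- "G"
  paste(chars, collapse = "")
}

#' Simulate promoter sequences with construction-rule class truth
#'
#' Builds one DNA sequence per promoter whose CpG class is fixed by
#' construction, not by running the classifier: HCP promoters embed a
#' 500-bp alternating-CG block (250 CpGs, GC 1.0, observed/expected 2.0);
#' LCP promoters contain no CG dinucleotide anywhere; ICP promoters embed a
#' 500-bp block with GC 0.5 and 18 CpGs (observed/expected ~0.58, between
#' the LCP ceiling and the HCP threshold). The flanking background is
#' CG-free with GC 0.5. Class assignment per promoter comes from the same
#' seeded layout as [simulate_probe_array()].
#'
#' @param config a [simulation_config()].
#' @return list with `promoters` (annotation data.frame incl. `sequence`
#'   and the construction-truth `cpg_class`) and `truth` (data.frame
#'   `gene_id`, `cpg_class`).
#' @export
simulate_promoter_sequences <- function(config = simulation_config()) {
  prom <- assign_promoters(config)
  win_len <- config$promoter_window[2L] - config$promoter_window[1L]
  core_len <- 500L
  if (win_len < core_len) stop("promoter window shorter than the 500-bp class core")
  lead <- (win_len - core_len) %/% 2L
  tail_len <- win_len - core_len - lead
  hcp_core <- paste(rep_len(c("C", "G"), core_len), collapse = "")
  icp <- icp_core(core_len)
  bg_lead <- cg_free_background(lead)
  bg_tail <- cg_free_background(tail_len)
  # background must not create a CG at the junctions: background ends with
  # pattern ...AGCT and cores start with C/A, so no boundary CG arises.
  seqs <- vapply(prom$cpg_class, function(cl) {
    core <- switch(cl, HCP = hcp_core, ICP = icp,
                   LCP = cg_free_background(core_len))
    paste0(bg_lead, core, bg_tail)
  }, character(1L), USE.NAMES = FALSE)
  prom$sequence <- seqs
  list(promoters = prom,
       truth = data.frame(gene_id = prom$gene_id, cpg_class = prom$cpg_class,
                          stringsAsFactors = FALSE))
}

#' Write simulated promoters as FASTA plus annotation TSV
#'
#' @param sim output of [simulate_promoter_sequences()].
#' @param fasta_path output FASTA path.
#' @param annotation_path output annotation TSV path.
#' @param truth_path optional path for the construction-truth class table.
#' @return Invisibly, the paths written.
#' @export
write_promoter_files <- function(sim, fasta_path, annotation_path,
                                 truth_path = NULL) {
  seqs <- Biostrings::DNAStringSet(sim$promoters$sequence)
  names(seqs) <- sim$promoters$gene_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  ann <- sim$promoters[c("gene_id", "chrom", "tss", "strand",
                         "win_start", "win_end")]
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta_path, annotation_path, truth_path))
}

#' Simulate bisulfite clone matrices
#'
#' Draws Bernoulli methylation calls per clone x CpG site for each animal,
#' with optional beta-distributed animal-level overdispersion around the
#' group mean.
#'
#' @param p_by_group named numeric: mean methylation probability per group.
#' @param n_animals animals per group.
#' @param n_clones clones sequenced per animal.
#' @param n_cpgs CpG sites in the amplicon.
#' @param amplicon_id amplicon label.
#' @param overdispersion beta concentration; 0 (default) means every
#'   animal uses the group mean exactly, larger values draw the animal
#'   probability from Beta(p*k, (1-p)*k) with k = `overdispersion`.
#' @param seed integer seed.
#' @return list with `matrices` (list of [bisulfite_clone_matrix()]) and
#'   `truth` (data.frame of group and animal-level probabilities).
#' @export
simulate_clone_matrices <- function(p_by_group, n_animals = 10L, n_clones = 10L,
                                    n_cpgs = 6L, amplicon_id = "amplicon",
                                    overdispersion = 0, seed = 1L) {
  if (any(p_by_group < 0 | p_by_group > 1)) stop("probabilities must be in [0, 1]")
  if (is.null(names(p_by_group))) stop("p_by_group must be named by group")
  set.seed(seed)
  matrices <- list()
  truth <- list()
  for (g in names(p_by_group)) {
    for (a in seq_len(n_animals)) {
      p <- p_by_group[[g]]
      if (overdispersion > 0 && p > 0 && p < 1) {
        p <- stats::rbeta(1L, p * overdispersion, (1 - p) * overdispersion)
      }
      calls <- matrix(stats::rbinom(n_clones * n_cpgs, 1L, p),
                      nrow = n_clones,
                      dimnames = list(paste0("clone_", seq_len(n_clones)),
                                      paste0("cpg_", seq_len(n_cpgs))))
      id <- paste0(g, "_", a)
      matrices[[paste0(id, ".", amplicon_id)]] <-
        bisulfite_clone_matrix(id, g, amplicon_id, calls)
      truth[[paste0(id, ".", amplicon_id)]] <-
        data.frame(animal_id = id, group = g, amplicon_id = amplicon_id,
                   p_group = p_by_group[[g]], p_animal = p,
                   stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(matrices = matrices, truth = truth)
}

#' Write clone matrices as a long-format TSV
#' @param matrices list of [bisulfite_clone_matrix()] objects.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_clone_tsv <- function(matrices, path) {
  rows <- lapply(matrices, function(m) {
    data.frame(animal_id = m$animal_id, group = m$group,
               amplicon_id = m$amplicon_id,
               clone_id = rownames(m$calls),
               m$calls, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a metabolic phenotype table
#'
#' Emulates a three-group weaning study (CON / HF / HF-inulin, n animals
#' per group): the control group sets the baseline, the HF group is scaled
#' by the configured effects, and the HF-inulin group sits in between.
#' Defaults echo the reported phenotype gaps: HF body weight x1.225 (the
#' 22.5% weaning gap) and an HF glucose excursion raising the OGTT AUC by
#' ~49.7%.
#'
#' @param n animals per group.
#' @param bw_multiplier_hf,bw_multiplier_inulin body-weight multipliers vs
#'   control for the HF and HF-inulin groups.
#' @param glucose_multiplier_hf,glucose_multiplier_inulin glucose-curve
#'   multipliers vs control.
#' @param insulin_multiplier_hf,insulin_multiplier_inulin fasting-insulin
#'   multipliers vs control.
#' @param baseline_bw control mean body weight at weaning (g).
#' @param baseline_glucose control glucose curve (mmol/L) at
#'   minutes 0/15/30/60/120.
#' @param baseline_insulin control fasting insulin.
#' @param noise_cv coefficient of variation of the Gaussian noise applied
#'   to every measurement (0 gives the exact configured effects).
#' @param ct_effects optional named list of per-gene log2 expression
#'   effects c(HF=, `HF-inulin`=) vs control used to build Ct columns.
#' @param seed integer seed.
#' @return A phenotype table (as from [read_phenotypes()]).
#' @export
simulate_phenotypes <- function(n = 10L,
                                bw_multiplier_hf = 1.225,
                                bw_multiplier_inulin = 1.08,
                                glucose_multiplier_hf = 1.497,
                                glucose_multiplier_inulin = 1.15,
                                insulin_multiplier_hf = 2,
                                insulin_multiplier_inulin = 1.3,
                                baseline_bw = 10,
                                baseline_glucose = c(5, 9, 10, 8, 6),
                                baseline_insulin = 10,
                                noise_cv = 0.08,
                                ct_effects = NULL,
                                seed = 1L) {
  stopifnot(length(baseline_glucose) == 5L)
  groups <- c("CON", "HF", "HF-inulin")
  mult <- list(CON = c(bw = 1, glu = 1, ins = 1),
               HF = c(bw = bw_multiplier_hf, glu = glucose_multiplier_hf,
                      ins = insulin_multiplier_hf),
               `HF-inulin` = c(bw = bw_multiplier_inulin,
                               glu = glucose_multiplier_inulin,
                               ins = insulin_multiplier_inulin))
  times <- c(0, 15, 30, 60, 120)
  set.seed(seed)
  noisy <- function(mean_val) {
    mean_val * (1 + stats::rnorm(length(mean_val), 0, noise_cv))
  }
  rows <- lapply(groups, function(g) {
    m <- mult[[g]]
    do.call(rbind, lapply(seq_len(n), function(a) {
      glu <- pmax(noisy(baseline_glucose * m[["glu"]]), 0)
      df <- data.frame(animal_id = paste0(g, "_", a), group = g,
                       body_weight = max(noisy(baseline_bw * m[["bw"]]), 0),
                       stringsAsFactors = FALSE, check.names = FALSE)
      for (i in seq_along(times)) df[[paste0("glucose_", times[i])]] <- glu[i]
      df$fasting_insulin <- max(noisy(baseline_insulin * m[["ins"]]), 0)
      df
    }))
  })
  out <- do.call(rbind, rows)
  if (!is.null(ct_effects)) {
    ct_ref <- 18
    out$ct_Gapdh <- ct_ref + stats::rnorm(nrow(out), 0, 0.1)
    for (gene in names(ct_effects)) {
      eff <- ct_effects[[gene]]
      # higher expression -> lower Ct; effect is log2 fold change vs CON
      shift <- ifelse(out$group == "HF", -eff[["HF"]],
                      ifelse(out$group == "HF-inulin", -eff[["HF-inulin"]], 0))
      out[[paste0("ct_", gene)]] <- 25 + shift + stats::rnorm(nrow(out), 0, 0.1)
    }
  }
  rownames(out) <- NULL
  structure(out, glucose_times = times,
            glucose_cols = paste0("glucose_", times),
            class = c("phenotype_table", "data.frame"))
}

#' Simulate a gene-set collection
#'
#' Builds random gene sets over a universe plus optional spiked sets
#' enriched in a given study list, for exercising the over-representation
#' stage end to end.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of random sets.
#' @param set_size genes per set.
#' @param study optional study genes to spike.
#' @param n_spiked number of spiked sets (drawn mostly from `study`).
#' @param spike_fraction fraction of a spiked set taken from `study`.
#' @param seed integer seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(universe, n_sets = 20L, set_size = 30L,
                               study = NULL, n_spiked = 2L,
                               spike_fraction = 0.6, seed = 1L) {
  set.seed(seed)
  set_size <- min(set_size, length(universe))
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  names(sets) <- sprintf("S%03d", seq_len(n_sets))
  if (!is.null(study) && n_spiked > 0L) {
    study <- intersect(study, universe)
    for (j in seq_len(n_spiked)) {
      k <- min(round(spike_fraction * set_size), length(study))
      members <- c(sample(study, k),
                   sample(setdiff(universe, study), set_size - k))
      sets[[sprintf("SPIKE%02d", j)]] <- members
    }
  }
  desc <- stats::setNames(
    ifelse(grepl("^SPIKE", names(sets)), "study-enriched set", "random set"),
    names(sets))
  gene_set_collection(sets, desc, universe)
}
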