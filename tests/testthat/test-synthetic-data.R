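test_that("generators are pure functions of config and seed", {
  cfg <- simulation_config(n_promoters = 60L, seed = 17L)
  a <- simulate_probe_array(cfg)
  b <- simulate_probe_array(cfg)
  expect_identical(a, b)
  expect_identical(simulate_promoter_sequences(cfg),
                   simulate_promoter_sequences(cfg))
  expect_identical(
    simulate_clone_matrices(c(CON = 0.4, HF = 0.6), seed = 3L),
    simulate_clone_matrices(c(CON = 0.4, HF = 0.6), seed = 3L))
  expect_identical(simulate_phenotypes(seed = 5L), simulate_phenotypes(seed = 5L))
  # a different seed changes the draw
  expect_false(identical(a$probes, simulate_probe_array(
    simulation_config(n_promoters = 60L, seed = 18L))$probes))
})

test_that("the array generator honours its geometry and truth bookkeeping", {
  cfg <- simulation_config(n_promoters = 80L, seed = 6L)
  arr <- simulate_probe_array(cfg)
  pt <- arr$probes
  expect_equal(nrow(pt), 80L * cfg$n_probes_per_promoter)
  expect_true(all(pt$end - pt$start == cfg$probe_length))
  expect_equal(length(sample_ids(pt)), 6L)
  # truth-file completeness: one interval per planted DMR, none spurious
  expect_equal(nrow(arr$truth), sum(arr$promoters$dmr != "none"))
  expect_equal(sort(arr$truth$gene_id),
               sort(arr$promoters$gene_id[arr$promoters$dmr != "none"]))
  expect_false(anyDuplicated(arr$truth$gene_id) > 0)
  # hypo DMRs sit in methylated promoters, hyper in unmethylated ones
  host_state <- arr$promoters$state[match(arr$truth$gene_id,
                                          arr$promoters$gene_id)]
  expect_true(all(host_state[arr$truth$direction == "hypo"] == "methylated"))
  expect_true(all(host_state[arr$truth$direction == "hyper"] == "unmethylated"))
  # each truth interval covers dmr_probes probes
  mid <- probe_midpoints(pt)
  for (i in seq_len(nrow(arr$truth))) {
    inside <- sum(pt$chrom == arr$truth$chrom[i] &
                    mid > arr$truth$start[i] & mid < arr$truth$end[i])
    expect_equal(inside, cfg$dmr_probes)
  }
})

test_that("noise-free limits reproduce configured effects exactly", {
  cfg <- simulation_config(n_promoters = 60L, probe_noise_sd = 0, seed = 4L)
  arr <- simulate_probe_array(cfg)
  mp <- compute_m_prime(arr$probes, arr$design, cfg$treatment, cfg$control)
  mid <- probe_midpoints(arr$probes)
  for (dir in c("hyper", "hypo")) {
    tr <- arr$truth[arr$truth$direction == dir, ]
    planted <- unlist(lapply(seq_len(nrow(tr)), function(i) {
      which(arr$probes$chrom == tr$chrom[i] & mid > tr$start[i] & mid < tr$end[i])
    }))
    expect_equal(mp$m_prime[planted],
                 rep(if (dir == "hyper") 1 else -1, length(planted)))
  }
  # unplanted probes have M' exactly zero without noise
  expect_equal(max(abs(mp$m_prime[-unlist(lapply(seq_len(nrow(arr$truth)),
    function(i) which(arr$probes$chrom == arr$truth$chrom[i] &
                        mid > arr$truth$start[i] & mid < arr$truth$end[i])))])),
    0)
})

test_that("a null effect leaves planted probes centred at zero M'", {
  cfg <- simulation_config(n_promoters = 100L, effect_size = 0, seed = 13L)
  arr <- simulate_probe_array(cfg)
  mp <- compute_m_prime(arr$probes, arr$design, cfg$treatment, cfg$control)
  mid <- probe_midpoints(arr$probes)
  planted <- unlist(lapply(seq_len(nrow(arr$truth)), function(i) {
    which(arr$probes$chrom == arr$truth$chrom[i] &
            mid > arr$truth$start[i] & mid < arr$truth$end[i])
  }))
  m <- mp$m_prime[planted]
  se <- cfg$probe_noise_sd * sqrt(2 / 3) / sqrt(length(m))
  expect_lt(abs(mean(m)), 3 * se)
})

test_that("per-probe CV targets translate to linear-scale noise", {
  cfg <- simulation_config(n_promoters = 200L, probe_cv_range = c(0.3, 0.5),
                           seed = 21L)
  arr <- simulate_probe_array(cfg)
  cvs <- apply(2^probe_values(arr$probes, design_samples(arr$design, "HF")),
               1, function(v) sd(v) / mean(v))
  # with 3 replicates individual CVs are noisy; the aggregate must sit in range
  expect_gt(median(cvs), 0.2)
  expect_lt(median(cvs), 0.6)
})

test_that("promoter sequence construction matches its declared class mix", {
  cfg <- simulation_config(n_promoters = 100L,
                           cpg_class_mix = c(HCP = 0.5, ICP = 0.25, LCP = 0.25),
                           seed = 30L)
  sim <- simulate_promoter_sequences(cfg)
  expect_equal(sum(sim$truth$cpg_class == "HCP"), 50L)
  expect_equal(sum(sim$truth$cpg_class == "ICP"), 25L)
  expect_equal(sum(sim$truth$cpg_class == "LCP"), 25L)
  # LCP sequences carry no CG dinucleotide at all
  lcp <- sim$promoters$sequence[sim$promoters$cpg_class == "LCP"]
  expect_false(any(grepl("CG", lcp, fixed = TRUE)))
  # sequences have the promoter window length
  expect_true(all(nchar(sim$promoters$sequence) ==
                    cfg$promoter_window[2] - cfg$promoter_window[1]))
  # FASTA + annotation round-trip through the reader
  fa <- tempfile(fileext = ".fa"); ann <- tempfile(fileext = ".tsv")
  tr <- tempfile(fileext = ".tsv")
  write_promoter_files(sim, fa, ann, tr)
  back <- read_fasta_promoters(fa, ann)
  expect_equal(back$sequence[match(sim$promoters$gene_id, back$gene_id)],
               sim$promoters$sequence)
})

test_that("clone matrix generator matches probabilities and amplicon sizes", {
  ones <- simulate_clone_matrices(c(CON = 1), n_animals = 2L, n_cpgs = 6L,
                                  seed = 1L)
  expect_true(all(vapply(ones$matrices,
                         function(m) methylation_ratio(m)$overall, 0) == 1))
  # pooled ratio within 3 binomial SEs of p = 0.5
  half <- simulate_clone_matrices(c(CON = 0.5), n_animals = 10L, n_clones = 10L,
                                  n_cpgs = 22L, seed = 2L)
  calls <- unlist(lapply(half$matrices, function(m) m$calls))
  expect_lt(abs(mean(calls) - 0.5), 3 * sqrt(0.25 / length(calls)))
  # the four amplicon sizes used in the validation assays
  for (k in c(6L, 22L, 9L, 31L)) {
    sim <- simulate_clone_matrices(c(CON = 0.3), n_animals = 1L, n_cpgs = k,
                                   seed = 3L)
    expect_equal(ncol(sim$matrices[[1L]]$calls), k)
  }
  # clone TSV round-trip
  tsv <- tempfile(fileext = ".tsv")
  write_clone_tsv(half$matrices, tsv)
  back <- read_clone_tsv(tsv)
  expect_equal(length(back), length(half$matrices))
  orig <- summarize_clone_matrices(half$matrices)
  got <- summarize_clone_matrices(back)
  got <- got[match(paste(orig$animal_id, orig$amplicon_id),
                   paste(got$animal_id, got$amplicon_id)), ]
  expect_equal(got$overall_ratio, orig$overall_ratio)
})

test_that("phenotype generator gives exchangeable groups under zero effects", {
  set.seed(88)
  ps <- replicate(40, {
    ph <- simulate_phenotypes(bw_multiplier_hf = 1, bw_multiplier_inulin = 1,
                              glucose_multiplier_hf = 1,
                              glucose_multiplier_inulin = 1,
                              insulin_multiplier_hf = 1,
                              insulin_multiplier_inulin = 1,
                              seed = sample.int(1e6, 1))
    group_compare(ph$body_weight, ph$group)$p_value
  })
  # p-values should look uniform: no excess of small values
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 0)
})
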