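test_that("M' is the treatment-minus-control mean with antisymmetry", {
  pt <- make_probe_table(list(t1 = rep(1, 5), t2 = rep(1, 5), t3 = rep(1, 5),
                              c1 = rep(0.5, 5), c2 = rep(0.5, 5),
                              c3 = rep(0.5, 5)))
  d <- make_design()
  mp <- compute_m_prime(pt, d, "T", "C")
  expect_equal(mp$m_prime, rep(0.5, 5))

  # identical groups -> all-zero track
  pt2 <- make_two_group_table(20, mean_t = 0.7, mean_c = 0.7)
  expect_equal(compute_m_prime(pt2, d, "T", "C")$m_prime, rep(0, 20))

  # swapping the contrast negates the track elementwise
  pt3 <- make_two_group_table(30, mean_t = 0.3, mean_c = -0.1, noise_sd = 0.4)
  ab <- compute_m_prime(pt3, d, "T", "C")
  ba <- compute_m_prime(pt3, d, "C", "T")
  expect_equal(ab$m_prime, -ba$m_prime)

  # a probe with < 2 non-missing values in a group is unresolvable
  pt4 <- make_probe_table(list(t1 = c(1, NA), t2 = c(1, NA), t3 = c(1, 2),
                               c1 = c(0, 0), c2 = c(0, 0), c3 = c(0, 0)))
  mp4 <- compute_m_prime(pt4, d, "T", "C")
  expect_true(is.na(mp4$m_prime[2]))
  # a minimal 2+2 design is accepted
  d22 <- group_design(c("t1", "t2", "c1", "c2"), c("T", "T", "C", "C"))
  expect_silent(compute_m_prime(pt4, d22, "T", "C"))
})

test_that("planted blocks are recovered in the matching direction", {
  d <- make_design()
  set.seed(21)
  n <- 400L
  shift <- numeric(n); shift[181:188] <- 1; shift[301:308] <- -1
  pt <- make_two_group_table(n, mean_t = shift, mean_c = 0, noise_sd = 0.3,
                             seed = 21)
  mp <- compute_m_prime(pt, d, "T", "C")
  hyper <- find_differential_peaks(mp, pt, direction = "hyper")
  hypo <- find_differential_peaks(mp, pt, direction = "hypo")
  block_hyper <- c(min(pt$start[181:188]), max(pt$end[181:188]))
  block_hypo <- c(min(pt$start[301:308]), max(pt$end[301:308]))
  expect_true(any(hyper$start < block_hyper[2] & hyper$end > block_hyper[1]))
  expect_true(any(hypo$start < block_hypo[2] & hypo$end > block_hypo[1]))
  expect_true(all(hyper$direction == "hyper"))
  expect_true(all(hypo$direction == "hypo"))
})

test_that("filter verdicts match the worked threshold cases", {
  d <- make_design()
  # criterion (1): both group medians below 0.3 -> reject
  pt <- make_two_group_table(10, mean_t = 0.25, mean_c = 0.20)
  mp <- compute_m_prime(pt, d, "T", "C")
  peaks <- data.frame(chrom = "chr1", start = pt$start[1], end = pt$end[10],
                      name = "peak_1", score = 3, n_probes = 10L,
                      direction = "hyper", stringsAsFactors = FALSE)
  peaks$probe_idx <- list(1:10)
  out <- filter_deps(peaks, pt, mp, d, keep_all = TRUE)
  expect_false(out$crit1)

  # same geometry with one group median at 0.3 and positive M' -> crit1 holds
  pt2 <- make_two_group_table(10, mean_t = 0.31, mean_c = 0.1)
  mp2 <- compute_m_prime(pt2, d, "T", "C")
  out2 <- filter_deps(peaks, pt2, mp2, d, keep_all = TRUE)
  expect_true(out2$crit1)

  # criterion (2): only 2 of 6 probes pass the CV rule in one group -> reject
  set.seed(31)
  noisy <- c(rnorm(4, 0, 2.5), rnorm(2, 0, 0.01))
  vals <- list(t1 = rep(1, 6), t2 = rep(1, 6), t3 = rep(1, 6),
               c1 = noisy, c2 = -noisy, c3 = noisy * 1.5)
  pt3 <- make_probe_table(vals)
  mp3 <- compute_m_prime(pt3, d, "T", "C")
  peaks3 <- peaks; peaks3$probe_idx <- list(1:6); peaks3$n_probes <- 6L
  peaks3$end <- pt3$end[6]
  out3 <- filter_deps(peaks3, pt3, mp3, d, keep_all = TRUE)
  cvs <- apply(2^cbind(noisy, -noisy, noisy * 1.5), 1,
               function(v) sd(v) / mean(v))
  expect_equal(unname(out3$cv_pass_C), mean(cvs <= 0.8))
  if (mean(cvs <= 0.8) < 0.5) expect_false(out3$crit2)
})

test_that("filter verdicts equal the straight-line oracle on random peaks", {
  d <- make_design()
  set.seed(77)
  n <- 500L
  pt <- make_two_group_table(n, mean_t = rnorm(n, 0.2, 0.6),
                             mean_c = rnorm(n, 0.2, 0.6), noise_sd = 0.5,
                             seed = 77)
  mp <- compute_m_prime(pt, d, "T", "C")
  mats <- list(T = probe_values(pt, design_samples(d, "T")),
               C = probe_values(pt, design_samples(d, "C")))
  peaks <- do.call(rbind, lapply(1:200, function(i) {
    a <- sample.int(n - 8L, 1L); len <- sample(2:8, 1L)
    data.frame(chrom = "chr1", start = pt$start[a], end = pt$end[a + len - 1L],
               name = paste0("peak_", i), score = 3, n_probes = len,
               direction = sample(c("hyper", "hypo"), 1L),
               stringsAsFactors = FALSE)
  }))
  peaks$probe_idx <- lapply(1:200, function(i) {
    a <- which(pt$start == peaks$start[i])[1L]
    a:(a + peaks$n_probes[i] - 1L)
  })
  got <- filter_deps(peaks, pt, mp, d, keep_all = TRUE)
  for (i in 1:200) {
    want <- oracle_filter_verdict(peaks$probe_idx[[i]], peaks$direction[i],
                                  mats, mp$m_prime)
    expect_equal(got$crit1[i], unname(want["crit1"]))
    expect_equal(got$crit2[i], unname(want["crit2"]))
    expect_equal(got$pass[i], unname(want["pass"]))
  }
})

test_that("tightening any filter threshold never adds a DEP", {
  arr <- simulate_probe_array(simulation_config(n_promoters = 120L, seed = 3L))
  fit <- medip_dmr(arr$probes, arr$design)
  base_n <- nrow(fit$deps)
  tighter <- list(dep_filter_params(median_ratio_min = 0.5),
                  dep_filter_params(cv_max = 0.4),
                  dep_filter_params(cv_pass_fraction_min = 0.9))
  for (fp in tighter) {
    refit <- medip_dmr(arr$probes, arr$design, filter_params = fp)
    expect_lte(nrow(refit$deps), base_n)
  }
})

test_that("swapping treatment and control exchanges hyper and hypo DEP sets", {
  arr <- simulate_probe_array(simulation_config(n_promoters = 150L, seed = 8L))
  ab <- medip_dmr(arr$probes, arr$design, "HF-inulin", "HF")
  ba <- medip_dmr(arr$probes, arr$design, "HF", "HF-inulin")
  key <- function(df, dir) {
    d <- df[df$direction == dir, c("chrom", "start", "end")]
    d <- d[order(d$chrom, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(ab$deps, "hyper"), key(ba$deps, "hypo"))
  expect_equal(key(ab$deps, "hypo"), key(ba$deps, "hyper"))
})

test_that("direction summaries reproduce exact percentage arithmetic", {
  deps <- data.frame(direction = c(rep("hyper", 3), rep("hypo", 0)))
  s <- summarize_directions(deps)
  expect_equal(s$percent, c(100, 0))
  s2 <- summarize_directions(data.frame(direction = c("hyper", "hypo")))
  expect_equal(s2$percent, c(50, 50))
  expect_error(summarize_directions(data.frame(direction = character())))
})

test_that("the medip_dmr object prints, summarizes and exports", {
  arr <- simulate_probe_array(simulation_config(n_promoters = 100L, seed = 5L))
  fit <- medip_dmr(arr$probes, arr$design)
  expect_s3_class(fit, "medip_dmr")
  expect_output(print(fit), "MeDIP differential methylation fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.medip_dmr")
  expect_output(print(s), "Direction breakdown")
  df <- as.data.frame(fit)
  expect_true(is.data.frame(df) && is.null(df$probe_idx))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})
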