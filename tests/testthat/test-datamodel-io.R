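test_that("probe tables validate, sort and convert two-channel intensities", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(probe_id = c("p3", "p1", "p2"),
                   chrom = c("chr2", "chr1", "chr1"),
                   start = c(100L, 500L, 100L), end = c(160L, 560L, 160L),
                   s1_MeDIP = c(4, 2, 8), s1_Input = c(2, 2, 2),
                   s2_MeDIP = c(1, 1, 1), s2_Input = c(1, 2, 4))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- read_probe_table(tmp, format = "two_channel")
  # sorted by (chrom, start), values aligned with the sorted rows
  expect_equal(pt$probe_id, c("p2", "p1", "p3"))
  expect_equal(pt$s1, c(2, 0, 1))        # log2(8/2), log2(2/2), log2(4/2)
  expect_equal(pt$s2, c(-2, -1, 0))
  expect_equal(sample_ids(pt), c("s1", "s2"))

  # independently sorted copy of a shuffled log2 table matches
  df2 <- data.frame(probe_id = paste0("q", 1:6),
                    chrom = rep(c("chr1", "chr2"), 3),
                    start = c(300L, 100L, 100L, 300L, 200L, 200L),
                    end = c(360L, 160L, 160L, 360L, 260L, 260L),
                    a = rnorm(6), b = rnorm(6))
  write.table(df2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  pt2 <- read_probe_table(tmp)
  ref <- df2[order(df2$chrom, df2$start), ]
  expect_equal(pt2$probe_id, ref$probe_id)
  expect_equal(pt2$a, ref$a)

  # rejections
  df$probe_id <- c("p1", "p1", "p2")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_probe_table(tmp, format = "two_channel"), "duplicate")
  df$probe_id <- c("p1", "p2", "p3"); df$s1_MeDIP[2] <- -1
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_probe_table(tmp, format = "two_channel"), "p2")
})

test_that("group designs require exactly two groups with >= 2 replicates", {
  expect_silent(group_design(letters[1:6], rep(c("A", "B"), each = 3)))
  expect_error(group_design(letters[1:3], c("A", "A", "A")), "two groups")
  expect_error(group_design(letters[1:3], c("A", "A", "B")), ">= 2")
  d <- make_design()
  expect_setequal(design_samples(d, "T"), c("t1", "t2", "t3"))
})

test_that("BED6 writing follows the format contract and round-trips", {
  tmp <- tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = "chr1", start = 100L, end = 500L,
                       name = "peak_1", score = 3.2), tmp)
  expect_equal(readLines(tmp), "chr1\t100\t500\tpeak_1\t3.2\t.")

  write_bed(data.frame(chrom = character(), start = integer(), end = integer()),
            tmp)
  expect_equal(file.size(tmp), 0)
  expect_equal(nrow(read_bed(tmp)), 0L)

  set.seed(7)
  recs <- data.frame(chrom = sample(paste0("chr", 1:3), 10, replace = TRUE),
                     start = sample.int(1e6, 10))
  recs$end <- recs$start + sample.int(1000, 10)
  recs$name <- paste0("peak_", 1:10)
  recs$score <- round(runif(10, 0, 900), 3)
  write_bed(recs, tmp)
  back <- read_bed(tmp)
  expect_equal(back$chrom, recs$chrom)
  expect_equal(back$start, recs$start)
  expect_equal(back$end, recs$end)
  expect_equal(back$name, recs$name)
  expect_equal(back$score, recs$score)
  expect_true(all(back$strand == "."))
})

test_that("promoter FASTA joins to annotation with case and id checks", {
  fa <- tempfile(fileext = ".fa"); ann <- tempfile(fileext = ".tsv")
  writeLines(c(">geneA", "acgtn", ">geneB", "GGGCC"), fa)
  write.table(data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                         tss = c(1000L, 2000L), strand = c("+", "-"),
                         win_start = c(995L, 1995L), win_end = c(1000L, 2000L)),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_fasta_promoters(fa, ann)
  expect_equal(rec$sequence[rec$gene_id == "geneA"], "ACGTN")

  writeLines(c(">geneA", "ACGTN"), fa)
  expect_error(read_fasta_promoters(fa, ann), "geneB")
  writeLines(c(">geneA", "ACGTN", ">geneB", "GGXCC"), fa)
  expect_error(read_fasta_promoters(fa, ann), "geneB")
})

test_that("GMT, clone and phenotype readers enforce their contracts", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tother\tg2\tg3\tg4"), gmt)
  gsc <- read_gmt(gmt)
  expect_equal(sort(gsc$sets$S1), c("g1", "g2"))
  expect_equal(length(gsc$sets$S2), 3L)
  expect_setequal(gsc$universe, paste0("g", 1:4))
  # restriction drops outside members and empty sets
  gsc2 <- read_gmt(gmt, universe = c("g1", "g2"))
  expect_equal(names(gsc2$sets), c("S1", "S2"))
  expect_equal(gsc2$sets$S2, "g2")

  cl <- tempfile(fileext = ".tsv")
  df <- data.frame(animal_id = "a1", group = "CON", amplicon_id = "Wnt5a",
                   clone_id = paste0("c", 1:10),
                   matrix(1L, 10, 6, dimnames = list(NULL, paste0("cpg_", 1:6))),
                   check.names = FALSE)
  write.table(df, cl, sep = "\t", quote = FALSE, row.names = FALSE)
  mats <- read_clone_tsv(cl)
  expect_length(mats, 1L)
  expect_equal(methylation_ratio(mats[[1L]])$overall, 1.0)
  df$cpg_3[2] <- 2L
  write.table(df, cl, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clone_tsv(cl), "outside \\{0,1,NA\\}")

  ph <- tempfile(fileext = ".tsv")
  pdf <- data.frame(animal_id = c("x1", "x2", "x3", "x4"),
                    group = rep(c("CON", "HF"), 2), body_weight = 10,
                    glucose_0 = 5, glucose_15 = 10, glucose_30 = 8,
                    glucose_60 = 7, glucose_120 = 6, fasting_insulin = 10)
  write.table(pdf, ph, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_phenotypes(ph)
  expect_equal(attr(tab, "glucose_times"), c(0, 15, 30, 60, 120))
  pdf$group[1] <- "MYSTERY"
  write.table(pdf, ph, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(ph), "MYSTERY")
})
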