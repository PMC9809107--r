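test_that("QC keeps reads at the threshold and drops those strictly below", {
  reads <- data.frame(read_id = c("a", "b", "c"),
                      mean_qscore = c(6.9, 7.0, 12.0), length = 100)
  kept <- qc_filter_reads(reads)
  expect_equal(kept$read_id, c("b", "c"))
  expect_equal(nrow(qc_filter_reads(reads[0, ])), 0)
  expect_equal(qc_filter_reads(reads, min_qscore = 0), reads)
  # idempotent
  expect_identical(qc_filter_reads(kept), kept)
})

test_that("N50 and depth follow their definitions and match a brute-force oracle", {
  reads <- data.frame(length = c(40, 30, 20, 10))
  st <- read_stats(reads, genome_size = 1000)
  expect_equal(st$total_bases, 100)
  expect_equal(st$n50, 30)
  expect_equal(read_stats(data.frame(length = 500), 1000)$depth, 0.5)
  expect_equal(read_stats(data.frame(length = 500), 1000)$n50, 500)
  expect_warning(st0 <- read_stats(data.frame(length = numeric()), 1000), "empty")
  expect_equal(st0$n50, 0)

  # independent oracle: largest L present such that reads >= L hold half the bases
  set.seed(17)
  lens <- sample(200:50000, 10000, replace = TRUE)
  oracle <- max(Filter(function(L) sum(lens[lens >= L]) >= sum(lens) / 2,
                       unique(lens)))
  st2 <- read_stats(data.frame(length = lens), 3e9)
  expect_equal(st2$n50, oracle)
  expect_equal(st2$depth, sum(lens) / 3e9)
})

test_that("CNV localization pools embryo boundaries to the modal grid position", {
  spec <- translocation_spec("cA", "cB", 125157514, 35465883, "q", "p")
  seg <- function(embryo, chrom, start, end, cn)
    data.frame(chrom = chrom, start = start, end = end, cn = cn,
               mosaic_pct = NA_integer_, stringsAsFactors = FALSE)
  lens <- c(cA = 243e6, cB = 181e6)
  lists <- list(
    e1 = rbind(seg("e1", "cA", 125200001, 243e6, 3),
               seg("e1", "cB", 1, 35400000, 1)),
    e2 = rbind(seg("e2", "cA", 125200001, 243e6, 1),
               seg("e2", "cB", 1, 35400000, 3)),
    e3 = rbind(seg("e3", "cA", 125400001, 243e6, 3),
               seg("e3", "cB", 1, 35400000, 1)))
  est <- localize_from_cnv(lists, spec, bin_width = 200000, lens)
  a <- est[est$chrom == "cA", ]
  expect_equal(a$position, 125200001)   # mode of {125200001 x2, 125400001}
  expect_equal(a$support, 3)
  expect_equal(a$half_window, 200000)   # max(bin, spread/2 = 100000)
  expect_equal(est$position[est$chrom == "cB"], 35400001)

  single <- localize_from_cnv(lists["e1"], spec, 200000, lens)
  expect_equal(single$position[single$chrom == "cA"], 125200001)
  expect_equal(unique(single$half_window), 200000)
  expect_equal(unique(single$support), 1)

  expect_error(localize_from_cnv(list(), spec, 200000), "reference")
})

test_that("junction clustering takes the modal coordinate and honors min support", {
  blk <- function(rid, chrom, start, end, strand, rs)
    data.frame(read_id = rid, chrom = chrom, start = start, end = end,
               strand = strand, read_start = rs, stringsAsFactors = FALSE)
  blocks <- rbind(
    blk("r1", "cA", 999001, 1000000, "+", 1), blk("r1", "cB", 500000, 500900, "+", 1001),
    blk("r2", "cA", 999101, 1000000, "+", 1), blk("r2", "cB", 500000, 500800, "+", 901),
    blk("r3", "cA", 999001, 1000001, "+", 1), blk("r3", "cB", 500000, 500900, "+", 1002))
  cl <- detect_junctions(blocks, tolerance = 10, min_support = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$pos_a, 1000000)  # mode of {1000000, 1000000, 1000001}
  expect_equal(cl$pos_b, 500000)
  expect_equal(cl$support, 3)

  expect_equal(nrow(detect_junctions(blocks[1:4, ], min_support = 3)), 0)

  # permutation invariance in read and block order
  perm <- blocks[sample(nrow(blocks)), ]
  cl2 <- detect_junctions(perm, tolerance = 10, min_support = 3)
  expect_equal(cl2$pos_a, cl$pos_a)
  expect_equal(cl2$pos_b, cl$pos_b)
})

test_that("error-free simulated reads recover the planted junction exactly", {
  g <- tiny_genome(); spec <- tiny_spec()
  derivs <- build_derivatives(spec, g)
  rl <- simulate_long_reads(g, derivs, n = 600, length_meanlog = log(150),
                            length_sdlog = 0.3, seed = 23)
  cl <- detect_junctions(rl$blocks, tolerance = 10, min_support = 3)
  expect_equal(nrow(cl), 2)                       # one junction per derivative
  expect_setequal(cl$pos_a, c(400, 401))          # (bp_a, bp_a + 1)
  expect_setequal(cl$pos_b, c(300, 301))
  expect_equal(length(unique(cl$translocation)), 1)  # reciprocal pair merged
  expect_true(all(cl$support >= 3))
})

test_that("concordance reports the distance and window membership", {
  cnv <- data.frame(chrom = "chr2", position = 125200001, half_window = 200000)
  split <- data.frame(chrom = "chr2", position = 125157514)
  cc <- check_concordance(cnv, split)
  expect_equal(cc$distance, 42487)
  expect_true(cc$within_window)

  cnv17 <- data.frame(chrom = "chr17", position = 34000001, half_window = 200000)
  cc17 <- check_concordance(cnv17, data.frame(chrom = "chr17", position = 33942282))
  expect_equal(cc17$distance, 57719)
  expect_true(cc17$within_window)

  same <- check_concordance(cnv, data.frame(chrom = "chr2", position = 125200001))
  expect_equal(same$distance, 0)
  expect_error(check_concordance(cnv, data.frame(chrom = "chr3", position = 1)),
               "different chromosomes")
})

test_that("minimal SAM split alignments feed junction detection", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:cA\tLN:5000000",
    "@SQ\tSN:cB\tLN:5000000",
    paste("r1", 0, "cA", 999901, 60, "100M100S", "*", 0, 0,
          strrep("A", 200), "*", sep = "\t"),
    paste("r1", 2048, "cB", 500000, 60, "100S100M", "*", 0, 0,
          strrep("A", 200), "*", sep = "\t"),
    paste("r2", 0, "cA", 999901, 60, "100M100S", "*", 0, 0,
          strrep("A", 200), "*", sep = "\t"),
    paste("r2", 2048, "cB", 500000, 60, "100S100M", "*", 0, 0,
          strrep("A", 200), "*", sep = "\t"),
    paste("r3", 0, "cA", 999901, 60, "100M100S", "*", 0, 0,
          strrep("A", 200), "*", sep = "\t"),
    paste("r3", 2048, "cB", 500000, 60, "100S100M", "*", 0, 0,
          strrep("A", 200), "*", sep = "\t")), sam)
  blocks <- read_split_alignments_sam(sam)
  expect_equal(nrow(blocks), 6)
  expect_equal(blocks$end[1], 1000000)
  expect_equal(blocks$read_start, rep(c(1, 101), 3))
  cl <- detect_junctions(blocks, min_support = 3)
  expect_equal(cl$pos_a, 1000000)
  expect_equal(cl$pos_b, 500000)
  unlink(sam)
})
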