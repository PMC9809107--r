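test_that("expected copy profile blends integer CN, mosaics, and straddled bins", {
  g <- tiny_genome(); spec <- tiny_spec()
  truth <- make_embryo("adj1", fixed_gamete(c("der_a", "B_normal"), spec, g),
                       spec, g)
  prof <- true_copy_profile(truth, g, bin_width = 100)
  # non-mosaic monosomic/trisomic bins are flat at the integer CN
  expect_true(all(prof$cn[prof$chrom == "c1" & prof$start > 400] == 1))
  expect_true(all(prof$cn[prof$chrom == "c2" & prof$end <= 300] == 3))

  # mosaic trisomy at 31% lifts the expected CN to 2.31
  tm <- make_embryo("mos", fixed_gamete(c("A_normal", "B_normal"), spec, g),
                    spec, g,
                    mosaic_events = data.frame(chrom = "c1", start = 1,
                                               end = 1000, type = "gained",
                                               fraction = 0.31))
  pm <- true_copy_profile(tm, g, bin_width = 100)
  expect_equal(unique(pm$cn[pm$chrom == "c1"]), 2.31)

  # a bin straddling the CN boundary gets the length-weighted mean
  p3 <- true_copy_profile(truth, g, bin_width = 300)
  straddle <- p3[p3$chrom == "c1" & p3$start == 301, ]
  expect_equal(straddle$cn, (100 * 2 + 200 * 1) / 300)

  expect_error(true_copy_profile(
    make_embryo("bad", fixed_gamete(c("A_normal", "B_normal"), spec, g),
                spec, g,
                mosaic_events = data.frame(chrom = "c1", start = 1, end = 10,
                                           type = "gained", fraction = 1.2)),
    g, 100), "fraction")
})

test_that("bin counts have the requested mean and reproduce under a fixed seed", {
  bins <- data.frame(chrom = "c1", start = seq(1, by = 1000, length.out = 10000),
                     end = seq(1000, by = 1000, length.out = 10000), cn = 2)
  bc <- simulate_bin_counts(bins, m = 100, dispersion = 0.1, seed = 11)
  expect_lt(abs(mean(bc$count) - 100) / 100, 0.02)

  bins$cn <- 2.31
  bc2 <- simulate_bin_counts(bins, m = 100, dispersion = 0.1, seed = 12)
  se <- stats::sd(bc2$count) / sqrt(nrow(bc2))
  expect_lt(abs(mean(bc2$count) - 115.5), 3 * se)
  # overdispersed relative to nothing, but still near-Poisson scale
  expect_gte(stats::var(bc2$count), 0.8 * mean(bc2$count))

  # dispersion 0: deterministic rounding of m * cn / 2
  bins$cn <- c(rep(2, 5000), rep(3, 5000))
  bc3 <- simulate_bin_counts(bins, m = 101, dispersion = 0, seed = 1)
  expect_identical(bc3$count, round(101 * bins$cn / 2))

  expect_error(simulate_bin_counts(bins, m = -5), "positive")
  expect_error(simulate_bin_counts(bins, m = 100, dispersion = -1),
               "non-negative")

  a <- simulate_bin_counts(bins, m = 100, dispersion = 0.1, seed = 99)
  b <- simulate_bin_counts(bins, m = 100, dispersion = 0.1, seed = 99)
  expect_identical(a, b)
})

test_that("SNP observations expose exactly the haplotypes present in the embryo", {
  g <- tiny_genome(); spec <- tiny_spec()
  linkage <- c(a = "H1", b = "H2")

  # euploid non-carrier, no dropout: observed = {transmitted carrier allele,
  # partner allele} at every site (brute-force expectation per site)
  truth <- make_embryo("eu", fixed_gamete(c("A_normal", "B_normal"), spec, g),
                       spec, g, linkage = linkage,
                       partner_hap = c(a = 1L, b = 1L))
  obs <- simulate_snp_observations(truth, g, ado = 0, error_rate = 0, seed = 3)
  snp <- g$snps
  for (i in seq_len(nrow(snp))) {
    carrier_hap <- if (snp$chrom[i] == "c1") "H2" else "H1"  # other(linkage)
    expected <- unique(c(if (carrier_hap == "H1") snp$h1[i] else snp$h2[i],
                         snp$partner1[i]))
    got <- sort(obs$allele[obs$chrom == snp$chrom[i] & obs$pos == snp$pos[i]])
    expect_identical(got, sort(expected))
  }

  # monosomic distal region: only the partner allele is visible
  adj <- make_embryo("adj", fixed_gamete(c("der_a", "B_normal"), spec, g),
                     spec, g, linkage = linkage, partner_hap = c(a = 1L, b = 1L))
  oa <- simulate_snp_observations(adj, g, ado = 0, error_rate = 0, seed = 4)
  distal <- snp[snp$chrom == "c1" & snp$pos > 400, ]
  for (i in seq_len(nrow(distal))) {
    got <- oa$allele[oa$chrom == "c1" & oa$pos == distal$pos[i]]
    expect_identical(got, distal$partner1[i])
  }

  # total dropout still reports exactly one allele per site
  o1 <- simulate_snp_observations(truth, g, ado = 1, seed = 5)
  expect_true(all(table(paste(o1$chrom, o1$pos)) == 1))
  expect_equal(nrow(o1), nrow(snp))
})

test_that("long reads map to correct blocks and junction breakends", {
  g <- tiny_genome(); spec <- tiny_spec()
  derivs <- build_derivatives(spec, g)
  rl <- simulate_long_reads(g, derivs, n = 400, length_meanlog = log(150),
                            length_sdlog = 0.3, seed = 21)
  # reads wholly inside a normal chromosome have a single block
  normals <- rl$reads$read_id[rl$reads$molecule %in% c("A_normal", "B_normal")]
  expect_true(all(table(rl$blocks$read_id[rl$blocks$read_id %in% normals]) == 1))
  expect_true(all(!rl$reads$spans_junction[rl$reads$molecule %in%
                                             c("A_normal", "B_normal")]))
  # junction-spanning reads break exactly at the planted breakpoints
  jr <- rl$reads$read_id[rl$reads$spans_junction]
  expect_gt(length(jr), 0)
  for (rid in jr) {
    b <- rl$blocks[rl$blocks$read_id == rid, ]
    b <- b[order(b$read_start), ]
    mol <- rl$reads$molecule[rl$reads$read_id == rid]
    p1 <- if (b$strand[1] == "+") b$end[1] else b$start[1]
    p2 <- if (b$strand[2] == "+") b$start[2] else b$end[2]
    if (mol == "der_a") expect_equal(sort(c(p1, p2)), c(300, 400))
    else expect_equal(sort(c(p1, p2)), c(301, 401))
  }
  # fixed seed gives bit-identical output
  rl2 <- simulate_long_reads(g, derivs, n = 400, length_meanlog = log(150),
                             length_sdlog = 0.3, seed = 21)
  expect_identical(rl, rl2)
})

test_that("FASTQ and truth-BED writers use the standard conventions", {
  g <- tiny_genome(); spec <- tiny_spec()
  derivs <- build_derivatives(spec, g)
  rl <- simulate_long_reads(g, derivs, n = 20, length_meanlog = log(150),
                            length_sdlog = 0.2, seed = 31)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rl, fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 4 * nrow(rl$reads))
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@read_")))
  expect_equal(nchar(lines[2]), rl$reads$length[1])
  expect_equal(nchar(lines[2]), nchar(lines[4]))

  bed <- tempfile(fileext = ".bed")
  write_truth_bed(rl, bed)
  b <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(b), nrow(rl$blocks))
  # BED is 0-based half-open: start shifts by 1, end does not
  expect_equal(b$V2, rl$blocks$start - 1)
  expect_equal(b$V3, rl$blocks$end)
  expect_true(all(b$V6 %in% c("+", "-")))
  unlink(c(fq, bed))
})
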