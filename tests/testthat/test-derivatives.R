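test_that("derivatives of a q/p exchange reproduce the clinical junction geometry", {
  lens <- clinical_fixtures()$chrom_lengths
  g <- genome_model(
    data.frame(chrom = c("chr2", "chr5"), length = lens[c("chr2", "chr5")]),
    data.frame(chrom = character(), pos = numeric(), h1 = character(),
               h2 = character(), partner1 = character(), partner2 = character()))
  spec <- translocation_spec("chr2", "chr5", 125157514, 35465883, "q", "p")
  d <- build_derivatives(spec, g)

  # der(2): proximal 2 forward, distal 5p inverted (telomere outward)
  expect_equal(d$der_a$chrom, c("chr2", "chr5"))
  expect_equal(d$der_a$start, c(1, 1))
  expect_equal(d$der_a$end, c(125157514, 35465883))
  expect_equal(d$der_a$strand, c("+", "-"))
  j <- attr(d$der_a, "junction")
  expect_equal(j[[1]]$pos, 125157514)
  expect_equal(j[[2]]$pos, 35465883)

  # der(5) takes every remaining base
  expect_equal(d$der_b$start, c(125157515, 35465884))
  expect_equal(d$der_b$end, unname(c(lens["chr2"], lens["chr5"])))
  expect_equal(derivative_length(d$der_a) + derivative_length(d$der_b),
               unname(lens["chr2"] + lens["chr5"]))
})

test_that("derivative pair is an exact base partition for every arm combination", {
  g <- tiny_genome()
  for (arms in list(c("q", "p"), c("q", "q"), c("p", "p"), c("p", "q"))) {
    spec <- translocation_spec("c1", "c2", 400, 300, arms[1], arms[2])
    d <- build_derivatives(spec, g)
    # exhaustive per-base coverage scan
    cov <- list(c1 = integer(1000), c2 = integer(1000))
    for (der in list(d$der_a, d$der_b))
      for (i in seq_len(nrow(der)))
        cov[[der$chrom[i]]][der$start[i]:der$end[i]] <-
          cov[[der$chrom[i]]][der$start[i]:der$end[i]] + 1L
    expect_true(all(cov$c1 == 1L), info = paste(arms, collapse = "/"))
    expect_true(all(cov$c2 == 1L), info = paste(arms, collapse = "/"))
    # each derivative: exactly one junction, two fragments
    expect_equal(nrow(d$der_a), 2)
    expect_equal(nrow(d$der_b), 2)
    expect_equal(derivative_length(d$der_a) + derivative_length(d$der_b), 2000)
  }
})

test_that("base conservation holds on the 1 kb toy case", {
  g <- tiny_genome()
  d <- build_derivatives(tiny_spec(), g)
  expect_equal(derivative_length(d$der_a) + derivative_length(d$der_b), 2000)
})

test_that("breakpoints outside the chromosome are rejected", {
  g <- tiny_genome()
  expect_error(build_derivatives(translocation_spec("c1", "c2", 1000, 300, "q", "p"), g),
               "outside")
  expect_error(build_derivatives(translocation_spec("c1", "c2", 400, 5000, "q", "p"), g),
               "outside")
  expect_error(translocation_spec("c1", "c1", 10, 20, "q", "p"), "different")
})

test_that("segregation modes transmit the expected elements and balance flags", {
  g <- tiny_genome(); spec <- tiny_spec()
  set.seed(7)
  outcomes <- list(
    alternate = list(c("A_normal", "B_normal"), c("der_a", "der_b")),
    adjacent1 = list(c("der_a", "B_normal"), c("A_normal", "der_b")),
    adjacent2 = list(c("A_normal", "der_a"), c("B_normal", "der_b")))
  for (mode in names(outcomes)) {
    for (i in 1:250) {
      gam <- segregate(spec, g, mode)
      expect_true(any(vapply(outcomes[[mode]],
                             function(o) setequal(o, gam$transmitted), TRUE)))
      expect_identical(gam$balanced, mode == "alternate")
    }
  }
  for (i in 1:250) {
    gam <- segregate(spec, g, "three_to_one")
    expect_length(gam$transmitted, 3)
    expect_false(gam$balanced)
  }
  expect_error(segregate(spec, g, "adjacent3"), "unknown segregation mode")
})

test_that("embryo copy number matches per-base brute-force enumeration", {
  g <- tiny_genome(); spec <- tiny_spec()
  cases <- list(c("der_a", "B_normal"), c("A_normal", "der_b"),
                c("A_normal", "der_a"), c("B_normal", "der_b"),
                c("A_normal", "B_normal"), c("der_a", "der_b"),
                c("A_normal", "B_normal", "der_a"))
  for (transmitted in cases) {
    truth <- make_embryo("t", fixed_gamete(transmitted, spec, g), spec, g)
    bf <- brute_force_cn(transmitted, spec, g)
    for (i in seq_len(nrow(truth$cn_segments))) {
      s <- truth$cn_segments[i, ]
      expect_true(all(bf[[s$chrom]][s$start:s$end] == s$cn),
                  info = paste(transmitted, collapse = "+"))
    }
    # segments tile each chromosome completely
    for (ch in c("c1", "c2")) {
      s <- truth$cn_segments[truth$cn_segments$chrom == ch, ]
      expect_equal(sum(s$end - s$start + 1), 1000)
    }
  }
})

test_that("adjacent-1 embryos show the reciprocal loss/gain dosage pattern", {
  g <- tiny_genome(); spec <- tiny_spec()  # bp_a = 400 (q), bp_b = 300 (p)
  truth <- make_embryo("adj1", fixed_gamete(c("der_a", "B_normal"), spec, g),
                       spec, g)
  s <- truth$cn_segments
  # monosomic for distal q of chromosome A, trisomic for distal p of B
  expect_equal(s$cn[s$chrom == "c1" & s$start == 401], 1)
  expect_equal(s$cn[s$chrom == "c2" & s$end == 300], 3)
  expect_equal(truth$carrier_status, "unbalanced")
})
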