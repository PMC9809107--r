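test_that("informative SNP selection keeps carrier-het/partner-hom flank sites", {
  spec <- translocation_spec("c1", "c2", 1e6, 5e5, "q", "p")
  sites <- data.frame(
    chrom = c("c1", "c1", "c1", "c1"),
    pos = c(5e5, 9e5, 9.5e5, 3e6 + 1e6),
    h1 = c("G", "G", "G", "G"), h2 = c("T", "G", "T", "T"),
    partner1 = c("G", "G", "G", "G"), partner2 = c("G", "G", "T", "G"),
    stringsAsFactors = FALSE)
  bp <- data.frame(chrom = "c1", position = 1e6)
  suppressWarnings(kept <- select_informative_snps(sites, bp, spec, 2e6))
  # carrier G/T + partner G/G kept; carrier hom and partner het excluded;
  # site beyond the flank window excluded
  expect_equal(kept$pos, 5e5)
  expect_equal(kept$flank, "proximal")
  expect_warning(expect_warning(
    select_informative_snps(sites[3, ], bp, spec, 2e6), "inconclusive"))
})

test_that("reference-embryo phasing recovers the planted derivative haplotypes", {
  fx <- phase_fixture(ado = 0)
  refs <- c("R1", "R2", "R3")
  link <- phase_derivative_from_references(fx$obs, fx$segs[refs], fx$spec,
                                           fx$snps)
  expect_equal(link$der_hap[link$chrom == "c1"], unname(fx$linkage["a"]))
  expect_equal(link$der_hap[link$chrom == "c2"], unname(fx$linkage["b"]))
  expect_true(all(link$consistency == 1))
  expect_equal(attr(link, "crosscheck_violations"), 0L)

  # the two reciprocal adjacent-1 gamete types agree on their own
  for (r in list("R1", "R2")) {
    l1 <- phase_derivative_from_references(fx$obs, fx$segs[r], fx$spec, fx$snps)
    expect_equal(l1$der_hap, link$der_hap)
  }
  expect_error(phase_derivative_from_references(fx$obs, list(), fx$spec, fx$snps),
               "no reference embryos")
})

test_that("conflicting reference votes stop with the discordant embryos named", {
  fx <- phase_fixture(ado = 0)
  # mislabel a complementary embryo as the same gamete type to force discord
  segs <- fx$segs[c("R1", "R2")]
  segs$R2 <- fx$segs$R1
  obs <- fx$obs
  expect_error(
    phase_derivative_from_references(obs, segs, fx$spec, fx$snps,
                                     consistency = 0.95),
    "phase not resolved")
})

test_that("junction-read phasing agrees with the reference route", {
  fx <- phase_fixture(ado = 0)
  derivs <- build_derivatives(fx$spec, fx$genome)
  rl <- simulate_long_reads(fx$genome, derivs, n = 1500,
                            length_meanlog = log(20000), length_sdlog = 0.3,
                            linkage = fx$linkage, seed = 61)
  cl <- detect_junctions(rl$blocks, min_support = 3)
  lr <- phase_from_junction_reads(rl, cl, fx$snps, fx$spec)
  expect_equal(lr$der_hap[lr$chrom == "c1"], unname(fx$linkage["a"]))
  expect_equal(lr$der_hap[lr$chrom == "c2"], unname(fx$linkage["b"]))
  expect_true(all(lr$votes_against == 0))

  ref <- phase_derivative_from_references(fx$obs, fx$segs[c("R1", "R2", "R3")],
                                          fx$spec, fx$snps)
  expect_equal(lr$der_hap, ref$der_hap)

  # reads without junctions contribute nothing
  no_j <- rl
  no_j$blocks <- no_j$blocks[no_j$blocks$read_id %in%
    no_j$reads$read_id[!no_j$reads$spans_junction], , drop = FALSE]
  cl0 <- detect_junctions(no_j$blocks, min_support = 3)
  expect_message(l0 <- phase_from_junction_reads(no_j, cl0, fx$snps, fx$spec),
                 "inconclusive")
  expect_true(all(is.na(l0$der_hap)))
})

test_that("carrier calls follow the transmitted haplotype on both flanks", {
  fx <- phase_fixture(ado = 0)
  link <- phase_derivative_from_references(fx$obs, fx$segs[c("R1", "R2", "R3")],
                                           fx$spec, fx$snps)
  eu1 <- call_carrier_status(karyotype_call("EU1"), fx$obs, link, fx$snps)
  expect_equal(eu1$call, "non_carrier")
  eu2 <- call_carrier_status(karyotype_call("EU2"), fx$obs, link, fx$snps)
  expect_equal(eu2$call, "carrier")
  expect_true(all(eu2$evidence$origin == "derivative"))
  expect_true(all(eu2$evidence$n_support >= 5))

  # unbalanced embryos are refused outright
  bad <- parse_karyotype("46, XN, +17p(×3)", embryo = "R1")
  expect_error(call_carrier_status(bad, fx$obs, link, fx$snps),
               "only defined for euploid")

  # insufficient informative SNPs gives inconclusive, never a guess
  few <- fx$snps[0, ]
  inc <- call_carrier_status(karyotype_call("EU1"), fx$obs, link, few)
  expect_equal(inc$call, "inconclusive")
})

test_that("votes are invariant to SNP and observation ordering", {
  fx <- phase_fixture(ado = 0.1, seed = 90)
  refs <- c("R1", "R2", "R3")
  base <- phase_derivative_from_references(fx$obs, fx$segs[refs], fx$spec,
                                           fx$snps, consistency = 0.75)
  set.seed(3)
  shuffled_obs <- fx$obs[sample(nrow(fx$obs)), ]
  shuffled_snps <- fx$snps[sample(nrow(fx$snps)), ]
  alt <- phase_derivative_from_references(shuffled_obs, fx$segs[rev(refs)],
                                          fx$spec, shuffled_snps,
                                          consistency = 0.75)
  expect_equal(alt$der_hap, base$der_hap)
  expect_equal(alt$votes_for + alt$votes_against,
               base$votes_for + base$votes_against)
})
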