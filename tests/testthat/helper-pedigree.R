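# shared tiny fixtures, built in code

# 2 x 1 kb genome with a SNP every 100 bp; breakpoints at 400 (q) / 300 (p)
tiny_genome <- function(seed = 42)
  toy_genome(c("c1", "c2"), lengths = 1000, snp_spacing = 100, seed = seed)

tiny_spec <- function(bp_a = 400, bp_b = 300)
  translocation_spec("c1", "c2", bp_a, bp_b, arm_a = "q", arm_b = "p")

# per-base copy number of gamete + normal partner complement, by brute force
brute_force_cn <- function(transmitted, spec, genome) {
  derivs <- build_derivatives(spec, genome)
  counts <- list()
  for (ch in c(spec$chrom_a, spec$chrom_b))
    counts[[ch]] <- rep(1L, chrom_length(genome, ch))  # partner copy
  bump <- function(chrom, start, end)
    counts[[chrom]][start:end] <<- counts[[chrom]][start:end] + 1L
  for (el in transmitted) {
    if (el == "A_normal") bump(spec$chrom_a, 1, chrom_length(genome, spec$chrom_a))
    else if (el == "B_normal") bump(spec$chrom_b, 1, chrom_length(genome, spec$chrom_b))
    else {
      d <- derivs[[el]]
      for (i in seq_len(nrow(d))) bump(d$chrom[i], d$start[i], d$end[i])
    }
  }
  counts
}

# true (unmerged) abnormal segments of an embryo, as the CNV caller would
# report them with perfect data
truth_segments <- function(truth) {
  s <- truth$cn_segments
  s <- s[s$cn != 2, , drop = FALSE]
  if (nrow(s) == 0) return(s)
  s$mosaic_pct <- NA_integer_
  rownames(s) <- NULL
  s
}

# small noiseless phased pedigree (3 reference + 2 euploid embryos) on a
# 2 x 1 Mb genome; used by the phasing tests and the acceptance properties
phase_fixture <- function(ado = 0, seed = 50) {
  g <- toy_genome(c("c1", "c2"), lengths = 1e6, snp_spacing = 2000, seed = 7)
  spec <- translocation_spec("c1", "c2", 400000, 300000, "q", "p")
  linkage <- c(a = "H2", b = "H1")
  bp <- data.frame(chrom = c("c1", "c2"), position = c(400000, 300000))
  snps <- select_informative_snps(g$snps, bp, spec, flank_window = 2e5)
  embryos <- list(
    R1 = c("der_a", "B_normal"), R2 = c("A_normal", "der_b"),
    R3 = c("der_a", "B_normal"),
    EU1 = c("A_normal", "B_normal"), EU2 = c("der_a", "der_b"))
  truths <- list(); obs <- list(); segs <- list()
  for (i in seq_along(embryos)) {
    id <- names(embryos)[i]
    truths[[id]] <- make_embryo(id, fixed_gamete(embryos[[id]], spec, g),
                                spec, g, linkage = linkage,
                                partner_hap = c(a = 1L, b = 2L))
    obs[[id]] <- simulate_snp_observations(truths[[id]], g, ado = ado,
                                           error_rate = 0, seed = seed + i)
    segs[[id]] <- truth_segments(truths[[id]])
  }
  list(genome = g, spec = spec, linkage = linkage, snps = snps,
       truths = truths, obs = do.call(rbind, obs), segs = segs)
}

# gamete object without random draw, for constructing specific embryos
fixed_gamete <- function(transmitted, spec, genome, mode = "manual") {
  cov <- gamete_coverage(transmitted, spec, genome)
  structure(list(mode = mode, transmitted = transmitted,
                 balanced = all(cov$copies == 1)), class = "gamete_spec")
}
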