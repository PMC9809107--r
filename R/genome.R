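#' Describe a balanced reciprocal translocation
#'
#' A `translocation_spec` records the carrier's t(A;B) event: the two
#' chromosomes involved, the base-pair position of each breakpoint, which arm
#' carries the exchanged distal fragment, and which parent is the carrier.
#'
#' @param chrom_a,chrom_b Chromosome identifiers (must differ).
#' @param bp_a,bp_b Breakpoint positions, 1-based. The breakpoint is the last
#'   base of the proximal fragment when the exchanged arm is `q`, and the last
#'   base of the distal fragment when it is `p`.
#' @param arm_a,arm_b `"p"` or `"q"`: the arm whose distal (telomeric)
#'   fragment is exchanged.
#' @param carrier_parent `"maternal"` or `"paternal"`.
#' @param band_a,band_b Optional cytoband labels for the breakpoints.
#' @return An object of class `translocation_spec`.
#' @examples
#' translocation_spec("chr2", "chr5", 125157514, 35465883, "q", "p")
#' @export
translocation_spec <- function(chrom_a, chrom_b, bp_a, bp_b, arm_a, arm_b,
                               carrier_parent = "maternal",
                               band_a = NA_character_, band_b = NA_character_) {
  stopifnot(length(chrom_a) == 1L, length(chrom_b) == 1L)
  if (identical(chrom_a, chrom_b))
    stop("a reciprocal translocation involves two different chromosomes")
  if (!arm_a %in% c("p", "q") || !arm_b %in% c("p", "q"))
    stop("arm tags must be 'p' or 'q'")
  if (!carrier_parent %in% c("maternal", "paternal"))
    stop("carrier_parent must be 'maternal' or 'paternal'")
  bp_a <- as.numeric(bp_a); bp_b <- as.numeric(bp_b)
  if (bp_a < 1 || bp_b < 1) stop("breakpoints are 1-based positions >= 1")
  structure(
    list(chrom_a = chrom_a, chrom_b = chrom_b, bp_a = bp_a, bp_b = bp_b,
         arm_a = arm_a, arm_b = arm_b, carrier_parent = carrier_parent,
         band_a = band_a, band_b = band_b),
    class = "translocation_spec")
}

#' @export
print.translocation_spec <- function(x, ...) {
  cat(sprintf("t(%s;%s) breakpoints %s:%s (%s arm) / %s:%s (%s arm), %s carrier\n",
              x$chrom_a, x$chrom_b,
              x$chrom_a, format(x$bp_a, big.mark = ","), x$arm_a,
              x$chrom_b, format(x$bp_b, big.mark = ","), x$arm_b,
              x$carrier_parent))
  invisible(x)
}

#' Breakpoint and exchanged arm for one chromosome of a translocation
#'
#' @param spec A [translocation_spec()].
#' @param chrom One of the two translocation chromosomes.
#' @return List with elements `bp` and `arm`.
#' @export
spec_side <- function(spec, chrom) {
  if (identical(chrom, spec$chrom_a)) list(bp = spec$bp_a, arm = spec$arm_a)
  else if (identical(chrom, spec$chrom_b)) list(bp = spec$bp_b, arm = spec$arm_b)
  else stop("chromosome ", chrom, " is not part of the translocation")
}

#' Construct a genome model
#'
#' A genome model bundles chromosome lengths with a phased SNP map for the
#' carrier parent (haplotypes H1/H2) and the partner parent's genotype at each
#' site. It is the coordinate system for the simulator and the phasing stages.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `h1`, `h2`
#'   (carrier haplotype alleles), `partner1`, `partner2` (partner genotype).
#' @return Object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, snps) {
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            all(c("chrom", "pos", "h1", "h2", "partner1", "partner2") %in% names(snps)))
  snps <- snps[order(match(snps$chrom, chromosomes$chrom), snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (anyDuplicated(p)) stop("duplicate SNP positions on ", ch)
    len <- chromosomes$length[chromosomes$chrom == ch]
    if (length(len) == 0) stop("SNPs on unknown chromosome ", ch)
    if (any(p < 1 | p > len)) stop("SNP position outside ", ch)
  }
  ok <- c("A", "C", "G", "T")
  if (!all(unlist(snps[c("h1", "h2", "partner1", "partner2")]) %in% ok))
    stop("alleles must be A/C/G/T")
  structure(list(chromosomes = chromosomes, snps = snps), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes (%s bp), %d SNPs\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","), nrow(x$snps)))
  invisible(x)
}

#' Length of a chromosome in a genome model
#' @param genome A [genome_model()].
#' @param chrom Chromosome id.
#' @return Integer length in bp.
#' @export
chrom_length <- function(genome, chrom) {
  len <- genome$chromosomes$length[genome$chromosomes$chrom == chrom]
  if (length(len) != 1) stop("unknown chromosome ", chrom)
  len
}

#' Toy two-chromosome genome for fast end-to-end runs
#'
#' Generates a small diploid genome (default two 5 Mb chromosomes with a SNP
#' every 2 kb) with phased carrier haplotypes and a partner genotype drawn so
#' that roughly a quarter of sites are fully informative (carrier
#' heterozygous, partner homozygous). Whole pipelines on this genome run in
#' seconds, which is the point.
#'
#' @param chrom_names Chromosome ids.
#' @param lengths Chromosome lengths (recycled).
#' @param snp_spacing Distance between successive SNPs in bp.
#' @param seed Integer seed; the map is reproducible.
#' @return A [genome_model()].
#' @export
toy_genome <- function(chrom_names = c("chrA", "chrB"), lengths = 5e6,
                       snp_spacing = 2000, seed = 100) {
  lengths <- rep_len(lengths, length(chrom_names))
  chromosomes <- data.frame(chrom = chrom_names, length = lengths,
                            stringsAsFactors = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  snps <- do.call(rbind, lapply(seq_along(chrom_names), function(i) {
    pos <- seq(snp_spacing, lengths[i] - 1, by = snp_spacing)
    n <- length(pos)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    carrier_het <- stats::runif(n) < 0.5
    partner_hom <- stats::runif(n) < 0.5
    partner_ref <- stats::runif(n) < 0.5
    p1 <- ifelse(partner_hom & !partner_ref, alt, ref)
    data.frame(chrom = chrom_names[i], pos = pos,
               h1 = ref,
               h2 = ifelse(carrier_het, alt, ref),
               partner1 = p1,
               partner2 = ifelse(partner_hom, p1, alt),
               stringsAsFactors = FALSE)
  }))
  genome_model(chromosomes, snps)
}

#' Default toy translocation matching the toy genome
#'
#' A q-arm/p-arm exchange between the two toy chromosomes, mirroring the
#' geometry of a t(2;5)(q;p) event at a desk scale.
#'
#' @param genome A [genome_model()]; breakpoints are placed at 46% and 34% of
#'   the two chromosome lengths.
#' @return A [translocation_spec()].
#' @export
toy_translocation <- function(genome = toy_genome()) {
  translocation_spec(genome$chromosomes$chrom[1], genome$chromosomes$chrom[2],
                     bp_a = 2345678, bp_b = 1711011,
                     arm_a = "q", arm_b = "p")
}

#' Validate a translocation against a genome
#'
#' Checks that both chromosomes exist and that each breakpoint lies strictly
#' inside its chromosome (1 <= bp < length).
#'
#' @param spec A [translocation_spec()].
#' @param genome A [genome_model()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_spec <- function(spec, genome) {
  for (side in list(c(spec$chrom_a, spec$bp_a), c(spec$chrom_b, spec$bp_b))) {
    len <- chrom_length(genome, side[1])
    bp <- as.numeric(side[2])
    if (bp < 1 || bp >= len)
      stop("breakpoint ", side[1], ":", side[2],
           " outside chromosome (length ", len, ")")
  }
  invisible(TRUE)
}

# preserve caller RNG state around internally seeded draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
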