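#' Simulate overdispersed binned read counts
#'
#' Draws one count per bin with mean `mu = m * cn / 2` from a negative
#' binomial with variance `(1 + dispersion) * mu`, i.e. `dispersion` is the
#' excess variance relative to Poisson, emulating the noisy coverage of
#' whole-genome-amplified single-embryo biopsies. `dispersion = 0`
#' degenerates to deterministic rounding of the mean (useful for exact
#' tests).
#'
#' @param expected_cn Per-bin expected copy number as returned by
#'   [true_copy_profile()] (`chrom,start,end,cn`).
#' @param m Mean count of a disomic (CN 2) bin; must be positive.
#' @param dispersion Non-negative overdispersion; default 0.1.
#' @param seed Integer seed.
#' @param embryo Embryo id to attach.
#' @return data.frame `chrom,start,end,count` of class `bin_counts`, with
#'   attributes `embryo` and `bin_width`.
#' @export
simulate_bin_counts <- function(expected_cn, m, dispersion = 0.1, seed = 1,
                                embryo = "sim") {
  if (m <= 0) stop("m must be positive")
  if (dispersion < 0) stop("dispersion must be non-negative")
  mu <- m * expected_cn$cn / 2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- if (dispersion == 0) round(mu)
            else stats::rnbinom(length(mu), mu = mu, size = mu / dispersion)
  out <- data.frame(chrom = expected_cn$chrom, start = expected_cn$start,
                    end = expected_cn$end, count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  class(out) <- c("bin_counts", "data.frame")
  attr(out, "embryo") <- embryo
  attr(out, "bin_width") <- attr(expected_cn, "bin_width")
  out
}

#' Simulate SNP allele observations for an embryo
#'
#' For each SNP the alleles of the haplotypes physically present in the
#' embryo (according to the transmitted gamete elements) are reported. Each
#' present distinct allele drops out independently with probability `ado`; if
#' all alleles at a site would drop, one survives (chosen with copy-number
#' weights), so a site always reports at least one allele — locus-level
#' dropout is not modeled. Genotyping errors replace a reported allele with a
#' random different base at rate `error_rate`.
#'
#' @param truth An [make_embryo()] result.
#' @param genome A [genome_model()].
#' @param ado Allele dropout probability in \[0,1\].
#' @param per_allele_depth Mean sequencing depth per surviving allele
#'   (Poisson, floored at 1).
#' @param error_rate Genotyping error probability in \[0,1\].
#' @param seed Integer seed.
#' @param sites Optional subset of the genome SNP table (same columns) to
#'   restrict simulation to, e.g. breakpoint flanks.
#' @return data.frame `embryo,chrom,pos,allele,depth`, one row per observed
#'   distinct allele.
#' @export
simulate_snp_observations <- function(truth, genome, ado = 0,
                                      per_allele_depth = 30, error_rate = 0,
                                      seed = 1, sites = NULL) {
  stopifnot(ado >= 0, ado <= 1, error_rate >= 0, error_rate <= 1)
  spec <- truth$spec
  snps <- if (is.null(sites)) genome$snps else sites
  snps <- snps[snps$chrom %in% c(spec$chrom_a, spec$chrom_b), , drop = FALSE]
  if (nrow(snps) == 0) return(NULL)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  S <- nrow(snps)
  # breakpoint region of each site (proximal = centromere side of the bp)
  is_a <- snps$chrom == spec$chrom_a
  bp <- ifelse(is_a, spec$bp_a, spec$bp_b)
  arm <- ifelse(is_a, spec$arm_a, spec$arm_b)
  region <- ifelse(arm == "q",
                   ifelse(snps$pos <= bp, "proximal", "distal"),
                   ifelse(snps$pos > bp, "proximal", "distal"))
  # carrier haplotypes present per chromosome/region, from the truth table
  fl <- truth$flank_haplotypes
  key <- paste(snps$chrom, region)
  hapstr <- fl$carrier_haps[match(key, paste(fl$chrom, fl$region))]
  haps <- strsplit(ifelse(is.na(hapstr), "", hapstr), ",")
  car1 <- vapply(haps, function(h) if (length(h) >= 1) h[1] else NA_character_, "")
  car2 <- vapply(haps, function(h) if (length(h) >= 2) h[2] else NA_character_, "")
  hap_allele <- function(hap)
    ifelse(is.na(hap), NA_character_, ifelse(hap == "H1", snps$h1, snps$h2))
  pn <- unname(truth$partner_hap[ifelse(is_a, "a", "b")])
  present <- cbind(hap_allele(car1), hap_allele(car2),
                   ifelse(pn == 1, snps$partner1, snps$partner2))
  long <- data.frame(site = rep(seq_len(S), 3), allele = as.vector(present),
                     stringsAsFactors = FALSE)
  long <- long[!is.na(long$allele), , drop = FALSE]
  # distinct alleles per site with copy counts (ADO acts per distinct allele)
  k <- paste(long$site, long$allele)
  copies <- as.vector(table(k)[k])
  distinct <- long[!duplicated(k), , drop = FALSE]
  distinct$copies <- copies[!duplicated(k)]
  distinct <- distinct[order(distinct$site), , drop = FALSE]
  keep <- stats::runif(nrow(distinct)) >= ado
  dropped_sites <- setdiff(unique(distinct$site), distinct$site[keep])
  for (s in dropped_sites) {  # retain one allele so the site never goes dark
    idx <- which(distinct$site == s)
    keep[idx[sample.int(length(idx), 1, prob = distinct$copies[idx])]] <- TRUE
  }
  obs <- distinct[keep, , drop = FALSE]
  err <- stats::runif(nrow(obs)) < error_rate
  if (any(err))
    obs$allele[err] <- vapply(obs$allele[err],
                              function(a) sample(setdiff(bases, a), 1), "")
  obs <- obs[!duplicated(paste(obs$site, obs$allele)), , drop = FALSE]
  out <- data.frame(embryo = truth$id,
                    chrom = snps$chrom[obs$site], pos = snps$pos[obs$site],
                    allele = obs$allele,
                    depth = pmax(1L, stats::rpois(nrow(obs), per_allele_depth)),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, genome$chromosomes$chrom), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Simulate long reads from a carrier genome
#'
#' Samples reads uniformly from the carrier's four molecules (the two normal
#' homologs and the two derivatives), so reads crossing a derivative junction
#' receive two alignment blocks with the correct breakend orientation. Reads
#' carry the SNP alleles of the haplotype physically present on the sampled
#' molecule, and a mean quality score drawn from a normal distribution so that
#' a configurable fraction falls below typical QC thresholds.
#'
#' @param genome A [genome_model()].
#' @param derivs A [build_derivatives()] result.
#' @param n Number of reads (> 0).
#' @param length_meanlog,length_sdlog Log-normal read-length parameters
#'   (defaults give a mean around 19 kb, emulating a long-read run).
#' @param qscore_mean,qscore_sd Normal distribution of per-read mean quality.
#' @param linkage Named vector `c(a=,b=)`: carrier haplotype on each
#'   derivative.
#' @param seed Integer seed.
#' @return Object of class `long_read_set`: list of data.frames `reads`
#'   (`read_id,length,mean_qscore,molecule,spans_junction`), `blocks`
#'   (`read_id,chrom,start,end,strand,read_start,read_end` in read order) and
#'   `snps` (`read_id,chrom,pos,allele`).
#' @export
simulate_long_reads <- function(genome, derivs, n,
                                length_meanlog = log(18000), length_sdlog = 0.35,
                                qscore_mean = 11, qscore_sd = 2.5,
                                linkage = c(a = "H1", b = "H1"), seed = 1) {
  if (n <= 0) stop("n must be positive")
  spec <- derivs$spec
  other <- function(h) if (h == "H1") "H2" else "H1"
  molecules <- list(
    A_normal = data.frame(chrom = spec$chrom_a, start = 1,
                          end = derivs$lengths["a"], strand = "+"),
    B_normal = data.frame(chrom = spec$chrom_b, start = 1,
                          end = derivs$lengths["b"], strand = "+"),
    der_a = derivs$der_a, der_b = derivs$der_b)
  mol_len <- vapply(molecules, derivative_length, 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  which_mol <- sample(names(molecules), n, replace = TRUE,
                      prob = mol_len / sum(mol_len))
  lens <- pmax(200, round(stats::rlnorm(n, length_meanlog, length_sdlog)))
  if (any(lens > mol_len[which_mol])) {
    warning("some read lengths exceed their molecule length; clipped")
    lens <- pmin(lens, mol_len[which_mol])
  }
  starts <- floor(stats::runif(n) * (mol_len[which_mol] - lens)) + 1
  qs <- stats::rnorm(n, qscore_mean, qscore_sd)
  hap_of_frag <- function(chrom)
    if (chrom == spec$chrom_a) linkage["a"] else linkage["b"]

  reads <- vector("list", n); blocks <- vector("list", n); snpobs <- vector("list", n)
  snp <- genome$snps
  for (i in seq_len(n)) {
    mol <- molecules[[which_mol[i]]]
    rid <- sprintf("read_%05d", i)
    s <- starts[i]; e <- s + lens[i] - 1
    # walk the molecule fragments, intersecting with [s, e] in molecule coords
    off <- 0; blk <- list()
    for (j in seq_len(nrow(mol))) {
      flen <- mol$end[j] - mol$start[j] + 1
      fs <- off + 1; fe <- off + flen     # fragment span in molecule coords
      ov_s <- max(s, fs); ov_e <- min(e, fe)
      if (ov_s <= ov_e) {
        if (mol$strand[j] == "+") {
          ref_s <- mol$start[j] + (ov_s - fs)
          ref_e <- mol$start[j] + (ov_e - fs)
        } else {
          ref_e <- mol$end[j] - (ov_s - fs)
          ref_s <- mol$end[j] - (ov_e - fs)
        }
        blk[[length(blk) + 1L]] <- data.frame(
          read_id = rid, chrom = mol$chrom[j], start = ref_s, end = ref_e,
          strand = mol$strand[j], read_start = ov_s - s + 1,
          read_end = ov_e - s + 1, stringsAsFactors = FALSE)
      }
      off <- off + flen
    }
    blk <- do.call(rbind, blk)
    spans <- nrow(blk) > 1 && length(unique(blk$chrom)) > 1
    reads[[i]] <- data.frame(read_id = rid, length = lens[i],
                             mean_qscore = qs[i], molecule = which_mol[i],
                             spans_junction = spans, stringsAsFactors = FALSE)
    blocks[[i]] <- blk
    # SNP alleles carried by this read, per block haplotype
    ob <- lapply(seq_len(nrow(blk)), function(j) {
      hit <- snp$chrom == blk$chrom[j] & snp$pos >= blk$start[j] &
             snp$pos <= blk$end[j]
      if (!any(hit)) return(NULL)
      sub <- snp[hit, , drop = FALSE]
      hap <- if (which_mol[i] == "A_normal") other(linkage["a"])
             else if (which_mol[i] == "B_normal") other(linkage["b"])
             else unname(hap_of_frag(blk$chrom[j]))
      data.frame(read_id = rid, chrom = sub$chrom, pos = sub$pos,
                 allele = if (hap == "H1") sub$h1 else sub$h2,
                 stringsAsFactors = FALSE)
    })
    ob <- do.call(rbind, ob)
    if (!is.null(ob)) snpobs[[i]] <- ob
  }
  structure(list(reads = do.call(rbind, reads),
                 blocks = do.call(rbind, blocks),
                 snps = do.call(rbind, snpobs[!vapply(snpobs, is.null, TRUE)])),
            class = "long_read_set")
}

#' @export
print.long_read_set <- function(x, ...) {
  cat(sprintf("long_read_set: %d reads (%d junction-spanning), %d blocks\n",
              nrow(x$reads), sum(x$reads$spans_junction), nrow(x$blocks)))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' Sequences are pseudo-random (seeded from the read index) since downstream
#' stages consume alignment blocks, not bases; the per-read quality line is
#' the phred+33 encoding of the read's rounded mean quality.
#'
#' @param reads A `long_read_set`.
#' @param path Output file.
#' @param seed Seed for the sequence generator.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  r <- reads$reads
  for (i in seq_len(nrow(r))) {
    seq <- paste(sample(c("A", "C", "G", "T"), r$length[i], replace = TRUE),
                 collapse = "")
    q <- max(0, min(93, round(r$mean_qscore[i])))
    writeLines(c(paste0("@", r$read_id[i]), seq, "+",
                 strrep(rawToChar(as.raw(q + 33L)), r$length[i])), con)
  }
  invisible(path)
}

#' Write read alignment blocks as a truth BED file
#'
#' One BED6 line per alignment block (0-based half-open, converted from the
#' internal 1-based inclusive coordinates), named by read id.
#'
#' @param reads A `long_read_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_truth_bed <- function(reads, path) {
  b <- reads$blocks
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   b$chrom, as.integer(b$start - 1), as.integer(b$end),
                   b$read_id, b$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write per-embryo SNP observations as TSV
#' @param obs Observation data.frame from [simulate_snp_observations()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_snp_tsv <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
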