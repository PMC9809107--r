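#' Select informative SNPs flanking the breakpoints
#'
#' Keeps sites within `flank_window` of a breakpoint on either translocation
#' chromosome that are fully informative: carrier parent heterozygous and
#' partner homozygous, so the transmitted carrier haplotype is identifiable
#' in an embryo. Each kept site is annotated with its flank (proximal =
#' centromere side of the breakpoint, distal = telomere side of the
#' exchanged arm).
#'
#' @param sites SNP table in the [genome_model()] layout
#'   (`chrom,pos,h1,h2,partner1,partner2`).
#' @param breakpoints A `breakpoint_estimates` data.frame (only `chrom` and
#'   `position` are used; either localization method works).
#' @param spec A [translocation_spec()].
#' @param flank_window Flank width in bp, default 2 Mb.
#' @return The informative subset with added `flank` and `bp` columns; warns
#'   when a proximal flank ends up with zero informative sites.
#' @export
select_informative_snps <- function(sites, breakpoints, spec,
                                    flank_window = 2e6) {
  out <- lapply(c(spec$chrom_a, spec$chrom_b), function(ch) {
    hit <- breakpoints$chrom == ch
    if (!any(hit)) return(NULL)
    bp <- breakpoints$position[which(hit)[1]]
    arm <- spec_side(spec, ch)$arm
    sub <- sites[sites$chrom == ch & abs(sites$pos - bp) <= flank_window, ,
                 drop = FALSE]
    informative <- sub$h1 != sub$h2 & sub$partner1 == sub$partner2
    sub <- sub[informative, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    sub$flank <- if (arm == "q") ifelse(sub$pos <= bp, "proximal", "distal")
                 else ifelse(sub$pos > bp, "proximal", "distal")
    sub$bp <- bp
    sub
  })
  out <- do.call(rbind, out)
  for (ch in c(spec$chrom_a, spec$chrom_b)) {
    if (is.null(out) || !any(out$chrom == ch & out$flank == "proximal"))
      warning("no informative SNPs on the proximal flank of ", ch,
              "; downstream carrier calls will be inconclusive")
  }
  if (!is.null(out)) rownames(out) <- NULL
  out
}

# Which carrier haplotype an embryo's observed alleles indicate, per site.
# For an informative site (carrier het h1/h2, partner hom a): when one
# carrier allele equals a, seeing the other allele proves its haplotype and
# its absence implies the shared one (vulnerable to dropout of the
# distinguishing allele); when both differ from a, either allele is directly
# diagnostic and seeing both or neither yields no call.
.transmitted_haps <- function(obs, sites) {
  if (is.null(obs) || nrow(obs) == 0) return(rep(NA_character_, nrow(sites)))
  obs_by <- split(obs$allele, paste(obs$chrom, obs$pos))
  vapply(seq_len(nrow(sites)), function(i) {
    O <- obs_by[[paste(sites$chrom[i], sites$pos[i])]]
    if (is.null(O)) return(NA_character_)
    h1 <- sites$h1[i]; h2 <- sites$h2[i]; a <- sites$partner1[i]
    if (h1 != a && h2 != a) {
      s1 <- h1 %in% O; s2 <- h2 %in% O
      if (s1 && !s2) "H1" else if (s2 && !s1) "H2" else NA_character_
    } else if (h1 == a) {
      if (h2 %in% O) "H2" else "H1"
    } else {
      if (h1 %in% O) "H1" else "H2"
    }
  }, "")
}

.other_hap <- function(h) ifelse(h == "H1", "H2", "H1")

.linkage_frame <- function(chroms) {
  data.frame(chrom = chroms, der_hap = NA_character_,
             votes_for = 0L, votes_against = 0L, consistency = NA_real_,
             source = NA_character_, stringsAsFactors = FALSE)
}

#' Phase the derivative haplotypes from reference embryos
#'
#' A reference embryo that is monosomic for the distal segment of chromosome
#' X received der(X): at every proximal-flank informative SNP its single
#' carrier allele is the allele physically on der(X), so each such SNP votes
#' for that haplotype. A reference embryo whose distal X segment is trisomic
#' received the normal X homolog instead, so its proximal carrier allele
#' votes for the *other* haplotype. SNPs inside monosomic regions serve as a
#' cross-check (the carrier allele must be absent there); violations are
#' counted, not voted. Votes pool over embryos and SNPs; the linkage for a
#' chromosome is emitted only when the winning haplotype holds at least the
#' consistency fraction of votes.
#'
#' @param observations SNP observation data.frame for the reference embryos
#'   (`embryo,chrom,pos,allele`).
#' @param ref_segments Named list (by embryo id) of called segment
#'   data.frames (`chrom,start,end,cn,mosaic_pct`).
#' @param spec A [translocation_spec()].
#' @param snps Informative SNP table from [select_informative_snps()].
#' @param consistency Minimum vote consistency, default 0.9.
#' @return data.frame of class `haplotype_linkage`
#'   (`chrom,der_hap,votes_for,votes_against,consistency,source`) with a
#'   `crosscheck_violations` attribute.
#' @export
phase_derivative_from_references <- function(observations, ref_segments, spec,
                                             snps, consistency = 0.9) {
  if (length(ref_segments) == 0)
    stop("no reference embryos: derivative haplotypes cannot be phased")
  chroms <- c(spec$chrom_a, spec$chrom_b)
  votes <- list(); discord <- list(); violations <- 0L
  for (embryo in names(ref_segments)) {
    segs <- ref_segments[[embryo]]
    obs <- observations[observations$embryo == embryo, , drop = FALSE]
    for (ch in chroms) {
      sd_ <- spec_side(spec, ch)
      s <- segs[segs$chrom == ch & is.na(segs$mosaic_pct) & segs$cn != 2, ,
                drop = FALSE]
      if (nrow(s) == 0) next
      mid <- (s$start + s$end) / 2
      distal <- if (sd_$arm == "q") mid > sd_$bp else mid <= sd_$bp
      received <- if (any(distal & s$cn < 2)) "derivative"
                  else if (any(distal & s$cn > 2)) "normal"
                  else next
      prox <- snps[snps$chrom == ch & snps$flank == "proximal", , drop = FALSE]
      if (nrow(prox) == 0) next
      hap <- .transmitted_haps(obs, prox)
      hap <- hap[!is.na(hap)]
      der_vote <- if (received == "derivative") hap else .other_hap(hap)
      votes[[length(votes) + 1L]] <- data.frame(
        embryo = embryo, chrom = ch, vote = der_vote,
        stringsAsFactors = FALSE)
      # cross-check: in the monosomic distal region the carrier allele must
      # be invisible (only the partner allele remains)
      if (received == "derivative") {
        dsnp <- snps[snps$chrom == ch & snps$flank == "distal", , drop = FALSE]
        if (nrow(dsnp) > 0) {
          h <- .transmitted_haps(obs, dsnp)
          # a confident carrier-haplotype call in a carrier-free region can
          # only come from dropout/error of the expected pattern
          direct <- dsnp$h1 != dsnp$partner1 & dsnp$h2 != dsnp$partner1
          violations <- violations + sum(!is.na(h) & direct)
        }
      }
    }
  }
  out <- .linkage_frame(chroms)
  out$source <- "reference_embryos"
  votes <- if (length(votes)) do.call(rbind, votes) else NULL
  for (i in seq_along(chroms)) {
    v <- votes$vote[votes$chrom == chroms[i]]
    if (length(v) == 0) next
    n1 <- sum(v == "H1"); n2 <- sum(v == "H2")
    win <- if (n1 >= n2) "H1" else "H2"
    cons <- max(n1, n2) / (n1 + n2)
    if (cons < consistency) {
      bad <- votes[votes$chrom == chroms[i] & votes$vote != win, , drop = FALSE]
      stop("phase not resolved on ", chroms[i], ": vote consistency ",
           sprintf("%.2f", cons), " below ", consistency,
           " (discordant votes from embryos ",
           paste(unique(bad$embryo), collapse = ", "), ")")
    }
    out$der_hap[i] <- win
    out$votes_for[i] <- max(n1, n2)
    out$votes_against[i] <- min(n1, n2)
    out$consistency[i] <- cons
  }
  class(out) <- c("haplotype_linkage", "data.frame")
  attr(out, "crosscheck_violations") <- violations
  out
}

#' Phase the derivative haplotypes directly from junction-spanning reads
#'
#' A read spanning a derivative junction lies on a derivative molecule, so
#' every informative SNP allele it carries belongs to the derivative
#' haplotype of that SNP's chromosome. Per SNP, supporting reads vote by
#' majority; per-SNP calls then pool into a per-chromosome linkage.
#'
#' @param reads A `long_read_set` (after QC).
#' @param clusters A [detect_junctions()] result; member reads define the
#'   junction-spanning set.
#' @param snps Informative SNP table from [select_informative_snps()].
#' @param spec A [translocation_spec()].
#' @param consistency Minimum vote consistency, default 0.9.
#' @return A `haplotype_linkage` data.frame (source `junction_reads`); when
#'   no junction read covers an informative SNP the linkage is `NA` with a
#'   message, and downstream carrier calls become inconclusive.
#' @export
phase_from_junction_reads <- function(reads, clusters, snps, spec,
                                      consistency = 0.9) {
  chroms <- c(spec$chrom_a, spec$chrom_b)
  out <- .linkage_frame(chroms)
  out$source <- "junction_reads"
  class(out) <- c("haplotype_linkage", "data.frame")
  jids <- unique(unlist(attr(clusters, "members")))
  ob <- reads$snps
  if (length(jids) == 0 || is.null(ob) || nrow(ob) == 0) {
    message("no junction-spanning reads with SNP observations; ",
            "junction-read phasing is inconclusive")
    return(out)
  }
  ob <- ob[ob$read_id %in% jids, , drop = FALSE]
  key <- paste(snps$chrom, snps$pos)
  ob <- ob[paste(ob$chrom, ob$pos) %in% key, , drop = FALSE]
  if (nrow(ob) == 0) {
    message("no junction-spanning read covers an informative SNP; ",
            "junction-read phasing is inconclusive")
    return(out)
  }
  idx <- match(paste(ob$chrom, ob$pos), key)
  ob$hap <- ifelse(ob$allele == snps$h1[idx], "H1",
                   ifelse(ob$allele == snps$h2[idx], "H2", NA))
  ob <- ob[!is.na(ob$hap), , drop = FALSE]
  # per-SNP majority over supporting reads, then pool per chromosome
  site_vote <- function(haps) {
    n1 <- sum(haps == "H1"); n2 <- sum(haps == "H2")
    if (n1 == n2) NA_character_ else if (n1 > n2) "H1" else "H2"
  }
  per_site <- tapply(ob$hap, paste(ob$chrom, ob$pos), site_vote)
  site_chrom <- sub(" .*$", "", names(per_site))
  for (i in seq_along(chroms)) {
    v <- per_site[site_chrom == chroms[i]]
    v <- v[!is.na(v)]
    if (length(v) == 0) next
    n1 <- sum(v == "H1"); n2 <- sum(v == "H2")
    win <- if (n1 >= n2) "H1" else "H2"
    cons <- max(n1, n2) / (n1 + n2)
    if (cons < consistency) {
      stop("phase not resolved on ", chroms[i],
           " from junction reads: vote consistency ",
           sprintf("%.2f", cons), " below ", consistency,
           " (discordant SNPs at ",
           paste(utils::head(sub("^.* ", "", names(v)[v != win]), 5),
                 collapse = ", "), ")")
    }
    out$der_hap[i] <- win
    out$votes_for[i] <- max(n1, n2)
    out$votes_against[i] <- min(n1, n2)
    out$consistency[i] <- cons
  }
  out
}

#' Call an euploid embryo carrier or non-carrier
#'
#' For each translocation chromosome the proximal-flank informative SNPs
#' determine by majority vote which carrier haplotype the embryo received.
#' If on both chromosomes the transmitted haplotype is the derivative-linked
#' one the embryo is a balanced `carrier`; if both are normal-linked it is a
#' `non_carrier`; disagreement between the chromosomes, unresolved linkage
#' or insufficient SNP evidence gives `inconclusive`. Carrier calls are only
#' defined for euploid (balanced) embryos.
#'
#' @param call The embryo's [karyotype_call()]; must be euploid.
#' @param observations The embryo's SNP observations
#'   (`embryo,chrom,pos,allele`).
#' @param linkage A resolved `haplotype_linkage`.
#' @param snps Informative SNP table from [select_informative_snps()].
#' @param min_snps Minimum voting SNPs per chromosome, default 5.
#' @param majority Minimum majority fraction, default 0.8.
#' @return Object of class `carrier_call`: `embryo`, `call`
#'   (`carrier`/`non_carrier`/`inconclusive`) and per-chromosome evidence.
#' @export
call_carrier_status <- function(call, observations, linkage, snps,
                                min_snps = 5, majority = 0.8) {
  if (!isTRUE(call$is_euploid))
    stop("carrier status is only defined for euploid embryos; embryo ",
         call$embryo, " has unbalanced segments")
  obs <- observations[observations$embryo == call$embryo, , drop = FALSE]
  chroms <- linkage$chrom
  ev <- data.frame(chrom = chroms, transmitted = NA_character_,
                   n_support = 0L, n_conflict = 0L,
                   origin = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(chroms)) {
    if (is.na(linkage$der_hap[i])) next
    prox <- snps[snps$chrom == chroms[i] & snps$flank == "proximal", ,
                 drop = FALSE]
    if (nrow(prox) == 0) next
    hap <- .transmitted_haps(obs, prox)
    hap <- hap[!is.na(hap)]
    if (length(hap) < min_snps) next
    n1 <- sum(hap == "H1"); n2 <- sum(hap == "H2")
    win <- if (n1 >= n2) "H1" else "H2"
    if (max(n1, n2) / (n1 + n2) < majority) next
    ev$transmitted[i] <- win
    ev$n_support[i] <- max(n1, n2)
    ev$n_conflict[i] <- min(n1, n2)
    ev$origin[i] <- if (win == linkage$der_hap[i]) "derivative" else "normal"
  }
  verdict <- if (any(is.na(ev$origin))) "inconclusive"
             else if (all(ev$origin == "derivative")) "carrier"
             else if (all(ev$origin == "normal")) "non_carrier"
             else "inconclusive"
  structure(list(embryo = call$embryo, call = verdict, evidence = ev),
            class = "carrier_call")
}

#' @export
print.carrier_call <- function(x, ...) {
  cat(sprintf("embryo %s: %s\n", x$embryo, x$call))
  print(x$evidence)
  invisible(x)
}
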