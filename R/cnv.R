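#' Normalize bin counts to copy-number estimates
#'
#' Per-bin copy number is `2 * count / median autosomal count`, with the
#' median taken over all autosomal bins (chromosome names containing X or Y
#' are excluded from the median but still normalized).
#'
#' @param counts A [simulate_bin_counts()] result or any data.frame with
#'   `chrom,start,end,count`.
#' @return The input with an added `cn` column, class `cn_bins`.
#' @export
normalize_counts <- function(counts) {
  autosomal <- !grepl("X|Y", counts$chrom)
  if (!any(autosomal)) autosomal <- rep(TRUE, nrow(counts))
  med <- stats::median(counts$count[autosomal])
  if (!is.finite(med) || med <= 0) stop("all autosomal bin counts are zero")
  out <- counts
  out$cn <- 2 * counts$count / med
  class(out) <- c("cn_bins", "data.frame")
  attr(out, "embryo") <- attr(counts, "embryo")
  attr(out, "bin_width") <- attr(counts, "bin_width")
  out
}

#' Aggregate consecutive bins
#'
#' Sums counts over groups of `factor` consecutive bins per chromosome, for a
#' coarse genome-wide segmentation pass before fine re-segmentation.
#'
#' @param counts Bin counts (`chrom,start,end,count`).
#' @param factor Number of consecutive bins to merge.
#' @return Aggregated bin counts.
#' @export
aggregate_bins <- function(counts, factor) {
  stopifnot(factor >= 1)
  out <- do.call(rbind, lapply(unique(counts$chrom), function(ch) {
    b <- counts[counts$chrom == ch, , drop = FALSE]
    grp <- (seq_len(nrow(b)) - 1) %/% factor
    data.frame(chrom = ch,
               start = tapply(b$start, grp, min),
               end = tapply(b$end, grp, max),
               count = tapply(b$count, grp, sum),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- class(counts)
  attr(out, "embryo") <- attr(counts, "embryo")
  bw <- attr(counts, "bin_width")
  if (!is.null(bw)) attr(out, "bin_width") <- bw * factor
  out
}

#' Segment a per-bin copy-number profile
#'
#' Recursive binary segmentation on mean shift: within each (sub)profile the
#' candidate cut maximizing the normalized mean difference between the two
#' sides is accepted when the raw mean change is at least `threshold` copies
#' and both sides keep at least `min_seg_bins` bins; accepted cuts recurse.
#' The boundary of a segment is reported at the first base of its first bin
#' (i.e. the first bin of the right-hand segment), so a clean 2-to-3 step
#' after bin k is reported at position `k * bin_width + 1`.
#'
#' @param cn_bins A [normalize_counts()] result (`chrom,start,end,cn`).
#' @param min_seg_bins Minimum bins per segment (>= 2).
#' @param threshold Minimum mean copy-number change to accept a cut.
#' @return data.frame `chrom,start,end,mean_cn,n_bins` covering every bin
#'   exactly once, class `cn_segments`.
#' @export
segment_profile <- function(cn_bins, min_seg_bins = 3, threshold = 0.3) {
  stopifnot(min_seg_bins >= 2)
  seg_one <- function(x) {
    # returns cut indices (last bin of left part) within x, recursively
    n <- length(x)
    if (n < 2 * min_seg_bins) return(integer())
    ks <- seq(min_seg_bins, n - min_seg_bins)
    csum <- cumsum(x)
    ml <- csum[ks] / ks
    mr <- (csum[n] - csum[ks]) / (n - ks)
    d <- abs(ml - mr)
    stat <- d * sqrt(ks * (n - ks) / n)   # CBS-style location statistic
    k <- ks[which.max(stat)]
    if (abs(mean(x[1:k]) - mean(x[(k + 1):n])) < threshold) return(integer())
    c(seg_one(x[1:k]), k, k + seg_one(x[(k + 1):n]))
  }
  out <- do.call(rbind, lapply(unique(cn_bins$chrom), function(ch) {
    b <- cn_bins[cn_bins$chrom == ch, , drop = FALSE]
    cuts <- sort(seg_one(b$cn))
    bounds <- c(0, cuts, nrow(b))
    do.call(rbind, lapply(seq_len(length(bounds) - 1), function(i) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      data.frame(chrom = ch, start = b$start[idx[1]],
                 end = b$end[idx[length(idx)]],
                 mean_cn = mean(b$cn[idx]), n_bins = length(idx),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("cn_segments", "data.frame")
  attr(out, "embryo") <- attr(cn_bins, "embryo")
  attr(out, "bin_width") <- attr(cn_bins, "bin_width")
  out
}

#' Call integer copy number and mosaic fraction from a segment mean
#'
#' Deviation `d = mean - 2`: below 0.2 in magnitude the segment is normal
#' (x2); between 0.2 and 0.7 it is called mosaic, CN 3 for gains and CN 1 for
#' losses, with the mosaic fraction `|d|` reported as a whole percentage
#' (a mean of 2.31 is a trisomic mosaic at ~31%); beyond 0.7 the call is the
#' rounded integer copy number clamped to 0..4.
#'
#' @param mean_cn Segment mean copy number (>= 0).
#' @return List with `cn` (integer) and `mosaic_pct` (whole percent or `NA`).
#' @export
call_segment_cn <- function(mean_cn) {
  stopifnot(mean_cn >= 0)
  d <- mean_cn - 2
  if (abs(d) < 0.2) list(cn = 2L, mosaic_pct = NA_integer_)
  else if (abs(d) <= 0.7)
    list(cn = if (d > 0) 3L else 1L, mosaic_pct = as.integer(round(abs(d) * 100)))
  else list(cn = max(0L, min(4L, as.integer(round(mean_cn)))),
            mosaic_pct = NA_integer_)
}

#' Annotate segments with copy-number calls
#'
#' Applies [call_segment_cn()] to every segment and keeps only abnormal ones
#' (CN != 2 or mosaic), which is what a karyotype string reports.
#'
#' @param segments A [segment_profile()] result.
#' @return The abnormal segments with `cn` and `mosaic_pct` columns.
#' @export
call_segments <- function(segments) {
  calls <- lapply(segments$mean_cn, call_segment_cn)
  segments$cn <- vapply(calls, function(x) x$cn, 0L)
  segments$mosaic_pct <- vapply(calls, function(x) x$mosaic_pct, 0L)
  out <- segments[segments$cn != 2L | !is.na(segments$mosaic_pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an embryo from its karyotype call
#'
#' An embryo is a *reference embryo* (class `reference_unbalanced`) when it
#' carries at least one non-mosaic unbalanced segment on each of the two
#' translocation chromosomes — such embryos received one derivative and so
#' expose both breakpoints and the derivative haplotypes. Embryos with no
#' segment calls are `euploid`; anything else (including mosaic-only events
#' and imbalances of other chromosomes) is `other_abnormal`.
#'
#' @param call A [karyotype_call()] (or anything with `segments` and
#'   `is_euploid`).
#' @param spec A [translocation_spec()].
#' @return List of class `embryo_class` with `embryo`, `class` and
#'   `chroms_involved`.
#' @export
classify_embryo <- function(call, spec) {
  segs <- call$segments
  norm <- function(ch) sub("^chr", "", ch)
  cls <- if (is.null(segs) || nrow(segs) == 0) "euploid" else {
    nm <- is.na(segs$mosaic_pct)
    on_a <- nm & norm(segs$chrom) == norm(spec$chrom_a)
    on_b <- nm & norm(segs$chrom) == norm(spec$chrom_b)
    if (any(on_a) && any(on_b)) "reference_unbalanced" else "other_abnormal"
  }
  structure(list(embryo = call$embryo,
                 class = cls,
                 chroms_involved = if (is.null(segs)) character()
                                   else unique(segs$chrom)),
            class = "embryo_class")
}

#' Select the reference embryos from a set of karyotype calls
#'
#' @param calls List of [karyotype_call()] objects.
#' @param spec A [translocation_spec()].
#' @return Character vector of reference embryo ids.
#' @export
select_reference_embryos <- function(calls, spec) {
  cls <- vapply(calls, function(x) classify_embryo(x, spec)$class, "")
  ids <- vapply(calls, function(x) x$embryo, "")
  ids[cls == "reference_unbalanced"]
}
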