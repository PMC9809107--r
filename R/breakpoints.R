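#' Quality-filter long reads
#'
#' Removes reads whose mean quality score is strictly below the threshold;
#' a read exactly at the threshold is kept. Filtering is idempotent and
#' order-independent.
#'
#' @param reads A `long_read_set` or a data.frame with a `mean_qscore`
#'   column.
#' @param min_qscore Threshold (default 7).
#' @return Same type as the input, with failing reads (and their blocks and
#'   SNP observations) removed.
#' @export
qc_filter_reads <- function(reads, min_qscore = 7) {
  if (inherits(reads, "long_read_set")) {
    if (any(!is.finite(reads$reads$mean_qscore))) stop("non-finite qscores")
    keep <- reads$reads$mean_qscore >= min_qscore
    ids <- reads$reads$read_id[keep]
    structure(list(reads = reads$reads[keep, , drop = FALSE],
                   blocks = reads$blocks[reads$blocks$read_id %in% ids, , drop = FALSE],
                   snps = if (is.null(reads$snps)) NULL
                          else reads$snps[reads$snps$read_id %in% ids, , drop = FALSE]),
              class = "long_read_set")
  } else {
    if (any(!is.finite(reads$mean_qscore))) stop("non-finite qscores")
    reads[reads$mean_qscore >= min_qscore, , drop = FALSE]
  }
}

#' Summary statistics of a read set
#'
#' N50 is the largest read length L such that reads of length >= L together
#' contain at least half of all sequenced bases (largest-first cumulative
#' scan); depth is total bases divided by genome size.
#'
#' @param reads A `long_read_set` or data.frame with a `length` column.
#' @param genome_size Genome size in bp (> 0).
#' @return List of class `read_stats`: `n_reads`, `total_bases`,
#'   `mean_length`, `n50`, `depth`.
#' @export
read_stats <- function(reads, genome_size) {
  stopifnot(genome_size > 0)
  lens <- if (inherits(reads, "long_read_set")) reads$reads$length else reads$length
  if (length(lens) == 0) {
    warning("read set is empty; statistics are zero")
    return(structure(list(n_reads = 0L, total_bases = 0, mean_length = 0,
                          n50 = 0, depth = 0), class = "read_stats"))
  }
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  structure(list(n_reads = length(lens), total_bases = total,
                 mean_length = mean(lens), n50 = n50,
                 depth = total / genome_size),
            class = "read_stats")
}

#' @export
print.read_stats <- function(x, ...) {
  cat(sprintf("%d reads, %.0f bases, mean %.0f bp, N50 %.0f bp, depth %.2fx\n",
              x$n_reads, x$total_bases, x$mean_length, x$n50, x$depth))
  invisible(x)
}

#' Localize breakpoints from reference-embryo CNV boundaries
#'
#' For each translocation chromosome, every reference embryo contributes the
#' copy-state change edge of its non-mosaic unbalanced segments that lies
#' closest to the centromere on the exchanged arm (adjacent same-direction
#' segments are merged first; edges at the chromosome termini are ignored).
#' Boundaries are snapped to the bin grid; the representative is the modal
#' grid position (median on ties, then the smaller coordinate). The reported
#' half-window is the larger of the bin width and half the spread of the
#' member boundaries.
#'
#' @param segment_lists Named list (by embryo) of called segment data.frames
#'   (`chrom,start,end,cn,mosaic_pct`) for the reference embryos.
#' @param spec A [translocation_spec()].
#' @param bin_width Bin width of the CNV grid in bp.
#' @param chrom_lengths Named vector of chromosome lengths (for terminus
#'   detection); defaults assume segments end at the observed maxima.
#' @return data.frame of class `breakpoint_estimates` with columns
#'   `chrom,position,half_window,method,support`, one row per translocation
#'   chromosome.
#' @export
localize_from_cnv <- function(segment_lists, spec, bin_width,
                              chrom_lengths = NULL) {
  if (length(segment_lists) == 0)
    stop("no reference embryos: translocation carrier status cannot be ",
         "resolved without at least one embryo unbalanced on both ",
         "translocation chromosomes")
  snap <- function(p) floor((p - 1) / bin_width) * bin_width + 1
  one_side <- function(chrom) {
    arm <- spec_side(spec, chrom)$arm
    boundaries <- numeric()
    for (embryo in names(segment_lists)) {
      segs <- segment_lists[[embryo]]
      segs <- segs[segs$chrom == chrom & is.na(segs$mosaic_pct) & segs$cn != 2,
                   , drop = FALSE]
      if (nrow(segs) == 0) next
      segs <- segs[order(segs$start), , drop = FALSE]
      # merge touching segments with the same direction
      merged <- segs[1, , drop = FALSE]
      for (i in seq_len(nrow(segs))[-1]) {
        n <- nrow(merged)
        same_dir <- (merged$cn[n] > 2) == (segs$cn[i] > 2)
        if (same_dir && segs$start[i] <= merged$end[n] + 1)
          merged$end[n] <- max(merged$end[n], segs$end[i])
        else merged <- rbind(merged, segs[i, ])
      }
      edges <- c(merged$start, merged$end + 1)
      len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
               chrom_lengths[[chrom]] else max(merged$end)
      edges <- edges[edges > 1 & edges <= len]
      if (length(edges) == 0) next
      boundaries <- c(boundaries,
                      if (arm == "q") min(edges) else max(edges))
    }
    if (length(boundaries) == 0)
      stop("no usable unbalanced segment on ", chrom, " in any reference embryo")
    grid <- snap(boundaries)
    rep_pos <- .modal_position(grid)
    data.frame(chrom = chrom, position = rep_pos,
               half_window = max(bin_width, (max(grid) - min(grid)) / 2),
               method = "cnv_boundary", support = length(boundaries),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(spec$chrom_a), one_side(spec$chrom_b))
  class(out) <- c("breakpoint_estimates", "data.frame")
  out
}

# deterministic representative: mode, then median of modal values, then the
# smaller coordinate
.modal_position <- function(x) {
  tab <- table(x)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  med <- stats::median(modal)
  if (med %in% modal) med else min(modal[modal >= med])
}

#' Detect interchromosomal junctions from split alignments
#'
#' Every pair of consecutive alignment blocks of a read that maps to two
#' different chromosomes yields a candidate breakend pair (the junction-facing
#' coordinate of each block, with its strand). Candidates with the same
#' chromosome pair and orientation are clustered greedily: a candidate within
#' `tolerance` bp of a cluster's current representative on both sides joins
#' it. Final representatives are the modal coordinate per side (median on
#' ties, then smaller); clusters below `min_support` reads are discarded.
#' Reciprocal partner clusters — same chromosome pair, opposite orientation,
#' representatives offset by at most 1 bp on both sides — are tagged with a
#' common translocation id.
#'
#' @param blocks data.frame of alignment blocks
#'   (`read_id,chrom,start,end,strand,read_start`), as produced by the
#'   simulator or [read_split_alignments_sam()].
#' @param tolerance Clustering tolerance in bp (default 10).
#' @param min_support Minimum supporting reads per cluster (default 3).
#' @return data.frame of class `junction_clusters` with columns
#'   `chrom_a,pos_a,strand_a,chrom_b,pos_b,strand_b,support,translocation`,
#'   plus a `members` attribute (list of read-id vectors per cluster).
#' @export
detect_junctions <- function(blocks, tolerance = 10, min_support = 3) {
  cands <- .junction_candidates(blocks)
  empty <- data.frame(chrom_a = character(), pos_a = numeric(),
                      strand_a = character(), chrom_b = character(),
                      pos_b = numeric(), strand_b = character(),
                      support = integer(), translocation = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(cands) == 0) {
    class(empty) <- c("junction_clusters", "data.frame")
    attr(empty, "members") <- list()
    return(empty)
  }
  key <- paste(cands$chrom_a, cands$chrom_b, cands$strand_a, cands$strand_b)
  clusters <- list()
  for (grp in split(cands, key)) {
    grp <- grp[order(grp$pos_a, grp$pos_b), , drop = FALSE]
    cur <- NULL
    for (i in seq_len(nrow(grp))) {
      if (!is.null(cur) &&
          abs(grp$pos_a[i] - cur$pos_a[1]) <= tolerance &&
          abs(grp$pos_b[i] - cur$pos_b[1]) <= tolerance) {
        cur <- rbind(cur, grp[i, ])
      } else {
        if (!is.null(cur)) clusters[[length(clusters) + 1L]] <- cur
        cur <- grp[i, , drop = FALSE]
      }
    }
    if (!is.null(cur)) clusters[[length(clusters) + 1L]] <- cur
  }
  clusters <- Filter(function(cl) nrow(cl) >= min_support, clusters)
  if (length(clusters) == 0) {
    class(empty) <- c("junction_clusters", "data.frame")
    attr(empty, "members") <- list()
    return(empty)
  }
  out <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(chrom_a = cl$chrom_a[1],
               pos_a = .modal_position(cl$pos_a), strand_a = cl$strand_a[1],
               chrom_b = cl$chrom_b[1],
               pos_b = .modal_position(cl$pos_b), strand_b = cl$strand_b[1],
               support = nrow(cl), stringsAsFactors = FALSE)))
  members <- lapply(clusters, function(cl) unique(cl$read_id))
  ord <- order(out$chrom_a, out$chrom_b, out$pos_a, out$pos_b)
  out <- out[ord, , drop = FALSE]; members <- members[ord]
  rownames(out) <- NULL
  # pair reciprocal clusters into one translocation
  out$translocation <- NA_integer_
  tid <- 0L
  for (i in seq_len(nrow(out))) {
    if (!is.na(out$translocation[i])) next
    tid <- tid + 1L
    out$translocation[i] <- tid
    if (i < nrow(out)) for (j in (i + 1):nrow(out)) {
      if (is.na(out$translocation[j]) &&
          out$chrom_a[j] == out$chrom_a[i] && out$chrom_b[j] == out$chrom_b[i] &&
          abs(out$pos_a[j] - out$pos_a[i]) <= 1 &&
          abs(out$pos_b[j] - out$pos_b[i]) <= 1 &&
          (out$strand_a[j] != out$strand_a[i] ||
           out$strand_b[j] != out$strand_b[i])) {
        out$translocation[j] <- tid
      }
    }
  }
  class(out) <- c("junction_clusters", "data.frame")
  attr(out, "members") <- members
  out
}

# candidate breakend pairs from consecutive blocks on different chromosomes,
# canonically ordered so chrom_a < chrom_b
.junction_candidates <- function(blocks) {
  res <- list()
  for (rid in unique(blocks$read_id)) {
    b <- blocks[blocks$read_id == rid, , drop = FALSE]
    b <- b[order(b$read_start), , drop = FALSE]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      if (b$chrom[i] == b$chrom[i + 1]) next
      # junction-facing coordinate: 3' end of the left block in read
      # orientation, 5' end of the right block
      p1 <- if (b$strand[i] == "+") b$end[i] else b$start[i]
      p2 <- if (b$strand[i + 1] == "+") b$start[i + 1] else b$end[i + 1]
      c1 <- b$chrom[i]; c2 <- b$chrom[i + 1]
      s1 <- b$strand[i]; s2 <- b$strand[i + 1]
      if (c1 > c2) {  # canonical order
        tmp <- c(c1, p1, s1); c1 <- c2; p1 <- p2; s1 <- s2
        c2 <- tmp[1]; p2 <- as.numeric(tmp[2]); s2 <- tmp[3]
      }
      res[[length(res) + 1L]] <- data.frame(
        read_id = rid, chrom_a = c1, pos_a = p1, strand_a = s1,
        chrom_b = c2, pos_b = p2, strand_b = s2, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    data.frame(read_id = character(), chrom_a = character(), pos_a = numeric(),
               strand_a = character(), chrom_b = character(), pos_b = numeric(),
               strand_b = character(), stringsAsFactors = FALSE)
  else do.call(rbind, res)
}

#' Split-read breakpoint estimates from junction clusters
#'
#' Converts each cluster into two single-base breakpoint estimates (one per
#' chromosome side) with `half_window = 0`.
#'
#' @param clusters A [detect_junctions()] result.
#' @return data.frame of class `breakpoint_estimates`.
#' @export
junctions_to_estimates <- function(clusters) {
  if (nrow(clusters) == 0)
    out <- data.frame(chrom = character(), position = numeric(),
                      half_window = numeric(), method = character(),
                      support = integer(), stringsAsFactors = FALSE)
  else
    out <- data.frame(
      chrom = c(clusters$chrom_a, clusters$chrom_b),
      position = c(clusters$pos_a, clusters$pos_b),
      half_window = 0,
      method = "split_read",
      support = rep(clusters$support, 2),
      stringsAsFactors = FALSE)
  class(out) <- c("breakpoint_estimates", "data.frame")
  out
}

#' Concordance between a CNV-window and a split-read breakpoint estimate
#'
#' @param cnv_estimate,split_estimate Single rows of a
#'   `breakpoint_estimates` table on the same chromosome.
#' @return List with `chrom`, `distance` (bp) and `within_window` (whether
#'   the split-read position falls inside the CNV half-window).
#' @export
check_concordance <- function(cnv_estimate, split_estimate) {
  if (cnv_estimate$chrom != split_estimate$chrom)
    stop("estimates are on different chromosomes: ",
         cnv_estimate$chrom, " vs ", split_estimate$chrom)
  d <- abs(cnv_estimate$position - split_estimate$position)
  list(chrom = cnv_estimate$chrom, distance = d,
       within_window = d <= cnv_estimate$half_window)
}

#' Read split alignments from a minimal SAM file
#'
#' Accepts plain-text SAM with supplementary alignments: each alignment line
#' contributes one block (POS plus reference span from the CIGAR M/D/N/=/X
#' operations; strand from FLAG bit 0x10; read offset from leading
#' soft/hard clips). Only the columns needed for junction detection are
#' interpreted.
#'
#' @param path SAM file path.
#' @return data.frame of blocks compatible with [detect_junctions()].
#' @export
read_split_alignments_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  res <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM line: ", substr(l, 1, 50))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) return(NULL)  # unmapped
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    ref_len <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    rev <- bitwAnd(flag, 16L) > 0
    # offset of the aligned part from the read's 5' end: for reverse-strand
    # alignments the 5' clip is the CIGAR's trailing one
    lead_clip <- if (!rev) {
      if (length(op) && op[1] %in% c("S", "H")) n[1] else 0
    } else {
      if (length(op) && op[length(op)] %in% c("S", "H")) n[length(op)] else 0
    }
    start <- as.numeric(f[4])
    data.frame(read_id = f[1], chrom = f[3], start = start,
               end = start + ref_len - 1,
               strand = if (rev) "-" else "+",
               read_start = lead_clip + 1,
               read_end = lead_clip + sum(n[op %in% c("M", "I", "=", "X")]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
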