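#' Build the derivative chromosome pair for a reciprocal translocation
#'
#' The exchange swaps the distal (telomeric) fragments of the two exchanged
#' arms: der(A) is the centromere-bearing part of A joined to the distal
#' fragment of B, and der(B) is the reciprocal product. The two derivatives
#' together cover every base of chromosomes A and B exactly once (no gain or
#' loss), and each has exactly one junction. Fragments are listed in molecule
#' order with a strand: a `-` fragment is traversed in descending reference
#' coordinates so that telomeres always face outward. For the common q-arm to
#' p-arm exchange, der(A) joins (A, bp_a) to (B, bp_b) with the B fragment
#' inverted, and der(B) joins (A, bp_a + 1) to (B, bp_b + 1).
#'
#' @param spec A [translocation_spec()].
#' @param genome A [genome_model()].
#' @return Object of class `derivative_pair`: list with `der_a`, `der_b`
#'   (data.frames of fragments `chrom,start,end,strand` in molecule order,
#'   each with a `junction` attribute giving the two joined breakends) and the
#'   originating `spec`.
#' @examples
#' g <- toy_genome()
#' build_derivatives(toy_translocation(g), g)
#' @export
build_derivatives <- function(spec, genome) {
  validate_spec(spec, genome)
  len_a <- chrom_length(genome, spec$chrom_a)
  len_b <- chrom_length(genome, spec$chrom_b)
  frag <- function(chrom, start, end, strand)
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  # proximal = centromere-bearing fragment, distal = exchanged fragment
  prox_a <- if (spec$arm_a == "q") frag(spec$chrom_a, 1, spec$bp_a, "+")
            else frag(spec$chrom_a, spec$bp_a + 1, len_a, "+")
  dist_a <- if (spec$arm_a == "q") frag(spec$chrom_a, spec$bp_a + 1, len_a, "+")
            else frag(spec$chrom_a, 1, spec$bp_a, "+")
  prox_b <- if (spec$arm_b == "q") frag(spec$chrom_b, 1, spec$bp_b, "+")
            else frag(spec$chrom_b, spec$bp_b + 1, len_b, "+")
  dist_b <- if (spec$arm_b == "q") frag(spec$chrom_b, spec$bp_b + 1, len_b, "+")
            else frag(spec$chrom_b, 1, spec$bp_b, "+")

  # Each fragment retains exactly one telomere; record on which coordinate
  # side it sits.  Proximal fragment of a q exchange keeps the p telomere
  # (low side); distal q fragment keeps the q telomere (high side); arms
  # swap for p exchanges.
  telo_low <- function(role, arm) (role == "prox") == (arm == "q")
  side <- list(prox_a = telo_low("prox", spec$arm_a),
               dist_a = telo_low("dist", spec$arm_a),
               prox_b = telo_low("prox", spec$arm_b),
               dist_b = telo_low("dist", spec$arm_b))

  # assemble a derivative so telomeres face outward: the leading fragment
  # needs its telomere at molecule start, the trailing one at molecule end
  join <- function(first, first_lo, second, second_lo) {
    first$strand <- if (first_lo) "+" else "-"
    second$strand <- if (second_lo) "-" else "+"
    d <- rbind(first, second)
    rownames(d) <- NULL
    # breakend of the first fragment is its molecule-end side
    be1 <- list(chrom = d$chrom[1],
                pos = if (d$strand[1] == "+") d$end[1] else d$start[1],
                strand = d$strand[1])
    be2 <- list(chrom = d$chrom[2],
                pos = if (d$strand[2] == "+") d$start[2] else d$end[2],
                strand = d$strand[2])
    attr(d, "junction") <- list(be1, be2)
    d
  }
  # der_a = proximal(A) + distal(B); written with A's retained telomere first
  # when A's exchange is on q, otherwise with the incoming distal B first
  der_a <- if (spec$arm_a == "q") join(prox_a, side$prox_a, dist_b, side$dist_b)
           else join(dist_b, side$dist_b, prox_a, side$prox_a)
  der_b <- if (spec$arm_b == "q") join(prox_b, side$prox_b, dist_a, side$dist_a)
           else join(dist_a, side$dist_a, prox_b, side$prox_b)
  structure(list(der_a = der_a, der_b = der_b, spec = spec,
                 lengths = c(a = len_a, b = len_b)),
            class = "derivative_pair")
}

#' @export
print.derivative_pair <- function(x, ...) {
  show <- function(name, d) {
    cat(name, ": ",
        paste(sprintf("%s:%s-%s(%s)", d$chrom,
                      format(d$start, big.mark = ","),
                      format(d$end, big.mark = ","), d$strand),
              collapse = " | "), "\n", sep = "")
  }
  show("der_a", x$der_a); show("der_b", x$der_b)
  invisible(x)
}

#' Total length of a derivative chromosome
#' @param der Fragment data.frame from a [build_derivatives()] result.
#' @return Length in bp.
#' @export
derivative_length <- function(der) sum(der$end - der$start + 1)

#' Which chromosome elements a gamete transmits
#'
#' Simulates meiosis I disjunction of the translocation quadrivalent
#' (A_normal, B_normal, der_a, der_b). Only alternate segregation yields
#' balanced gametes; adjacent-1, adjacent-2 and 3:1 segregation produce
#' unbalanced ones. The balanced flag is computed by a base-coverage check of
#' the transmitted elements against chromosomes A and B, never hard-coded.
#'
#' @param spec A [translocation_spec()].
#' @param genome A [genome_model()].
#' @param mode One of `"alternate"`, `"adjacent1"`, `"adjacent2"`,
#'   `"three_to_one"`.
#' @return Object of class `gamete_spec`: list with `mode`, `transmitted`
#'   (subset of `A_normal`, `B_normal`, `der_a`, `der_b`) and `balanced`.
#' @export
segregate <- function(spec, genome, mode) {
  outcomes <- switch(mode,
    alternate = list(c("A_normal", "B_normal"), c("der_a", "der_b")),
    adjacent1 = list(c("der_a", "B_normal"), c("A_normal", "der_b")),
    adjacent2 = list(c("A_normal", "der_a"), c("B_normal", "der_b")),
    three_to_one = utils::combn(c("A_normal", "B_normal", "der_a", "der_b"),
                                3, simplify = FALSE),
    stop("unknown segregation mode: ", mode))
  transmitted <- outcomes[[sample.int(length(outcomes), 1)]]
  cov <- gamete_coverage(transmitted, spec, genome)
  structure(list(mode = mode, transmitted = transmitted,
                 balanced = all(cov$copies == 1)),
            class = "gamete_spec")
}

#' Per-base copy coverage of a set of transmitted elements
#'
#' Returns the number of copies each region of chromosomes A and B receives
#' from the given elements, as disjoint segments. Used both for the balanced
#' flag and for embryo copy-number truth.
#'
#' @param transmitted Character vector of elements (`A_normal`, `B_normal`,
#'   `der_a`, `der_b`).
#' @param spec A [translocation_spec()].
#' @param genome A [genome_model()].
#' @return data.frame `chrom,start,end,copies` covering both chromosomes.
#' @export
gamete_coverage <- function(transmitted, spec, genome) {
  derivs <- build_derivatives(spec, genome)
  pieces <- list()
  add <- function(chrom, start, end) {
    pieces[[length(pieces) + 1L]] <<-
      data.frame(chrom = chrom, start = start, end = end)
  }
  for (el in transmitted) {
    if (el == "A_normal") add(spec$chrom_a, 1, chrom_length(genome, spec$chrom_a))
    else if (el == "B_normal") add(spec$chrom_b, 1, chrom_length(genome, spec$chrom_b))
    else {
      d <- derivs[[if (el == "der_a") "der_a" else "der_b"]]
      for (i in seq_len(nrow(d))) add(d$chrom[i], d$start[i], d$end[i])
    }
  }
  pieces <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  out <- lapply(c(spec$chrom_a, spec$chrom_b), function(ch) {
    len <- chrom_length(genome, ch)
    p <- pieces[pieces$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(1, len + 1, p$start, p$end + 1)))
    cuts <- cuts[cuts >= 1 & cuts <= len + 1]
    starts <- cuts[-length(cuts)]; ends <- cuts[-1] - 1
    copies <- vapply(seq_along(starts), function(i)
      sum(p$start <= starts[i] & p$end >= ends[i]), 0)
    data.frame(chrom = ch, start = starts, end = ends, copies = copies,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # merge runs with equal copy number
  merged <- out[0, ]
  for (i in seq_len(nrow(out))) {
    n <- nrow(merged)
    if (n > 0 && merged$chrom[n] == out$chrom[i] &&
        merged$copies[n] == out$copies[i] &&
        merged$end[n] + 1 == out$start[i]) {
      merged$end[n] <- out$end[i]
    } else merged <- rbind(merged, out[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' Assemble an embryo with full ground truth
#'
#' Combines a carrier gamete with a normal partner gamete (one copy of each
#' chromosome) into an embryo: true copy-number segments, carrier status, the
#' carrier haplotype physically present on each chromosome flank, and any
#' mosaic events to overlay.
#'
#' Haplotype bookkeeping: the translocation arose on one specific homolog of
#' each chromosome, so the derivative-linked carrier haplotypes
#' (`linkage["a"]`, `linkage["b"]`) sit on both fragments of der(A)/der(B),
#' while the untouched homologs carry the complementary haplotypes.
#'
#' @param id Embryo identifier.
#' @param gamete A [segregate()] result (or a list with a `transmitted`
#'   field).
#' @param spec,genome Translocation and genome.
#' @param linkage Named character vector `c(a=,b=)` giving the carrier
#'   haplotype (`"H1"`/`"H2"`) on each derivative.
#' @param partner_hap Named integer vector `c(a=,b=)` in `{1,2}`: which
#'   partner haplotype was transmitted per chromosome.
#' @param mosaic_events Optional data.frame `chrom,start,end,type,fraction`
#'   with `type` in `gained`/`lost` and `fraction` in \[0,1\].
#' @return Object of class `embryo_truth`.
#' @export
make_embryo <- function(id, gamete, spec, genome,
                        linkage = c(a = "H1", b = "H1"),
                        partner_hap = c(a = 1L, b = 1L),
                        mosaic_events = NULL) {
  transmitted <- gamete$transmitted
  cov <- gamete_coverage(transmitted, spec, genome)
  cov$cn <- cov$copies + 1  # partner adds one copy of each chromosome
  status <- if (setequal(transmitted, c("der_a", "der_b"))) "balanced_carrier"
            else if (setequal(transmitted, c("A_normal", "B_normal"))) "non_carrier"
            else "unbalanced"
  if (!is.null(mosaic_events) && nrow(mosaic_events) > 0) {
    if (any(mosaic_events$fraction < 0 | mosaic_events$fraction > 1))
      stop("mosaic fraction outside [0,1]")
  }
  other <- function(h) if (h == "H1") "H2" else "H1"
  # carrier haplotypes present per (chromosome, region): proximal/distal wrt bp
  hap_of <- function(chrom, region) {
    d <- if (chrom == spec$chrom_a) "a" else "b"
    haps <- character()
    for (el in transmitted) {
      h <- switch(el,
        A_normal = if (chrom == spec$chrom_a) other(linkage["a"]) else NA,
        B_normal = if (chrom == spec$chrom_b) other(linkage["b"]) else NA,
        der_a = if ((chrom == spec$chrom_a && region == "proximal") ||
                    (chrom == spec$chrom_b && region == "distal"))
                  unname(linkage[d]) else NA,
        der_b = if ((chrom == spec$chrom_a && region == "distal") ||
                    (chrom == spec$chrom_b && region == "proximal"))
                  unname(linkage[d]) else NA)
      if (!is.na(h)) haps <- c(haps, unname(h))
    }
    haps
  }
  flanks <- expand.grid(chrom = c(spec$chrom_a, spec$chrom_b),
                        region = c("proximal", "distal"),
                        stringsAsFactors = FALSE)
  flanks$carrier_haps <- vapply(seq_len(nrow(flanks)), function(i)
    paste(hap_of(flanks$chrom[i], flanks$region[i]), collapse = ","), "")
  structure(list(id = id, gamete = gamete, spec = spec,
                 cn_segments = cov[, c("chrom", "start", "end", "cn")],
                 carrier_status = status,
                 linkage = linkage, partner_hap = partner_hap,
                 flank_haplotypes = flanks,
                 mosaic_events = mosaic_events),
            class = "embryo_truth")
}

#' @export
print.embryo_truth <- function(x, ...) {
  cat(sprintf("embryo %s: %s gamete {%s}, status %s\n", x$id, x$gamete$mode,
              paste(x$gamete$transmitted, collapse = ","), x$carrier_status))
  invisible(x)
}

#' Expected copy number per fixed-width bin
#'
#' Converts an embryo's true integer copy-number segments (plus any mosaic
#' events) into the expected fractional copy number of each genomic bin. A
#' mosaic gain of fraction f adds f to the segment's copy number, a loss
#' subtracts f (e.g. a trisomic mosaic at 31% gives 2.31). A bin straddling a
#' copy-number boundary gets the length-weighted mean of the two states.
#'
#' @param truth An [make_embryo()] result.
#' @param genome A [genome_model()].
#' @param bin_width Bin width in bp; bins start at position 1.
#' @return data.frame `chrom,start,end,cn` with one row per bin.
#' @export
true_copy_profile <- function(truth, genome, bin_width) {
  segs <- truth$cn_segments
  segs$cn <- as.numeric(segs$cn)
  me <- truth$mosaic_events
  if (!is.null(me) && nrow(me) > 0) {
    if (any(me$fraction < 0 | me$fraction > 1))
      stop("mosaic fraction outside [0,1]")
    for (i in seq_len(nrow(me))) {
      delta <- if (me$type[i] == "gained") me$fraction[i] else -me$fraction[i]
      segs <- .overlay_delta(segs, me$chrom[i], me$start[i], me$end[i], delta)
    }
  }
  out <- lapply(unique(segs$chrom), function(ch) {
    len <- chrom_length(genome, ch)
    nb <- ceiling(len / bin_width)
    starts <- (seq_len(nb) - 1) * bin_width + 1
    ends <- pmin(starts + bin_width - 1, len)
    s <- segs[segs$chrom == ch, , drop = FALSE]
    cn <- vapply(seq_len(nb), function(i) {
      ov_start <- pmax(s$start, starts[i]); ov_end <- pmin(s$end, ends[i])
      w <- pmax(0, ov_end - ov_start + 1)
      sum(w * s$cn) / (ends[i] - starts[i] + 1)
    }, 0)
    data.frame(chrom = ch, start = starts, end = ends, cn = cn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  out
}

# add delta to cn over [start,end] on chrom, splitting segments as needed
.overlay_delta <- function(segs, chrom, start, end, delta) {
  res <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$chrom != chrom || s$end < start || s$start > end) {
      res[[length(res) + 1L]] <- s; next
    }
    if (s$start < start)
      res[[length(res) + 1L]] <- transform(s, end = start - 1)
    mid <- transform(s, start = max(s$start, start), end = min(s$end, end))
    mid$cn <- mid$cn + delta
    res[[length(res) + 1L]] <- mid
    if (s$end > end)
      res[[length(res) + 1L]] <- transform(s, start = end + 1)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
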