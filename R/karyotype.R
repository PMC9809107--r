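#' Whole-megabase size label for a genomic segment
#'
#' Clinical segment strings label sizes at whole-Mb resolution with a leading
#' tilde; the label is the floor of the segment length in Mb (a 35.47 Mb
#' segment is "~35Mb", a 118.04 Mb one "~118Mb").
#'
#' @param start,end 1-based inclusive segment bounds.
#' @return Character label like `"~35Mb"`.
#' @examples
#' size_label(1, 35465883)
#' @export
size_label <- function(start, end) {
  stopifnot(end >= start)
  sprintf("~%dMb", size_label_mb(start, end))
}

#' @rdname size_label
#' @return `size_label_mb` returns the bare integer Mb value.
#' @export
size_label_mb <- function(start, end) as.integer(floor((end - start + 1) / 1e6))

#' Construct a karyotype call
#'
#' A karyotype call is the structured form of a ploidy-result string such as
#' `"46, XN, +2q(q14.3→q37.3,~118Mb,×3), -5p(pter→p13.2,~35Mb,×1)"`: a modal
#' chromosome count token, a sex token (masked as `XN` by default), and an
#' ordered list of unbalanced segment calls.
#'
#' @param embryo Embryo id.
#' @param segments data.frame with columns `chrom` (token without the `chr`
#'   prefix), `arm`, `band_start`, `band_end`, `size_mb`, `cn`, `mosaic_pct`;
#'   band and size fields may be `NA` for a whole-arm call. Zero rows mean a
#'   euploid call.
#' @param modal Modal count token, default `"46"`.
#' @param sex Sex token (`"XN"`, `"XX"`, `"XY"`).
#' @return Object of class `karyotype_call`.
#' @export
karyotype_call <- function(embryo, segments = NULL, modal = "46", sex = "XN") {
  if (is.null(segments))
    segments <- data.frame(chrom = character(), arm = character(),
                           band_start = character(), band_end = character(),
                           size_mb = integer(), cn = integer(),
                           mosaic_pct = integer(), stringsAsFactors = FALSE)
  structure(list(embryo = embryo, modal = modal, sex = sex,
                 segments = segments, is_euploid = nrow(segments) == 0),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat(x$embryo, ": ", format_karyotype(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a karyotype call to its string form
#'
#' @param call A [karyotype_call()].
#' @return Single string in the clinical segment-string dialect.
#' @export
format_karyotype <- function(call) {
  segs <- call$segments
  seg_str <- vapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    sign <- if (s$cn > 2) "+" else "-"
    inner <- if (is.na(s$band_start)) sprintf("×%d", s$cn)
    else {
      base <- sprintf("%s→%s,~%dMb,×%d",
                      s$band_start, s$band_end, s$size_mb, s$cn)
      if (!is.na(s$mosaic_pct))
        base <- sprintf("%s,mos,~%d%%", base, s$mosaic_pct)
      base
    }
    sprintf("%s%s%s(%s)", sign, s$chrom, s$arm, inner)
  }, "")
  paste(c(call$modal, call$sex, seg_str), collapse = ", ")
}

.seg_regex <- paste0(
  "^([+-])([A-Za-z0-9]+)([pq])\\(",
  "(?:((?:[pq][0-9.]+)|pter|qter)→((?:[pq][0-9.]+)|pter|qter),",
  "~([0-9]+)Mb,)?",
  "×([0-9]+)",
  "(?:,mos,~([0-9]+)%)?\\)$")

#' Parse a karyotype string
#'
#' Inverse of [format_karyotype()]: accepts the modal count, sex token and
#' zero or more segment strings. Whole-arm calls without band/size fields
#' (e.g. `"+17p(×3)"`) are accepted. Serializing the result reproduces the
#' input (round-trip identity).
#'
#' @param text Karyotype string.
#' @param embryo Embryo id to attach.
#' @return A [karyotype_call()].
#' @export
parse_karyotype <- function(text, embryo = NA_character_) {
  tokens <- .split_karyotype(text)
  if (length(tokens) < 2) stop("karyotype string needs modal and sex tokens: ", text)
  modal <- tokens[1]; sex <- tokens[2]
  if (!grepl("^[0-9]+$", modal)) stop("bad modal count token: '", modal, "'")
  if (!grepl("^X[NXY]$", sex)) stop("bad sex token: '", sex, "'")
  segs <- lapply(tokens[-(1:2)], function(tok) {
    m <- regmatches(tok, regexec(.seg_regex, tok))[[1]]
    if (length(m) != 9) stop("cannot parse segment token: '", tok, "'")
    # m: full, sign, chrom, arm, band_start, band_end, size, cn, mosaic_pct
    cn <- as.integer(m[8])
    if ((m[2] == "+") != (cn > 2))
      stop("sign/copy-number mismatch in segment token: '", tok, "'")
    data.frame(chrom = m[3], arm = m[4],
               band_start = if (m[5] == "") NA_character_ else m[5],
               band_end = if (m[6] == "") NA_character_ else m[6],
               size_mb = if (m[7] == "") NA_integer_ else as.integer(m[7]),
               cn = cn,
               mosaic_pct = if (m[9] == "") NA_integer_ else as.integer(m[9]),
               stringsAsFactors = FALSE)
  })
  segs <- if (length(segs)) do.call(rbind, segs) else NULL
  karyotype_call(embryo, segs, modal = modal, sex = sex)
}

# split on ", " outside parentheses
.split_karyotype <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0; buf <- character(); out <- character()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth == 0 && ch == "," ) {
      out <- c(out, paste(buf, collapse = "")); buf <- character()
      # skip following spaces
      while (i < length(chars) && chars[i + 1] == " ") i <- i + 1
    } else buf <- c(buf, ch)
    i <- i + 1
  }
  if (depth != 0) stop("unbalanced parentheses in karyotype string: '", text, "'")
  c(out, paste(buf, collapse = ""))
}

#' Build a karyotype call from copy-number segments
#'
#' Converts called abnormal segments ([call_segments()]) to the clinical
#' string dialect: coordinates become cytoband tokens via the band map (with
#' `pter`/`qter` for chromosome ends), the size label is the floor of the
#' length in Mb, and the sign follows the copy-number direction.
#'
#' @param embryo Embryo id.
#' @param segments Called segments (`chrom,start,end,cn,mosaic_pct`).
#' @param bands A [load_cytobands()] map covering the segment chromosomes.
#' @param genome A [genome_model()] (for chromosome ends).
#' @param sex Sex token, default `"XN"`.
#' @return A [karyotype_call()].
#' @export
make_karyotype_call <- function(embryo, segments, bands, genome, sex = "XN") {
  if (is.null(segments) || nrow(segments) == 0)
    return(karyotype_call(embryo, NULL, sex = sex))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    len <- chrom_length(genome, s$chrom)
    arm_mid <- band_at(bands, s$chrom, floor((s$start + s$end) / 2))
    arm <- substr(arm_mid, 1, 1)
    bs <- if (s$start == 1) "pter" else band_at(bands, s$chrom, s$start)
    be <- if (s$end >= len) "qter" else band_at(bands, s$chrom, s$end)
    data.frame(chrom = sub("^chr", "", s$chrom), arm = arm,
               band_start = bs, band_end = be,
               size_mb = size_label_mb(s$start, s$end),
               cn = s$cn, mosaic_pct = s$mosaic_pct,
               stringsAsFactors = FALSE)
  })
  karyotype_call(embryo, do.call(rbind, rows), sex = sex)
}

#' Load a UCSC-dialect cytoband file
#'
#' Five tab-separated columns: chrom, 0-based start, end, band name, stain.
#' Coordinates are converted to the package's internal 1-based inclusive
#' convention on load. Bands must not overlap within a chromosome.
#'
#' @param path Cytoband file path.
#' @return data.frame `chrom,start,end,band,stain` of class `cytoband_map`.
#' @export
load_cytobands <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5)
  if (length(bad))
    stop("malformed cytoband line ", bad[1], ": expected 5 tab-separated fields")
  m <- do.call(rbind, parts)
  out <- data.frame(chrom = m[, 1],
                    start = as.numeric(m[, 2]) + 1,  # 0-based -> 1-based
                    end = as.numeric(m[, 3]),
                    band = m[, 4], stain = m[, 5],
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-numeric coordinates in cytoband file")
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
      stop("overlapping cytobands on ", ch)
  }
  class(out) <- c("cytoband_map", "data.frame")
  out
}

#' Cytoband containing a position
#'
#' @param bands A [load_cytobands()] map.
#' @param chrom,pos Query position (1-based).
#' @return Band name, or `NA` if not covered.
#' @export
band_at <- function(bands, chrom, pos) {
  hit <- bands$chrom == chrom & bands$start <= pos & bands$end >= pos
  if (!any(hit)) return(NA_character_)
  bands$band[which(hit)[1]]
}

#' Interval of a named cytoband
#'
#' @param bands A [load_cytobands()] map.
#' @param chrom,band Chromosome and band name.
#' @return Numeric `c(start, end)`, 1-based inclusive.
#' @export
band_interval <- function(bands, chrom, band) {
  hit <- bands$chrom == chrom & bands$band == band
  if (!any(hit)) stop("no band ", band, " on ", chrom)
  c(start = bands$start[which(hit)[1]], end = bands$end[which(hit)[1]])
}

#' Synthetic cytoband map for a toy genome
#'
#' Divides each chromosome into a p arm (40%) and q arm (60%), each split
#' into evenly sized numbered bands, mimicking the UCSC naming scheme. Purely
#' synthetic: band names carry no relation to any real genome.
#'
#' @param genome A [genome_model()].
#' @param n_bands Bands per arm.
#' @return A `cytoband_map`.
#' @export
toy_cytobands <- function(genome, n_bands = 4) {
  out <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    ch <- genome$chromosomes$chrom[i]; len <- genome$chromosomes$length[i]
    cen <- floor(len * 0.4)
    mk <- function(arm, a, b) {
      cuts <- round(seq(a - 1, b, length.out = n_bands + 1))
      # p-band numbering runs outward from the centromere
      nums <- if (arm == "p") rev(seq_len(n_bands)) else seq_len(n_bands)
      data.frame(chrom = ch, start = cuts[-length(cuts)] + 1, end = cuts[-1],
                 band = sprintf("%s%d", arm, nums + 10),
                 stain = "gneg", stringsAsFactors = FALSE)
    }
    rbind(mk("p", 1, cen), mk("q", cen + 1, len))
  }))
  rownames(out) <- NULL
  class(out) <- c("cytoband_map", "data.frame")
  out
}

#' Write a cytoband map in the UCSC file dialect
#' @param bands A `cytoband_map`.
#' @param path Output file (tab-separated, 0-based start).
#' @return Invisibly, `path`.
#' @export
write_cytobands <- function(bands, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", bands$chrom,
                   as.integer(bands$start - 1), as.integer(bands$end),
                   bands$band, bands$stain)
  writeLines(lines, path)
  invisible(path)
}
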