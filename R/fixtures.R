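#' Worked-example fixtures for two clinical PGT-SR pedigrees
#'
#' Bundles the published analysis artifacts of two balanced reciprocal
#' translocation carriers — 46,XX,t(2;5)(q14.2;p13.1) and
#' 46,XY,t(13;17)(q11;q11.2) — for use as worked examples and regression
#' fixtures:
#'
#' * the reference embryos' chromosome-ploidy strings in the clinical
#'   segment dialect, plus the stated classes of the remaining embryos;
#' * the CNV-window breakpoint localizations (grid centers with +/-200 kb
#'   half-windows);
#' * the single-base split-read breakpoint coordinates
#'   (chr2:125,157,514 / chr5:35,465,883 and
#'   chr13:26,208,296 / chr17:33,942,282);
#' * GRCh37 lengths of the involved chromosomes.
#'
#' The published record gives reference-embryo segments at cytoband
#' resolution only, so each reference embryo additionally carries
#' `encoded_segments`: synthetic base-pair coordinates placed on the 200 kb
#' analysis grid consistent with the published windows, which let the
#' CNV-localization code run on the pedigrees end to end.
#'
#' @return List with elements `patient1` and `patient2`, each containing
#'   `spec` ([translocation_spec()]), `karyotype` (parental karyotype
#'   string), `table1` (embryo id, ploidy string, reference flag),
#'   `statuses` (stated class of every embryo), `encoded_segments` (named
#'   list of coordinate segment tables for the reference embryos), `windows`
#'   (`chrom,position,half_window`), `splitread` (`chrom,position`) and
#'   `n_embryos`; plus `chrom_lengths` (GRCh37).
#' @export
clinical_fixtures <- function() {
  grch37 <- c(chr2 = 243199373, chr5 = 180915260,
              chr13 = 115169878, chr17 = 81195210)
  seg <- function(chrom, start, end, cn)
    data.frame(chrom = chrom, start = start, end = end, cn = cn,
               mosaic_pct = NA_integer_, stringsAsFactors = FALSE)

  p1_table1 <- data.frame(
    embryo = c("B", "F", "G", "H", "K"),
    string = c(
      "46, XN, +2q(q14.3→q37.3,~118Mb,×3), -5p(pter→p13.2,~35Mb,×1)",
      "46, XN, -2q(q14.3→q14.3,~5Mb,×1), -2q(q21.1→q37.1,~104Mb,×1), -2q(q37.1→q37.3,~8Mb,×1), +5p(pter→p13.2,~35Mb,×3)",
      "46, XN, -2q(q14.3→q37.3,~118Mb,×1), +5p(p15.33→p13.2,~34Mb,×3), +6q(q11.1→q14.1,~20Mb,×3,mos,~31%), -10q(q24.2→q25.1,~11Mb,×1,mos,~33%)",
      "46, XN, +2q(q14.3→q37.3,~118Mb,×3), -5p(pter→p13.2,~35Mb,×1)",
      "46, XX, +Xp(p21.3→p11.4,~14Mb,×3,mos,~31%), -2q(q14.3→q37.3,~118Mb,×1), +5p(pter→p13.2,~35Mb,×3)"),
    reference = TRUE, stringsAsFactors = FALSE)
  p1_statuses <- data.frame(
    embryo = LETTERS[1:11],
    status = c("other_abnormal",            # A: abnormal chr1
               "reference_unbalanced",      # B
               "euploid", "euploid", "euploid",  # C D E
               "reference_unbalanced",      # F
               "reference_unbalanced",      # G
               "reference_unbalanced",      # H
               "other_abnormal",            # I: trisomy 15p mosaicism
               "euploid",                   # J
               "reference_unbalanced"),     # K
    stringsAsFactors = FALSE)
  # synthetic grid encodings of the reference-embryo imbalances (200 kb grid)
  p1_enc <- list(
    B = rbind(seg("chr2", 125200001, 243199373, 3),
              seg("chr5", 1, 35500000, 1)),
    F = rbind(seg("chr2", 125200001, 130200000, 1),
              seg("chr2", 135400001, 239400000, 1),
              seg("chr2", 239400001, 243199373, 1),
              seg("chr5", 1, 35500000, 3)),
    G = rbind(seg("chr2", 125200001, 243199373, 1),
              seg("chr5", 1400001, 35500000, 3)),
    H = rbind(seg("chr2", 125200001, 243199373, 3),
              seg("chr5", 1, 35500000, 1)),
    K = rbind(seg("chr2", 125200001, 243199373, 1),
              seg("chr5", 1, 35500000, 3)))
  p1 <- list(
    patient = "patient1",
    karyotype = "46,XX,t(2;5)(q14.2;p13.1)",
    spec = translocation_spec("chr2", "chr5", 125157514, 35465883,
                              arm_a = "q", arm_b = "p",
                              carrier_parent = "maternal",
                              band_a = "q14.2", band_b = "p13.1"),
    table1 = p1_table1, statuses = p1_statuses, encoded_segments = p1_enc,
    windows = data.frame(chrom = c("chr2", "chr5"),
                         position = c(125200001, 35500001),
                         half_window = 200000, stringsAsFactors = FALSE),
    splitread = data.frame(chrom = c("chr2", "chr5"),
                           position = c(125157514, 35465883),
                           stringsAsFactors = FALSE),
    n_embryos = 11L)

  p2_table1 <- data.frame(
    embryo = c("D", "E", "G", "H", "I"),
    string = c(
      "46, XN, -13q(q12.13→q34,~88Mb,×1), +14q(q22.1→q32.33,~52Mb,×3,mos,~51%), +17q(q12→q25.3,~46Mb,×3)",
      "46, XN, -5p(pter→p15.1,~16Mb,×1), -13q(q12.11→q12.12,~6Mb,×1), +17p(×3), +17q(q11.2→q12,~8Mb,×3)",
      "46, XN, +13q(q12.13→q34,~88Mb,×3), -17q(q12→q25.3,~46Mb,×1)",
      "46, XN, -13q(q12.13→q34,~88Mb,×1), +17q(q12→q25.3,~46Mb,×3)",
      "46, XN, +13q(q12.13→q34,~88Mb,×3), -17q(q12→q25.3,~46Mb,×1)"),
    reference = TRUE, stringsAsFactors = FALSE)
  p2_statuses <- data.frame(
    embryo = LETTERS[1:12],
    status = c("euploid", "euploid", "euploid",         # A B C
               "reference_unbalanced",                  # D
               "reference_unbalanced",                  # E
               "other_abnormal",                        # F: monosomy 6q
               "reference_unbalanced",                  # G
               "reference_unbalanced",                  # H
               "reference_unbalanced",                  # I
               "other_abnormal",                        # J: monosomy 7
               "other_abnormal",                        # K: mosaic -10q only
               "euploid"),                              # L
    stringsAsFactors = FALSE)
  p2_enc <- list(
    D = rbind(seg("chr13", 26200001, 115169878, 1),
              seg("chr17", 34000001, 81195210, 3)),
    E = rbind(seg("chr13", 26200001, 32200000, 1),
              seg("chr17", 1, 34000000, 3)),
    G = rbind(seg("chr13", 26200001, 115169878, 3),
              seg("chr17", 34000001, 81195210, 1)),
    H = rbind(seg("chr13", 26200001, 115169878, 1),
              seg("chr17", 34000001, 81195210, 3)),
    I = rbind(seg("chr13", 26200001, 115169878, 3),
              seg("chr17", 34000001, 81195210, 1)))
  p2 <- list(
    patient = "patient2",
    karyotype = "46,XY,t(13;17)(q11;q11.2)",
    spec = translocation_spec("chr13", "chr17", 26208296, 33942282,
                              arm_a = "q", arm_b = "q",
                              carrier_parent = "paternal",
                              band_a = "q11", band_b = "q11.2"),
    table1 = p2_table1, statuses = p2_statuses, encoded_segments = p2_enc,
    windows = data.frame(chrom = c("chr13", "chr17"),
                         position = c(26200001, 34000001),
                         half_window = 200000, stringsAsFactors = FALSE),
    splitread = data.frame(chrom = c("chr13", "chr17"),
                           position = c(26208296, 33942282),
                           stringsAsFactors = FALSE),
    n_embryos = 12L)

  list(patient1 = p1, patient2 = p2, chrom_lengths = grch37)
}

#' Karyotype calls for one fixture pedigree
#'
#' Parses the pedigree's ploidy strings into [karyotype_call()] objects and
#' fills in empty (euploid) calls for the embryos the record reports as
#' euploid, so a full per-embryo call list is available. Embryos whose only
#' reported abnormality involves other chromosomes get a placeholder
#' non-translocation segment so classification treats them as
#' `other_abnormal`.
#'
#' @param patient One element of [clinical_fixtures()] (`patient1`/`patient2`).
#' @return Named list of [karyotype_call()] objects, one per embryo.
#' @export
fixture_karyotype_calls <- function(patient) {
  calls <- list()
  for (i in seq_len(nrow(patient$statuses))) {
    id <- patient$statuses$embryo[i]
    st <- patient$statuses$status[i]
    if (id %in% patient$table1$embryo) {
      calls[[id]] <- parse_karyotype(
        patient$table1$string[patient$table1$embryo == id], embryo = id)
    } else if (st == "euploid") {
      calls[[id]] <- karyotype_call(id)
    } else {
      # stand-in single-segment call on an uninvolved chromosome
      calls[[id]] <- karyotype_call(id, data.frame(
        chrom = "1", arm = "q", band_start = "q21", band_end = "qter",
        size_mb = 100L, cn = 1L, mosaic_pct = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  calls
}
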