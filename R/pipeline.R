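#' Configuration for a full simulated PGT-SR analysis
#'
#' Collects every simulator setting and stage threshold with an explicit
#' master seed; all stage seeds are derived deterministically from it, so a
#' config fully determines every output byte.
#'
#' @param seed Master integer seed.
#' @param genome_seed Seed for the SNP map (kept separate so the same
#'   pedigree can be re-simulated on the same genome).
#' @param n_embryos Number of embryos in the pedigree.
#' @param mode_probs Named probabilities of the segregation modes.
#' @param bin_width CNV bin width in bp.
#' @param m Mean count per disomic bin.
#' @param dispersion Negative-binomial overdispersion of bin counts.
#' @param ado Allele dropout probability.
#' @param per_allele_depth Mean per-allele SNP depth.
#' @param snp_error_rate Genotyping error probability.
#' @param n_reads Number of long reads from the carrier genome.
#' @param qscore_mean,qscore_sd Read mean-quality distribution.
#' @param min_qscore Read QC threshold.
#' @param min_seg_bins,seg_threshold Segmentation controls.
#' @param cluster_tolerance,min_junction_support Junction clustering controls.
#' @param flank_window,min_snps,majority,consistency Phasing controls.
#' @param mosaic_events Optional mosaic overlay (see [make_embryo()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, genome_seed = 100,
                            n_embryos = 12,
                            mode_probs = c(alternate = 0.5, adjacent1 = 0.35,
                                           adjacent2 = 0.15, three_to_one = 0),
                            bin_width = 2e5, m = 500, dispersion = 0.1,
                            ado = 0.05, per_allele_depth = 30,
                            snp_error_rate = 0.001,
                            n_reads = 5000, qscore_mean = 11, qscore_sd = 2.5,
                            min_qscore = 7,
                            min_seg_bins = 3, seg_threshold = 0.3,
                            cluster_tolerance = 10, min_junction_support = 3,
                            flank_window = 2e6, min_snps = 5, majority = 0.8,
                            consistency = 0.9,
                            mosaic_events = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Simulate a complete pedigree with ground truth
#'
#' Builds the toy genome and translocation, draws the derivative-linked
#' haplotypes and one gamete per embryo according to the segregation-mode
#' mix, and returns embryo truths plus simulated bin counts, SNP
#' observations and carrier long reads.
#'
#' @param config A [pipeline_config()].
#' @return List of class `sim_pedigree` with `genome`, `spec`, `derivs`,
#'   `linkage_truth`, `embryos` (list of [make_embryo()] truths), `counts`
#'   (named list of bin counts), `snp_obs` (one data.frame) and `reads`
#'   (a `long_read_set`).
#' @export
simulate_pedigree <- function(config = pipeline_config()) {
  genome <- toy_genome(seed = config$genome_seed)
  spec <- toy_translocation(genome)
  derivs <- build_derivatives(spec, genome)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  linkage <- c(a = sample(c("H1", "H2"), 1), b = sample(c("H1", "H2"), 1))
  probs <- config$mode_probs[config$mode_probs > 0]
  modes <- sample(names(probs), config$n_embryos, replace = TRUE,
                  prob = probs)
  embryos <- list(); counts <- list(); obs <- list()
  for (i in seq_len(config$n_embryos)) {
    id <- sprintf("E%02d", i)
    gam <- segregate(spec, genome, modes[i])
    partner <- c(a = sample(1:2, 1), b = sample(1:2, 1))
    truth <- make_embryo(id, gam, spec, genome, linkage = linkage,
                         partner_hap = partner,
                         mosaic_events = config$mosaic_events)
    embryos[[id]] <- truth
    prof <- true_copy_profile(truth, genome, config$bin_width)
    counts[[id]] <- simulate_bin_counts(prof, config$m, config$dispersion,
                                        seed = config$seed * 1000 + i,
                                        embryo = id)
    obs[[id]] <- simulate_snp_observations(
      truth, genome, ado = config$ado,
      per_allele_depth = config$per_allele_depth,
      error_rate = config$snp_error_rate,
      seed = config$seed * 2000 + i)
  }
  reads <- simulate_long_reads(genome, derivs, config$n_reads,
                               qscore_mean = config$qscore_mean,
                               qscore_sd = config$qscore_sd,
                               linkage = linkage,
                               seed = config$seed * 3000 + 1)
  structure(list(genome = genome, spec = spec, derivs = derivs,
                 linkage_truth = linkage, embryos = embryos, counts = counts,
                 snp_obs = do.call(rbind, obs), reads = reads,
                 config = config),
            class = "sim_pedigree")
}

#' Run the full PGT-SR analysis on a simulated pedigree
#'
#' Orchestrates every stage: bin-count normalization and segmentation per
#' embryo, copy-number calls and karyotype strings, embryo classification and
#' reference selection, breakpoint localization from CNV boundaries and from
#' split long reads, concordance between the two, haplotype phasing by both
#' routes, and carrier calls for the euploid embryos. Deterministic under a
#' fixed config.
#'
#' @param config A [pipeline_config()].
#' @param pedigree Optionally a pre-simulated [simulate_pedigree()] result
#'   (must match the config).
#' @return List of class `pgtsr_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), pedigree = NULL) {
  ped <- if (is.null(pedigree)) simulate_pedigree(config) else pedigree
  genome <- ped$genome; spec <- ped$spec
  bands <- toy_cytobands(genome)
  chrom_lengths <- stats::setNames(genome$chromosomes$length,
                                   genome$chromosomes$chrom)

  # CNV stage
  seg_calls <- list(); karyos <- list()
  for (id in names(ped$counts)) {
    cn <- normalize_counts(ped$counts[[id]])
    segs <- segment_profile(cn, config$min_seg_bins, config$seg_threshold)
    called <- call_segments(segs)
    seg_calls[[id]] <- called
    karyos[[id]] <- make_karyotype_call(id, called, bands, genome)
  }
  classes <- lapply(karyos, classify_embryo, spec = spec)
  refs <- select_reference_embryos(karyos, spec)
  euploids <- names(karyos)[vapply(classes, function(x) x$class, "") == "euploid"]

  # long-read stage
  reads <- qc_filter_reads(ped$reads, config$min_qscore)
  stats <- read_stats(reads, sum(genome$chromosomes$length))
  clusters <- detect_junctions(reads$blocks, config$cluster_tolerance,
                               config$min_junction_support)
  split_est <- junctions_to_estimates(clusters)

  # breakpoints + concordance
  cnv_est <- NULL; concordance <- NULL
  if (length(refs) > 0) {
    cnv_est <- localize_from_cnv(seg_calls[refs], spec, config$bin_width,
                                 chrom_lengths)
    concordance <- do.call(rbind, lapply(seq_len(nrow(cnv_est)), function(i) {
      hit <- split_est[split_est$chrom == cnv_est$chrom[i], , drop = FALSE]
      if (nrow(hit) == 0) return(NULL)
      as.data.frame(check_concordance(cnv_est[i, ], hit[1, ]))
    }))
  }

  # phasing: reference-embryo route and junction-read route
  bp_for_snps <- if (nrow(split_est) > 0) split_est else cnv_est
  snps <- linkage_ref <- linkage_reads <- NULL
  carrier_calls <- list()
  if (!is.null(bp_for_snps)) {
    snps <- select_informative_snps(genome$snps, bp_for_snps, spec,
                                    config$flank_window)
  }
  if (!is.null(snps) && length(refs) > 0) {
    linkage_ref <- phase_derivative_from_references(
      ped$snp_obs, seg_calls[refs], spec, snps, config$consistency)
  }
  if (!is.null(snps)) {
    linkage_reads <- phase_from_junction_reads(reads, clusters, snps, spec,
                                               config$consistency)
  }
  linkage <- if (!is.null(linkage_ref) && !any(is.na(linkage_ref$der_hap)))
               linkage_ref else linkage_reads
  for (id in euploids) {
    carrier_calls[[id]] <- if (is.null(linkage) || is.null(snps)) {
      structure(list(embryo = id, call = "inconclusive",
                     evidence = NULL), class = "carrier_call")
    } else {
      call_carrier_status(karyos[[id]], ped$snp_obs, linkage, snps,
                          config$min_snps, config$majority)
    }
  }

  structure(list(pedigree = ped, karyotypes = karyos, classes = classes,
                 reference_embryos = refs, euploid_embryos = euploids,
                 segment_calls = seg_calls,
                 read_stats = stats, junction_clusters = clusters,
                 cnv_estimates = cnv_est, split_estimates = split_est,
                 concordance = concordance, informative_snps = snps,
                 linkage_reference = linkage_ref,
                 linkage_junction_reads = linkage_reads,
                 carrier_calls = carrier_calls, config = config),
            class = "pgtsr_report")
}

#' @export
print.pgtsr_report <- function(x, ...) {
  cat(sprintf("PGT-SR report: %d embryos, %d reference, %d euploid\n",
              length(x$karyotypes), length(x$reference_embryos),
              length(x$euploid_embryos)))
  if (!is.null(x$cnv_estimates)) {
    cat("CNV breakpoints:\n"); print(x$cnv_estimates)
  }
  if (nrow(x$split_estimates) > 0) {
    cat("split-read breakpoints:\n"); print(x$split_estimates)
  }
  calls <- vapply(x$carrier_calls, function(cc) cc$call, "")
  if (length(calls)) {
    cat("carrier calls: ",
        paste(sprintf("%s=%s", names(calls), calls), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits TSV tables (karyotype strings, embryo classes, breakpoints,
#' concordance, haplotype linkage, carrier calls, a SNP-by-embryo haplotype
#' matrix), BEDPE junctions (0-based half-open), and a JSON summary.
#' Re-running on identical inputs produces byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character()
  karyo_df <- data.frame(
    embryo = names(report$karyotypes),
    karyotype = vapply(report$karyotypes, format_karyotype, ""),
    class = vapply(report$classes, function(x) x$class, ""),
    stringsAsFactors = FALSE)
  files <- c(files, tsv(karyo_df, "karyotypes.tsv"))
  est <- rbind(report$cnv_estimates, report$split_estimates)
  if (!is.null(est) && nrow(est) > 0) files <- c(files, tsv(est, "breakpoints.tsv"))
  if (!is.null(report$concordance))
    files <- c(files, tsv(report$concordance, "concordance.tsv"))
  cl <- report$junction_clusters
  if (nrow(cl) > 0) {
    bedpe <- data.frame(chrom1 = cl$chrom_a, start1 = as.integer(cl$pos_a - 1),
                        end1 = as.integer(cl$pos_a), chrom2 = cl$chrom_b,
                        start2 = as.integer(cl$pos_b - 1),
                        end2 = as.integer(cl$pos_b),
                        name = sprintf("junction_%d", seq_len(nrow(cl))),
                        score = cl$support, strand1 = cl$strand_a,
                        strand2 = cl$strand_b, stringsAsFactors = FALSE)
    path <- file.path(dir, "junctions.bedpe")
    utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, path)
  }
  linkages <- rbind(report$linkage_reference, report$linkage_junction_reads)
  if (!is.null(linkages)) files <- c(files, tsv(linkages, "haplotype_linkage.tsv"))
  if (length(report$carrier_calls)) {
    cc <- data.frame(
      embryo = names(report$carrier_calls),
      call = vapply(report$carrier_calls, function(x) x$call, ""),
      stringsAsFactors = FALSE)
    files <- c(files, tsv(cc, "carrier_calls.tsv"))
  }
  hm <- haplotype_matrix(report)
  if (!is.null(hm)) files <- c(files, tsv(hm, "haplotype_matrix.tsv"))
  summary <- list(
    n_embryos = length(report$karyotypes),
    reference_embryos = as.list(report$reference_embryos),
    euploid_embryos = as.list(report$euploid_embryos),
    read_stats = unclass(report$read_stats),
    carrier_calls = lapply(report$carrier_calls, function(x) x$call),
    thresholds = unclass(report$config)[c(
      "bin_width", "m", "dispersion", "ado", "min_qscore", "min_seg_bins",
      "seg_threshold", "cluster_tolerance", "min_junction_support",
      "flank_window", "min_snps", "majority", "consistency")],
    seed = report$config$seed)
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, path)
  invisible(files)
}

#' SNP-by-embryo transmitted-haplotype matrix
#'
#' Rows are informative SNPs, columns are embryos, cells are the carrier
#' haplotype (H1/H2) each embryo's observed alleles indicate at that site —
#' the tabular form of a flanking-SNP haplotype figure.
#'
#' @param report A [run_pipeline()] result.
#' @return data.frame, or `NULL` when no informative SNPs were selected.
#' @export
haplotype_matrix <- function(report) {
  snps <- report$informative_snps
  if (is.null(snps) || nrow(snps) == 0) return(NULL)
  obs <- report$pedigree$snp_obs
  ids <- names(report$karyotypes)
  m <- data.frame(chrom = snps$chrom, pos = snps$pos, flank = snps$flank,
                  stringsAsFactors = FALSE)
  for (id in ids) {
    m[[id]] <- .transmitted_haps(obs[obs$embryo == id, , drop = FALSE], snps)
  }
  m
}
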