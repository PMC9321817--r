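# Orchestration of the three analyses. Defaults reproduce the documented
# study parameterisation: 35% frequency bounds with the 1% dead-group
# floor, five-of-ten call-rate requirement, three-sample t-test cutoff,
# 1000-bp / 1000-SNP windows, coverage strictly above 10x and below the
# per-pool 95th percentile, 3-bp indel distance, 2-bp splice window.
# Outputs are pure functions of (inputs, config, seed); every run writes
# a provenance log with parameters and input checksums.

#' Pipeline run configuration
#'
#' @param window_mode,window_size window definition for the pooled scan.
#' @param cmh_mode `"all_pairs"` or `"independent"` strata.
#' @param min_cov,cov_quantile coverage filter parameters.
#' @param indel_distance SNP/indel exclusion distance (bp).
#' @param min_called per-group called-individual requirement for the
#'   frequency filter.
#' @param min_samples_with_data overall data requirement for the t-test.
#' @param alpha Bonferroni-adjusted significance level.
#' @param splice_window splice-site window (bp).
#' @param presence_thresholds list passed to [build_presence_matrix()].
#' @param network_limit parsimony network connection limit or `"auto"`.
#' @param seed integer seed recorded in the provenance log.
#' @param outdir output directory (`NULL` = do not write files).
#' @return list of class `run_config`.
#' @export
run_config <- function(window_mode = "genomic_bp", window_size = 1000,
                       cmh_mode = "all_pairs", min_cov = 10,
                       cov_quantile = 0.95, indel_distance = 3,
                       min_called = 5, min_samples_with_data = 3,
                       alpha = 0.05, splice_window = 2,
                       presence_thresholds = list(min_supporting_reads = 1,
                                                  min_allele_fraction = 0.05,
                                                  min_depth_for_call = 5),
                       network_limit = "auto", seed = 1, outdir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

write_provenance <- function(config, inputs, outdir, stage) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sums <- vapply(inputs, function(p)
    if (is.character(p) && length(p) == 1 && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_, "")
  params <- config[!vapply(config, is.list, TRUE)]
  lines <- c(sprintf("stage\t%s", stage),
             sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("%s\t%s", names(params),
                     vapply(params, function(v) paste(format(v), collapse = ","), "")),
             sprintf("input_md5_%s\t%s", names(sums), sums))
  writeLines(lines, file.path(outdir, paste0(stage, "_provenance.tsv")))
  invisible(NULL)
}

write_tsv <- function(df, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Run the pooled genome scan
#'
#' Sync input -> coverage filter -> biallelic extraction -> per-site and
#' windowed F_ST over all pools -> CMH across strata -> ranked report.
#' Indel-proximity filtering is applied first when indel anchors are
#' given (biallelic sites falling within `indel_distance` of an anchor
#' are removed).
#'
#' @param sync a [sync_table()] or path readable by [read_sync()].
#' @param samples a [sample_sheet()] or path.
#' @param config a [run_config()].
#' @param indels optional [variant_table()] of indel anchors.
#' @param pool_ids needed when `sync` is a path.
#' @return list: `sites` (per-site fst + cmh), `windows`, `report`,
#'   `strata`.
#' @export
run_poolscan <- function(sync, samples, config = run_config(),
                         indels = NULL, pool_ids = NULL) {
  paths <- list(sync = sync, samples = samples)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  if (is.character(sync)) {
    if (is.null(pool_ids))
      pool_ids <- samples$sample_id[samples$role == "pool"]
    sync <- read_sync(sync, pool_ids)
  }
  sync <- coverage_filter(sync, min_cov = config$min_cov,
                          upper_quantile = config$cov_quantile)
  hap <- stats::setNames(samples$pool_haploid_size, samples$sample_id)
  pc <- sync_to_pool_counts(sync, haploid_sizes = hap[sync$pool_ids])
  if (!is.null(indels) && nrow(indels$variants)) {
    keep <- rep(TRUE, nrow(pc$sites))
    for (ch in unique(pc$sites$chrom)) {
      ipos <- indels$variants$pos[indels$variants$chrom == ch]
      if (!length(ipos)) next
      i <- which(pc$sites$chrom == ch)
      keep[i] <- vapply(pc$sites$pos[i], function(p)
        min(abs(p - ipos)) > config$indel_distance, TRUE)
    }
    pc$sites <- pc$sites[keep, , drop = FALSE]
    pc$ref_count <- pc$ref_count[keep, , drop = FALSE]
    pc$alt_count <- pc$alt_count[keep, , drop = FALSE]
  }
  fst <- fst_sites(pc)
  spec <- window_spec(config$window_mode, config$window_size)
  windows <- assign_windows(pc$sites$chrom, pc$sites$pos, spec)
  fst_win <- window_means(fst$fst, windows)
  strata <- build_strata(samples, mode = config$cmh_mode)
  cmh <- cmh_scan(pc, strata)
  report <- scan_report(fst_win, cmh, windows)
  sites <- cbind(fst, chi2 = cmh$chi2, p_value = cmh$p_value,
                 k_used = cmh$k_used)
  write_provenance(config, paths, config$outdir, "poolscan")
  write_tsv(sites, config$outdir, "poolscan_sites.tsv")
  write_tsv(report, config$outdir, "poolscan_windows.tsv")
  list(sites = sites, windows = fst_win, report = report, strata = strata)
}

#' Run the targeted-enrichment association stage
#'
#' Presence matrix -> per-group frequencies -> frequency-differential
#' filter in all three comparisons -> intersection -> per-comparison
#' t-tests with Bonferroni -> effect classification of the significant
#' variants.
#'
#' @param variants a [variant_table()] or path.
#' @param samples a [sample_sheet()] or path.
#' @param gm a [gene_model()] or path (for effect classification;
#'   optional).
#' @param reference full-gene reference sequence (required with `gm`).
#' @param config a [run_config()].
#' @return list: `frequencies`, `filter` (per comparison), `common`,
#'   `ttests` (per comparison), `effects`, `category_counts`.
#' @export
run_assoc <- function(variants, samples, gm = NULL, reference = NULL,
                      config = run_config()) {
  paths <- list(variants = variants, samples = samples, gene_model = gm)
  if (is.character(variants)) variants <- read_variant_table(variants)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  if (is.character(gm)) gm <- read_gene_model(gm)
  pm <- do.call(build_presence_matrix,
                c(list(variants), config$presence_thresholds))
  freqs <- group_frequencies(pm, samples)
  filt <- lapply(stats::setNames(COMPARISONS, COMPARISONS), function(cmp)
    frequency_filter(freqs, cmp, min_called = config$min_called))
  common <- intersect_comparisons(filt)
  tt <- lapply(stats::setNames(COMPARISONS, COMPARISONS), function(cmp)
    ttest_association(pm, samples, cmp,
                      min_samples_with_data = config$min_samples_with_data))
  effects <- NULL
  category_counts <- NULL
  if (!is.null(gm) && !is.null(reference)) {
    sig <- do.call(rbind, lapply(COMPARISONS, function(cmp) {
      s <- filt[[cmp]]
      if (!nrow(s)) return(NULL)
      v <- variants$variants[s$variant, , drop = FALSE]
      eff <- classify_effect(v, gm, reference,
                             splice_window = config$splice_window)
      cbind(comparison = cmp, eff)
    }))
    if (!is.null(sig)) {
      effects <- sig
      category_counts <- summarize_by_category(sig)
    }
  }
  write_provenance(config, paths, config$outdir, "assoc")
  for (cmp in COMPARISONS) {
    write_tsv(filt[[cmp]], config$outdir,
              sprintf("assoc_filter_%s.tsv", gsub("-", "", cmp)))
    write_tsv(tt[[cmp]], config$outdir,
              sprintf("assoc_ttest_%s.tsv", gsub("-", "", cmp)))
  }
  list(frequencies = freqs, filter = filt, common = common, ttests = tt,
       effects = effects, category_counts = category_counts)
}

#' Run the candidate-gene haplotype analysis
#'
#' Phasing (unless pre-phased input is supplied) -> region diversity
#' statistics -> amino-acid scan -> parsimony network -> neighbor-joining
#' tree.
#'
#' @param alignment a [sequence_set()] or FASTA path (ambiguity-coded
#'   consensus, or phased copies with `prephased = TRUE`).
#' @param gm a [gene_model()] or path.
#' @param samples a [sample_sheet()] or path (country labels used as
#'   populations).
#' @param reference full-gene reference sequence; defaults to the
#'   majority-rule consensus of the phased haplotypes.
#' @param config a [run_config()].
#' @param prephased treat input records as haplotype copies named
#'   `<individual>.1/.2`.
#' @return list: `haplotypes`, `stats`, `aa_variants`, `network`, `tree`.
#' @export
run_hapdiv <- function(alignment, gm, samples = NULL, reference = NULL,
                       config = run_config(), prephased = FALSE) {
  paths <- list(alignment = alignment, gene_model = gm, samples = samples)
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(gm)) gm <- read_gene_model(gm)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  pop <- NULL
  if (!is.null(samples))
    pop <- stats::setNames(samples$country, samples$sample_id)
  if (prephased) {
    ind <- sub("\\.[12]$", "", names(alignment$seq))
    hs <- haplotype_set(alignment$seq, individual = ind,
                        population = if (!is.null(pop)) unname(pop[ind]))
  } else {
    hs <- phase_sequences(alignment, population = pop)
  }
  if (is.null(reference)) {
    m <- seq_matrix(hs$seq)
    reference <- paste(apply(m, 2, function(col)
      names(sort(table(col[col != "N"]), decreasing = TRUE))[1]),
      collapse = "")
  }
  stats_df <- partition_stats(hs, gm)
  aa <- amino_acid_scan(hs, gm, reference)
  net <- parsimony_network(hs, connection_limit = config$network_limit)
  tree <- distance_tree(hs)
  write_provenance(config, paths, config$outdir, "hapdiv")
  write_tsv(stats_df, config$outdir, "hapdiv_diversity.tsv")
  write_tsv(aa, config$outdir, "hapdiv_aa_variants.tsv")
  if (!is.null(config$outdir)) {
    write_network(net, file.path(config$outdir, "hapdiv_network.tsv"))
    write_tree_file(tree, file.path(config$outdir, "hapdiv_tree.nwk"))
  }
  list(haplotypes = hs, stats = stats_df, aa_variants = aa, network = net,
       tree = tree)
}
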