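# Individual-level targeted-enrichment association: presence/absence
# frequency-differential filter between phenotype groups, three-way
# comparison intersection, per-variant unpaired t-test with Bonferroni
# correction, and codon-level effect classification against a gene model.

COMPARISONS <- c("R-C", "R-S", "C-S")
GROUP_CODE <- c(R = "alive", C = "dead", S = "lab_susceptible")
EFFECT_CATEGORIES <- c("Nsyn", "SpS", "Syn", "Int", "5'UTR", "3'UTR",
                       "intergenic")

## ---- presence matrix -----------------------------------------------------

#' Build a presence/absence/missing call matrix
#'
#' A cell is `missing` when the sample's depth at the variant is below
#' `min_depth_for_call` (no data, never treated as absence); otherwise
#' `present` when the supporting reads and allele fraction both clear
#' their thresholds, else `absent`.
#'
#' @param vt a [variant_table()].
#' @param min_supporting_reads minimum alt-supporting reads for presence.
#' @param min_allele_fraction minimum supporting/depth for presence.
#' @param min_depth_for_call minimum depth for a call at all.
#' @return object of class `presence_matrix`: list with `calls`
#'   (character matrix `present`/`absent`/`missing`), `fraction`
#'   (numeric, `NA` when missing), `variants`, `samples`, `params`.
#' @export
build_presence_matrix <- function(vt, min_supporting_reads = 1,
                                  min_allele_fraction = 0.05,
                                  min_depth_for_call = 5) {
  stopifnot(inherits(vt, "variant_table"))
  frac <- allele_fractions(vt)
  missing <- vt$depth < min_depth_for_call
  present <- !missing & vt$supporting >= min_supporting_reads &
    !is.na(frac) & frac >= min_allele_fraction
  calls <- matrix("absent", nrow(vt$variants), length(vt$samples),
                  dimnames = list(NULL, vt$samples))
  calls[present] <- "present"
  calls[missing] <- "missing"
  frac[missing] <- NA_real_
  structure(list(calls = calls, fraction = frac, variants = vt$variants,
                 samples = vt$samples,
                 params = list(min_supporting_reads = min_supporting_reads,
                               min_allele_fraction = min_allele_fraction,
                               min_depth_for_call = min_depth_for_call)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d variant(s) x %d individual(s)\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' Per-group presence frequencies
#'
#' The frequency of a variant in a group is the fraction of *called*
#' (non-missing) individuals in which it is present — mosquitoes are
#' counted, read fractions are not averaged. A group with zero called
#' individuals at a variant yields `NA` (excluded downstream).
#'
#' @param pm a [build_presence_matrix()] result.
#' @param samples a [sample_sheet()] (role `individual`).
#' @return data.frame: one row per variant x group with `group` (R/C/S),
#'   `n_called`, `n_present`, `freq`.
#' @export
group_frequencies <- function(pm, samples) {
  stopifnot(inherits(pm, "presence_matrix"))
  ind <- samples[samples$role == "individual", , drop = FALSE]
  out <- list()
  for (g in names(GROUP_CODE)) {
    ids <- intersect(ind$sample_id[ind$group == GROUP_CODE[[g]]], pm$samples)
    if (!length(ids)) next
    sub <- pm$calls[, ids, drop = FALSE]
    n_called <- rowSums(sub != "missing")
    n_present <- rowSums(sub == "present")
    out[[g]] <- data.frame(variant = seq_len(nrow(pm$variants)),
                           chrom = pm$variants$chrom, pos = pm$variants$pos,
                           alt = pm$variants$alt, group = g,
                           n_called = n_called, n_present = n_present,
                           freq = ifelse(n_called > 0,
                                         n_present / n_called, NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- frequency-differential filter ---------------------------------------

#' Frequency-differential significance filter
#'
#' For the field alive/dead comparison (`R-C`) a variant is significant
#' when its presence frequency is in `[0.35, 1]` in the high group and in
#' `[0.01, 0.35)` in the low group (the 1% lower bound means the variant
#' must be observed in the low group at least once; set
#' `low_bounds = c(0, 0.35)` to drop it). For comparisons against the
#' susceptible laboratory colony (`R-S`, `C-S`) the field group must
#' exceed 0.35 and the colony be below 0.35. Both groups additionally
#' need at least `min_called` called individuals.
#'
#' `direction = "auto"` tests the default orientation (first group high)
#' and, for `R-C`, also the reversed orientation — populations where
#' resistance is near fixation can show the informative differential with
#' the dead group high.
#'
#' @param freqs output of [group_frequencies()].
#' @param comparison one of `"R-C"`, `"R-S"`, `"C-S"`.
#' @param high_bounds closed interval for the high group (default
#'   `c(0.35, 1)`; lower bound inclusive, and for S-comparisons the
#'   lower bound is exclusive per the `>35%` rule).
#' @param low_bounds interval for the low group; upper bound exclusive.
#' @param min_called minimum called individuals per group (default 5,
#'   i.e., five out of 10).
#' @param direction `"auto"`, `"R-high"` or `"C-high"`.
#' @return data.frame of significant variants: `variant`, `chrom`, `pos`,
#'   `alt`, `comparison`, `direction`, `freq_high`, `freq_low`.
#' @export
frequency_filter <- function(freqs, comparison = c("R-C", "R-S", "C-S"),
                             high_bounds = c(0.35, 1),
                             low_bounds = NULL,
                             min_called = 5,
                             direction = c("auto", "R-high", "C-high")) {
  comparison <- match.arg(comparison)
  direction <- match.arg(direction)
  gg <- strsplit(comparison, "-", fixed = TRUE)[[1]]
  vs_lab <- gg[2] == "S"
  if (is.null(low_bounds))
    low_bounds <- if (vs_lab) c(0, 0.35) else c(0.01, 0.35)

  wide <- merge(freqs[freqs$group == gg[1], ],
                freqs[freqs$group == gg[2], ],
                by = c("variant", "chrom", "pos", "alt"),
                suffixes = c("_1", "_2"))
  ok_n <- !is.na(wide$freq_1) & !is.na(wide$freq_2) &
    wide$n_called_1 >= min_called & wide$n_called_2 >= min_called

  in_high <- function(f) if (vs_lab)
    f > high_bounds[1] & f <= high_bounds[2]
  else f >= high_bounds[1] & f <= high_bounds[2]
  in_low <- function(f) f >= low_bounds[1] & f < low_bounds[2]

  fwd <- ok_n & in_high(wide$freq_1) & in_low(wide$freq_2)
  rev <- ok_n & in_high(wide$freq_2) & in_low(wide$freq_1)

  dir_of <- function(first_high) {
    hi <- if (first_high) gg[1] else gg[2]
    if (hi == "R") "R-high" else "C-high"
  }
  sel <- switch(direction,
                "R-high" = if (gg[1] == "R") fwd else rev,
                "C-high" = if (gg[1] == "C") fwd else if (gg[2] == "C") rev
                           else fwd & FALSE,
                "auto" = if (comparison == "R-C") fwd | rev else fwd)
  out <- wide[sel, , drop = FALSE]
  if (nrow(out) == 0)
    return(data.frame(variant = integer(), chrom = character(),
                      pos = integer(), alt = character(),
                      comparison = character(), direction = character(),
                      freq_high = numeric(), freq_low = numeric()))
  first_high <- fwd[sel]
  data.frame(variant = out$variant, chrom = out$chrom, pos = out$pos,
             alt = out$alt, comparison = comparison,
             direction = vapply(first_high, dir_of, ""),
             freq_high = ifelse(first_high, out$freq_1, out$freq_2),
             freq_low = ifelse(first_high, out$freq_2, out$freq_1),
             row.names = NULL)
}

#' Intersect per-comparison significant variant sets
#'
#' Intersection is on the (chrom, pos, alt) key. When gene intervals are
#' supplied, the unique genes containing at least one common variant are
#' listed.
#'
#' @param sets named list (>= 2) of [frequency_filter()] outputs.
#' @param genes optional data.frame `gene_id`, `chrom`, `start`, `end`.
#' @return list with `variants` (data.frame chrom, pos, alt) and
#'   `genes` (character vector).
#' @export
intersect_comparisons <- function(sets, genes = NULL) {
  stopifnot(length(sets) >= 2)
  keys <- lapply(sets, function(s) paste(s$chrom, s$pos, s$alt, sep = "\r"))
  common <- Reduce(intersect, keys)
  first <- sets[[1]]
  hit <- paste(first$chrom, first$pos, first$alt, sep = "\r") %in% common
  vars <- unique(first[hit, c("chrom", "pos", "alt"), drop = FALSE])
  rownames(vars) <- NULL
  gl <- character()
  if (!is.null(genes) && nrow(vars)) {
    for (i in seq_len(nrow(vars))) {
      g <- genes$gene_id[genes$chrom == vars$chrom[i] &
                           genes$start <= vars$pos[i] &
                           genes$end >= vars$pos[i]]
      gl <- union(gl, g)
    }
  }
  list(variants = vars, genes = gl)
}

## ---- t-test association ---------------------------------------------------

#' Per-variant unpaired t-test on individual allele fractions
#'
#' Two-sample pooled-variance (Student) t-test on per-individual allele
#' fractions, two-sided, with Bonferroni correction over the variants
#' actually tested in the comparison. A variant is tested when it has
#' non-missing fractions in at least `min_samples_with_data` individuals
#' overall and at least two per group. Zero variance in both groups with
#' equal means yields `t = 0, p = 1`; zero variance with unequal means
#' yields `t = +/-Inf, p = 0`. Reference significance thresholds
#' `p = 5e-5` (field-field) and `p = 5e-22` (field versus laboratory
#' colony) are marked on the output.
#'
#' @param pm a [build_presence_matrix()] result (its `fraction` matrix is
#'   used; missing cells are excluded).
#' @param samples a [sample_sheet()].
#' @param comparison one of `"R-C"`, `"R-S"`, `"C-S"`.
#' @param min_samples_with_data minimum individuals with data overall.
#' @return data.frame per tested variant: `variant`, `chrom`, `pos`,
#'   `alt`, `comparison`, `mean_1`, `mean_2`, `t`, `df`, `p`,
#'   `p_bonferroni`, `n_with_data`, `below_threshold` (logical at the
#'   marked threshold); attribute `"m_tests"` gives the Bonferroni m,
#'   attribute `"skipped"` a data.frame of skipped variants with reasons.
#' @export
ttest_association <- function(pm, samples, comparison = c("R-C", "R-S", "C-S"),
                              min_samples_with_data = 3) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(pm, "presence_matrix"))
  gg <- strsplit(comparison, "-", fixed = TRUE)[[1]]
  ind <- samples[samples$role == "individual", , drop = FALSE]
  ids1 <- intersect(ind$sample_id[ind$group == GROUP_CODE[[gg[1]]]],
                    pm$samples)
  ids2 <- intersect(ind$sample_id[ind$group == GROUP_CODE[[gg[2]]]],
                    pm$samples)
  x <- pm$fraction[, ids1, drop = FALSE]
  y <- pm$fraction[, ids2, drop = FALSE]
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  tested <- n1 + n2 >= min_samples_with_data & n1 >= 2 & n2 >= 2
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- apply(x, 1, stats::var, na.rm = TRUE)
  v2 <- apply(y, 1, stats::var, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se,
                  ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  p <- ifelse(is.finite(tstat),
              2 * stats::pt(-abs(tstat), df),
              0)
  p[tstat == 0] <- 1
  m <- sum(tested)
  thr <- if (any(gg == "S")) 5e-22 else 5e-5
  out <- data.frame(variant = seq_len(nrow(pm$variants)),
                    chrom = pm$variants$chrom, pos = pm$variants$pos,
                    alt = pm$variants$alt, comparison = comparison,
                    mean_1 = m1, mean_2 = m2, t = tstat, df = df, p = p,
                    p_bonferroni = pmin(1, p * m),
                    n_with_data = n1 + n2)[tested, , drop = FALSE]
  out$below_threshold <- out$p < thr
  rownames(out) <- NULL
  attr(out, "m_tests") <- m
  attr(out, "threshold") <- thr
  skip <- data.frame(variant = which(!tested),
                     reason = ifelse(n1[!tested] < 2 | n2[!tested] < 2,
                                     "fewer than 2 individuals with data in a group",
                                     "too few individuals with data overall"))
  attr(out, "skipped") <- skip
  out
}

## ---- effect classification -------------------------------------------------

# genomic position -> 1-based coding index (NA outside CDS), strand-aware
coding_index <- function(pos, gm) {
  cds <- gm$cds_intervals
  widths <- cds$end - cds$start + 1
  offs <- cumsum(c(0, widths[-length(widths)]))
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(cds))) {
    in_i <- pos >= cds$start[i] & pos <= cds$end[i]
    idx[in_i] <- offs[i] + pos[in_i] - cds$start[i] + 1L
  }
  if (gm$strand == "-") idx <- ifelse(is.na(idx), NA_integer_,
                                      gm$coding_length - idx + 1L)
  idx
}

# extract the concatenated coding sequence from a full-gene sequence,
# reverse-complemented for minus-strand models
coding_sequence <- function(seq, gm) {
  pieces <- substring(seq, gm$cds_intervals$start, gm$cds_intervals$end)
  cds <- paste(pieces, collapse = "")
  if (gm$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

translate_dna <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Classify the coding effect of variants against a gene model
#'
#' SNPs inside the coding region are translated (standard genetic code,
#' strand-aware) to `Syn` or `Nsyn` with an amino-acid change string such
#' as `G454A` (positions are 1-based on the translated coding sequence).
#' Intronic positions within `splice_window` bp of an exon/intron
#' boundary are splice-site (`SpS`), other intron positions `Int`; UTR
#' membership is by interval; positions outside the model are
#' `intergenic`. A premature stop is reported as a nonsense change (alt
#' residue `*`), not an error. Multi-base variants spanning a feature
#' boundary are classified by their first base with a warning.
#'
#' @param variants data.frame with `pos` (gene-local, 1-based), `ref`,
#'   `alt`.
#' @param gm a [gene_model()].
#' @param reference full-gene reference sequence (length
#'   `gm$total_length`).
#' @param splice_window bp from an exon boundary classified as splice
#'   site (default 2).
#' @return data.frame: `pos`, `ref`, `alt`, `category`,
#'   `amino_acid_change` (`NA` unless `Nsyn`).
#' @export
classify_effect <- function(variants, gm, reference, splice_window = 2) {
  stopifnot(inherits(gm, "gene_model"),
            nchar(reference) == gm$total_length)
  reference <- toupper(reference)
  cds_ref <- coding_sequence(reference, gm)
  aa_ref <- translate_dna(cds_ref)
  # per-base feature lookup: UTRs and introns are authoritative, exon
  # bases outside them are coding
  feat <- rep("intergenic", gm$total_length)
  for (i in which(gm$features$kind == "exon"))
    feat[gm$features$start[i]:gm$features$end[i]] <- "cds"
  for (i in which(gm$features$kind != "exon"))
    feat[gm$features$start[i]:gm$features$end[i]] <- gm$features$kind[i]
  intr <- gm$features[gm$features$kind == "intron", , drop = FALSE]

  n <- nrow(variants)
  category <- character(n)
  aa_change <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pos <- variants$pos[i]
    if (nchar(variants$ref[i]) > 1) {
      span <- pos:(pos + nchar(variants$ref[i]) - 1)
      if (length(unique(feat[pmin(span, gm$total_length)])) > 1)
        warning("variant at ", pos,
                " spans a feature boundary; classified by first base")
    }
    if (pos < 1 || pos > gm$total_length) { category[i] <- "intergenic"; next }
    f <- feat[pos]
    if (f == "cds") {
      ci <- coding_index(pos, gm)
      alt_base <- substr(variants$alt[i], 1, 1)
      if (gm$strand == "-")
        alt_base <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(alt_base)))
      cds_alt <- cds_ref
      substr(cds_alt, ci, ci) <- alt_base
      codon <- (ci - 1) %/% 3 + 1
      aa_from <- substr(aa_ref, codon, codon)
      aa_to <- translate_dna(substr(cds_alt, (codon - 1) * 3 + 1, codon * 3))
      if (aa_from == aa_to) {
        category[i] <- "Syn"
      } else {
        category[i] <- "Nsyn"
        aa_change[i] <- paste0(aa_from, codon, aa_to)
      }
    } else if (f == "intron") {
      j <- which(intr$start <= pos & intr$end >= pos)[1]
      d <- min(pos - intr$start[j] + 1, intr$end[j] - pos + 1)
      category[i] <- if (d <= splice_window) "SpS" else "Int"
    } else if (f == "five_prime_utr") {
      category[i] <- "5'UTR"
    } else if (f == "three_prime_utr") {
      category[i] <- "3'UTR"
    } else {
      category[i] <- "intergenic"
    }
  }
  data.frame(pos = variants$pos, ref = variants$ref, alt = variants$alt,
             category = category, amino_acid_change = aa_change)
}

#' Count significant variants by effect category
#'
#' @param annotated data.frame with a `category` column (and optionally
#'   `comparison`).
#' @return data.frame of counts in the fixed category order
#'   (Nsyn, SpS, Syn, Int, 5'UTR, 3'UTR, intergenic), one row per
#'   comparison when present.
#' @export
summarize_by_category <- function(annotated) {
  cats <- EFFECT_CATEGORIES
  count_one <- function(df) {
    tab <- table(factor(df$category, levels = cats))
    stats::setNames(as.data.frame(as.list(as.integer(tab))), cats)
  }
  if (!is.null(annotated$comparison) && nrow(annotated)) {
    sp <- split(annotated, annotated$comparison)
    out <- do.call(rbind, lapply(sp, count_one))
    out <- cbind(comparison = names(sp), out)
    rownames(out) <- NULL
    out
  } else {
    count_one(if (nrow(annotated)) annotated else
      data.frame(category = character()))
  }
}
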