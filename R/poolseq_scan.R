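# Replicated pooled-template genome scan: site filters, per-site and
# windowed F_ST on pool allele frequencies, and the Cochran-Mantel-Haenszel
# test across replicate alive/dead pool pairings.

## ---- biallelic extraction ------------------------------------------------

#' Extract biallelic sites from a sync table
#'
#' A site is biallelic when exactly two of the four nucleotides have a
#' nonzero read count summed over pools. The reference allele is the
#' site's reference base when it is one of the two observed alleles,
#' otherwise the majority allele; the other observed allele is the
#' alternate.
#'
#' @param sync a [sync_table()].
#' @param haploid_sizes named numeric vector of pool haploid sizes
#'   (chromosomes); defaults to `NA` (only needed by bias-corrected
#'   estimators).
#' @return An object of class `pool_counts`: list with `sites`
#'   (chrom, pos, ref_allele, alt_allele), matrices `ref_count` and
#'   `alt_count` (sites x pools), `pool_ids`, `haploid_sizes`.
#' @export
sync_to_pool_counts <- function(sync, haploid_sizes = NULL) {
  stopifnot(inherits(sync, "sync_table"))
  np <- length(sync$pool_ids)
  if (is.null(haploid_sizes))
    haploid_sizes <- stats::setNames(rep(NA_real_, np), sync$pool_ids)
  nuc <- c("A", "T", "C", "G")
  tot <- apply(sync$counts[, nuc, , drop = FALSE], c(1, 2), sum)
  if (nrow(sync$sites) == 0)
    tot <- matrix(0, 0, 4, dimnames = list(NULL, nuc))
  nall <- rowSums(tot > 0)
  keep <- which(nall == 2)
  sites <- sync$sites[keep, , drop = FALSE]
  ref_a <- alt_a <- character(length(keep))
  ref_count <- alt_count <- matrix(0L, length(keep), np,
                                   dimnames = list(NULL, sync$pool_ids))
  for (k in seq_along(keep)) {
    i <- keep[k]
    obs <- nuc[tot[i, ] > 0]
    if (sites$ref[k] %in% obs) {
      ref_a[k] <- sites$ref[k]
      alt_a[k] <- setdiff(obs, sites$ref[k])
    } else {
      o <- obs[order(tot[i, obs], decreasing = TRUE)]
      ref_a[k] <- o[1]; alt_a[k] <- o[2]
    }
    ref_count[k, ] <- sync$counts[i, ref_a[k], ]
    alt_count[k, ] <- sync$counts[i, alt_a[k], ]
  }
  structure(list(sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                                    ref_allele = ref_a, alt_allele = alt_a),
                 ref_count = ref_count, alt_count = alt_count,
                 pool_ids = sync$pool_ids, haploid_sizes = haploid_sizes),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d biallelic site(s) x %d pool(s)\n",
              nrow(x$sites), length(x$pool_ids)))
  invisible(x)
}

#' Pool sample allele frequencies
#' @param x a `pool_counts` object.
#' @return matrix of alternate-allele frequencies, `NA` at zero coverage.
#' @export
pool_frequencies <- function(x) {
  stopifnot(inherits(x, "pool_counts"))
  cov <- x$ref_count + x$alt_count
  f <- x$alt_count / cov
  f[cov == 0] <- NA_real_
  f
}

## ---- site filters --------------------------------------------------------

#' Remove SNPs close to predicted indels
#'
#' Retains a SNP only when its distance to the nearest indel anchor
#' position on the same chromosome is strictly greater than
#' `min_distance` (default 3 bp, so a SNP exactly 3 bp from an indel is
#' removed).
#'
#' @param snps,indels [variant_table()]s sorted by chrom, pos.
#' @param min_distance minimum exclusive distance in bp.
#' @return the filtered SNP [variant_table()].
#' @export
filter_near_indels <- function(snps, indels, min_distance = 3) {
  stopifnot(inherits(snps, "variant_table"), inherits(indels, "variant_table"))
  if (nrow(indels$variants) == 0) return(snps)
  keep <- rep(TRUE, nrow(snps$variants))
  for (ch in unique(snps$variants$chrom)) {
    s_idx <- which(snps$variants$chrom == ch)
    ipos <- sort(indels$variants$pos[indels$variants$chrom == ch])
    if (!length(ipos)) next
    spos <- snps$variants$pos[s_idx]
    lo <- findInterval(spos, ipos)
    d_lo <- ifelse(lo >= 1, spos - ipos[pmax(lo, 1)], Inf)
    d_hi <- ifelse(lo < length(ipos), ipos[pmin(lo + 1, length(ipos))] - spos,
                   Inf)
    keep[s_idx] <- pmin(d_lo, d_hi) > min_distance
  }
  subset_variant_table(snps, keep)
}

# row subset of a variant_table
subset_variant_table <- function(x, keep) {
  variant_table(x$variants[keep, , drop = FALSE],
                x$supporting[keep, , drop = FALSE],
                x$depth[keep, , drop = FALSE], x$samples)
}

#' Coverage filter for pooled sites
#'
#' Per pool, the upper threshold is that pool's empirical 95th coverage
#' percentile (linear interpolation) over all sites in the input. A site
#' is retained only when every pool's coverage is strictly greater than
#' `min_cov` and strictly below its pool's threshold. With constant
#' coverage the percentile equals that coverage and every site is dropped
#' by the strict upper bound; this edge case is intentional and tested.
#'
#' @param sync a nonempty [sync_table()].
#' @param min_cov strict lower bound on coverage (default 10).
#' @param upper_quantile quantile for the per-pool upper threshold.
#' @return filtered [sync_table()], with the thresholds attached as
#'   attribute `"upper_thresholds"`.
#' @export
coverage_filter <- function(sync, min_cov = 10, upper_quantile = 0.95) {
  stopifnot(inherits(sync, "sync_table"))
  if (nrow(sync$sites) == 0) stop("empty sync table")
  cov <- sync_coverage(sync)
  thr <- apply(cov, 2, stats::quantile, probs = upper_quantile, names = FALSE)
  keep <- rowSums(cov > min_cov) == ncol(cov) &
    rowSums(sweep(cov, 2, thr, "<")) == ncol(cov)
  out <- sync_table(sync$sites[keep, , drop = FALSE],
                    sync$counts[keep, , , drop = FALSE], sync$pool_ids)
  attr(out, "upper_thresholds") <- stats::setNames(thr, sync$pool_ids)
  out
}

## ---- F_ST ----------------------------------------------------------------

#' Per-site F_ST over a set of pools
#'
#' Classical heterozygosity estimator on pool sample frequencies:
#' `H_S` is the unweighted mean over included pools of `2*p(1-p)`,
#' `H_T = 2*pbar*(1-pbar)` with `pbar` the unweighted mean frequency, and
#' `F_ST = (H_T - H_S)/H_T`, undefined (`NA`) when `H_T = 0`. Negative
#' values are reported as computed. With `correct_bias = TRUE` the
#' within-pool heterozygosity is inflated by `c/(c-1)` (read-sampling
#' small-coverage correction, requiring coverage >= 2).
#'
#' @param pc a `pool_counts` object.
#' @param pools pool ids (or indices) to include; default all.
#' @param correct_bias apply the finite-coverage correction to `H_S`.
#' @return data.frame with chrom, pos, `h_s`, `h_t`, `fst`.
#' @export
fst_sites <- function(pc, pools = pc$pool_ids, correct_bias = FALSE) {
  stopifnot(inherits(pc, "pool_counts"))
  if (length(pools) < 2) stop("need at least 2 pools")
  f <- pool_frequencies(pc)[, pools, drop = FALSE]
  het <- 2 * f * (1 - f)
  if (correct_bias) {
    cov <- (pc$ref_count + pc$alt_count)[, pools, drop = FALSE]
    het <- het * cov / pmax(cov - 1, 1)
  }
  h_s <- rowMeans(het)
  pbar <- rowMeans(f)
  h_t <- 2 * pbar * (1 - pbar)
  fst <- ifelse(h_t == 0, NA_real_, (h_t - h_s) / h_t)
  data.frame(chrom = pc$sites$chrom, pos = pc$sites$pos,
             h_s = h_s, h_t = h_t, fst = fst)
}

#' Pairwise per-site F_ST between two pool subsets
#'
#' The two subsets are pooled into one included set; see [fst_sites()].
#' Symmetric in argument order and invariant under ref/alt relabeling.
#'
#' @param pc a `pool_counts` object.
#' @param pools_a,pools_b nonempty, disjoint pool id vectors.
#' @inheritParams fst_sites
#' @return as [fst_sites()].
#' @export
site_fst <- function(pc, pools_a, pools_b, correct_bias = FALSE) {
  if (!length(pools_a) || !length(pools_b)) stop("empty pool subset")
  fst_sites(pc, pools = c(pools_a, pools_b), correct_bias = correct_bias)
}

## ---- windows -------------------------------------------------------------

#' Window specification
#'
#' @param mode `"genomic_bp"` (fixed-width nonoverlapping windows; window
#'   `k` covers 1-based positions `[k*size+1, (k+1)*size]`) or
#'   `"snp_count"` (consecutive runs of `size` retained SNPs per
#'   chromosome; the last partial window is kept and flagged).
#' @param size window size (bp or SNPs), >= 1.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(mode = c("genomic_bp", "snp_count"), size = 1000) {
  mode <- match.arg(mode)
  stopifnot(size >= 1)
  structure(list(mode = mode, size = as.integer(size)), class = "window_spec")
}

#' Assign sites to nonoverlapping windows
#'
#' Windows never span chromosomes.
#'
#' @param chrom,pos site coordinates (sorted by chrom, pos).
#' @param spec a [window_spec()].
#' @return data.frame with `window_id` (text key `chrom:index`), `chrom`,
#'   `window_index` (0-based), `win_start`, `win_end` (1-based inclusive;
#'   for `snp_count` mode the realized position span), `partial` flag.
#' @export
assign_windows <- function(chrom, pos, spec) {
  stopifnot(inherits(spec, "window_spec"))
  n <- length(pos)
  if (n == 0)
    return(data.frame(window_id = character(), chrom = character(),
                      window_index = integer(), win_start = integer(),
                      win_end = integer(), partial = logical()))
  if (spec$mode == "genomic_bp") {
    idx <- as.integer((pos - 1) %/% spec$size)
    data.frame(window_id = paste0(chrom, ":", idx), chrom = chrom,
               window_index = idx, win_start = idx * spec$size + 1L,
               win_end = (idx + 1L) * spec$size, partial = FALSE)
  } else {
    idx <- integer(n); partial <- logical(n)
    for (ch in unique(chrom)) {
      w <- which(chrom == ch)
      k <- (seq_along(w) - 1L) %/% spec$size
      idx[w] <- k
      nlast <- sum(k == max(k))
      partial[w] <- k == max(k) & nlast < spec$size
    }
    # realized span per window
    key <- paste0(chrom, ":", idx)
    st <- stats::ave(pos, key, FUN = min)
    en <- stats::ave(pos, key, FUN = max)
    data.frame(window_id = key, chrom = chrom, window_index = idx,
               win_start = st, win_end = en, partial = partial)
  }
}

#' Window means of a per-site statistic
#'
#' Undefined (`NA`) site values are excluded from the mean; a window with
#' no defined site gets `NA` and `n_sites` counts defined sites only.
#'
#' @param values per-site numeric statistic.
#' @param windows output of [assign_windows()] for the same sites.
#' @return data.frame, one row per window, ordered by (chrom, window
#'   index): `window_id`, `chrom`, `window_index`, `win_start`,
#'   `win_end`, `partial`, `mean_value`, `n_sites`.
#' @export
window_means <- function(values, windows) {
  stopifnot(length(values) == nrow(windows))
  if (nrow(windows) == 0)
    return(data.frame(window_id = character(), chrom = character(),
                      window_index = integer(), win_start = integer(),
                      win_end = integer(), partial = logical(),
                      mean_value = numeric(), n_sites = integer()))
  sp <- split(seq_along(values), windows$window_id)
  rows <- lapply(sp, function(i) {
    v <- values[i]
    data.frame(window_id = windows$window_id[i[1]],
               chrom = windows$chrom[i[1]],
               window_index = windows$window_index[i[1]],
               win_start = min(windows$win_start[i]),
               win_end = max(windows$win_end[i]),
               partial = any(windows$partial[i]),
               mean_value = if (all(is.na(v))) NA_real_
                            else mean(v, na.rm = TRUE),
               n_sites = sum(!is.na(v)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- CMH strata and test -------------------------------------------------

#' Build alive/dead strata for the CMH test
#'
#' `all_pairs` forms the Cartesian product of alive and dead pools (e.g.,
#' six strata from three alive and two dead pools); this reuses pools
#' across strata and therefore violates the independence assumption of
#' the test — kept because the scan design it reproduces did the same.
#' `independent` takes an explicit disjoint pairing.
#'
#' @param samples a [sample_sheet()] restricted to pools.
#' @param mode `"all_pairs"` or `"independent"`.
#' @param pairing for `independent`: data.frame with columns `alive`,
#'   `dead` of pool ids, no pool reused.
#' @return data.frame with columns `alive`, `dead`, one row per stratum.
#' @export
build_strata <- function(samples, mode = c("all_pairs", "independent"),
                         pairing = NULL) {
  mode <- match.arg(mode)
  pools <- samples[samples$role == "pool", , drop = FALSE]
  alive <- pools$sample_id[pools$group == "alive"]
  dead <- pools$sample_id[pools$group == "dead"]
  if (!length(alive) || !length(dead))
    stop("need at least one alive and one dead pool")
  if (mode == "all_pairs") {
    expand.grid(alive = alive, dead = dead, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, c("alive", "dead")]
  } else {
    stopifnot(!is.null(pairing), all(c("alive", "dead") %in% names(pairing)))
    ids <- c(pairing$alive, pairing$dead)
    if (anyDuplicated(ids))
      stop("independent pairing reuses pool(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (!all(pairing$alive %in% alive) || !all(pairing$dead %in% dead))
      stop("pairing references unknown or mis-grouped pools")
    pairing[, c("alive", "dead")]
  }
}

#' Cochran-Mantel-Haenszel scan over sites
#'
#' Each stratum contributes a 2x2 table of (alt, ref) read counts for its
#' (alive, dead) pool pair. With `a_k` the alive alt count, row totals
#' `R1_k` (alt) and `R2_k` (ref), column totals `C1_k` (alive) and
#' `C2_k` (dead) and `N_k` the table total, the continuity-corrected
#' statistic is
#' `chi2 = (|sum a_k - sum E_k| - 0.5)^2 / sum V_k` with
#' `E_k = R1_k C1_k / N_k` and
#' `V_k = R1_k R2_k C1_k C2_k / (N_k^2 (N_k - 1))`; the p-value is from
#' the chi-square distribution with 1 df. Strata with a zero margin (or
#' `N_k < 2`) are dropped per site and `k_used` reports how many remain;
#' a site where all strata are degenerate gets `NA`.
#'
#' @param pc a `pool_counts` object.
#' @param strata data.frame from [build_strata()].
#' @return data.frame: chrom, pos, `chi2`, `p_value`, `k_used`.
#' @export
cmh_scan <- function(pc, strata) {
  stopifnot(inherits(pc, "pool_counts"))
  n <- nrow(pc$sites)
  suma <- sumE <- sumV <- numeric(n)
  k_used <- integer(n)
  for (s in seq_len(nrow(strata))) {
    a <- pc$alt_count[, strata$alive[s]]
    b <- pc$ref_count[, strata$alive[s]]
    c_ <- pc$alt_count[, strata$dead[s]]
    d <- pc$ref_count[, strata$dead[s]]
    N <- a + b + c_ + d
    R1 <- a + c_; R2 <- b + d; C1 <- a + b; C2 <- c_ + d
    ok <- N >= 2 & R1 > 0 & R2 > 0 & C1 > 0 & C2 > 0
    E <- ifelse(ok, R1 * C1 / N, 0)
    V <- ifelse(ok, R1 * R2 * C1 * C2 / (N^2 * (N - 1)), 0)
    suma <- suma + ifelse(ok, a, 0)
    sumE <- sumE + E
    sumV <- sumV + V
    k_used <- k_used + ok
  }
  # the 0.5 correction is applied only when |delta| >= 0.5, matching the
  # classical definition (the correction must not overshoot zero)
  delta <- abs(suma - sumE)
  cc <- ifelse(delta >= 0.5, 0.5, 0)
  chi2 <- ifelse(sumV > 0, (delta - cc)^2 / sumV, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chrom = pc$sites$chrom, pos = pc$sites$pos,
             chi2 = chi2, p_value = p, k_used = k_used)
}

#' CMH test for a single site
#'
#' Scalar interface over [cmh_scan()] for one 2x2xK table of read counts.
#'
#' @param alive_alt,alive_ref,dead_alt,dead_ref numeric vectors of length
#'   K (one entry per stratum).
#' @return list with `chi2`, `p_value`, `k_used`.
#' @export
cmh_test <- function(alive_alt, alive_ref, dead_alt, dead_ref) {
  K <- length(alive_alt)
  stopifnot(length(alive_ref) == K, length(dead_alt) == K,
            length(dead_ref) == K)
  ids <- c(paste0("a", seq_len(K)), paste0("d", seq_len(K)))
  pc <- structure(list(
    sites = data.frame(chrom = "x", pos = 1L, ref_allele = "A",
                       alt_allele = "C"),
    ref_count = matrix(c(alive_ref, dead_ref), 1,
                       dimnames = list(NULL, ids)),
    alt_count = matrix(c(alive_alt, dead_alt), 1,
                       dimnames = list(NULL, ids)),
    pool_ids = ids,
    haploid_sizes = stats::setNames(rep(NA_real_, 2 * K), ids)),
    class = "pool_counts")
  strata <- data.frame(alive = paste0("a", seq_len(K)),
                       dead = paste0("d", seq_len(K)))
  r <- cmh_scan(pc, strata)
  if (is.na(r$chi2)) stop("all strata degenerate (zero margin)")
  list(chi2 = r$chi2, p_value = r$p_value, k_used = r$k_used)
}

## ---- report --------------------------------------------------------------

#' Ranked per-window scan report
#'
#' Combines windowed F_ST means with the strongest CMH signal per window
#' and annotates windows with overlapping genes (half-open interval
#' intersection, so a gene touching only the window boundary end is not
#' double counted). Rows are ordered by (chrom, window index); ranking
#' ties break by that same order.
#'
#' @param fst_win output of [window_means()] on per-site F_ST.
#' @param cmh output of [cmh_scan()] (per site).
#' @param windows the [assign_windows()] frame used for `fst_win`.
#' @param genes optional data.frame `gene_id`, `chrom`, `start`, `end`.
#' @return data.frame: window columns, `mean_fst`, `n_sites`,
#'   `neg_log10_p` (max over sites in the window), `genes`
#'   (comma-separated), `rank_fst`, `rank_cmh`.
#' @export
scan_report <- function(fst_win, cmh, windows, genes = NULL) {
  if (nrow(fst_win) == 0) {
    return(data.frame(window_id = character(), chrom = character(),
                      window_index = integer(), win_start = integer(),
                      win_end = integer(), mean_fst = numeric(),
                      n_sites = integer(), neg_log10_p = numeric(),
                      genes = character(), rank_fst = integer(),
                      rank_cmh = integer()))
  }
  stopifnot(nrow(cmh) == nrow(windows))
  nl <- -log10(cmh$p_value)
  best <- vapply(split(nl, windows$window_id), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), 0)
  out <- fst_win
  names(out)[names(out) == "mean_value"] <- "mean_fst"
  out$neg_log10_p <- unname(best[out$window_id])
  out$genes <- ""
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(out))) {
      # half-open intersection of [start, end+1): nonempty iff
      # g.start < w.end+1 and w.start < g.end+1
      hit <- genes$chrom == out$chrom[i] &
        genes$start < out$win_end[i] + 1L & out$win_start[i] < genes$end + 1L
      out$genes[i] <- paste(genes$gene_id[hit], collapse = ",")
    }
  }
  ord <- order(out$chrom, out$window_index)
  out <- out[ord, , drop = FALSE]
  out$rank_fst <- rank(-out$mean_fst, ties.method = "first",
                       na.last = "keep")
  out$rank_cmh <- rank(-out$neg_log10_p, ties.method = "first",
                       na.last = "keep")
  rownames(out) <- NULL
  out
}
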