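# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately use the most literal O(n^2)/O(nL)
# formulations so they stay independent of the package's vectorised code
# paths.

# all-pairs nucleotide diversity over non-N columns
bf_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  m <- m[, colSums(m == "N") == 0, drop = FALSE]
  n <- nrow(m)
  L <- ncol(m)
  if (L == 0) return(0)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (choose(n, 2) * L)
}

# haplotype diversity from the raw multiplicity table
bf_hd <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  m <- m[, colSums(m == "N") == 0, drop = FALSE]
  cnt <- table(apply(m, 1, paste, collapse = ""))
  n <- sum(cnt)
  n / (n - 1) * (1 - sum((cnt / n)^2))
}

# segregating sites by literal column scan
bf_s <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  m <- m[, colSums(m == "N") == 0, drop = FALSE]
  sum(vapply(seq_len(ncol(m)), function(j)
    length(unique(m[, j])) > 1, TRUE))
}

# per-site heterozygosity F_ST from a vector of pool frequencies
bf_fst <- function(p) {
  hs <- mean(2 * p * (1 - p))
  pbar <- mean(p)
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(NA_real_)
  (ht - hs) / ht
}

# minimum spanning tree weight by Prim's algorithm on a distance matrix
bf_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  for (step in seq_len(n - 1)) {
    best <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree))
      if (d[i, j] < best) { best <- d[i, j]; bj <- j }
    total <- total + best
    in_tree[bj] <- TRUE
  }
  total
}

# random haplotype_set: n copies (even) of length L over ACGT with some
# shared structure so spectra are nontrivial
random_hapset <- function(n_ind, L, n_var = max(2, L %/% 10)) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  sites <- sample(L, min(n_var, L))
  copies <- replicate(2 * n_ind, {
    res <- base
    hit <- sites[runif(length(sites)) < 0.4]
    res[hit] <- vapply(res[hit], function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    paste(res, collapse = "")
  })
  names(copies) <- paste0(rep(sprintf("i%02d", 1:n_ind), each = 2), ".", 1:2)
  haplotype_set(copies, individual = rep(sprintf("i%02d", 1:n_ind), each = 2))
}

# tiny pool_counts object from a frequency matrix (sites x pools) at a
# fixed coverage, exact counts
make_pool_counts <- function(p, coverage = 10) {
  p <- as.matrix(p)
  ids <- paste0("p", seq_len(ncol(p)))
  alt <- round(p * coverage)
  structure(list(
    sites = data.frame(chrom = "2L", pos = seq_len(nrow(p)) * 10L,
                       ref_allele = "A", alt_allele = "C"),
    ref_count = matrix(as.integer(coverage - alt), nrow(p),
                       dimnames = list(NULL, ids)),
    alt_count = matrix(as.integer(alt), nrow(p), dimnames = list(NULL, ids)),
    pool_ids = ids,
    haploid_sizes = stats::setNames(rep(80, ncol(p)), ids)),
    class = "pool_counts")
}

# gene model with no UTRs or introns: one coding exon of length L
coding_only_gene <- function(L) {
  gene_model("toy", "+", data.frame(kind = "exon", start = 1, end = L))
}

# a minimal variant_table around given SNP positions (one sample)
snp_table <- function(pos, chrom = "2L") {
  n <- length(pos)
  variant_table(
    data.frame(chrom = rep(chrom, n), pos = as.integer(pos),
               ref = rep("A", n), alt = rep("C", n), kind = rep("SNP", n)),
    matrix(5L, n, 1), matrix(10L, n, 1), "s1")
}

indel_table <- function(pos, chrom = "2L") {
  n <- length(pos)
  variant_table(
    data.frame(chrom = rep(chrom, n), pos = as.integer(pos),
               ref = rep("AT", n), alt = rep("A", n), kind = rep("indel", n)),
    matrix(0L, n, 0), matrix(0L, n, 0), character())
}
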