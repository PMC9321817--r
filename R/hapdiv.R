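# Candidate-gene polymorphism and sweep characterisation: deterministic
# parsimony phasing of ambiguity-coded diploid consensus sequences,
# haplotype/nucleotide diversity over gene regions, amino-acid scans,
# statistical-parsimony haplotype networks and neighbor-joining trees.

## ---- haplotype sets --------------------------------------------------------

#' Construct a haplotype set
#'
#' Two phased, gap-free copies per individual over `{A,C,G,T,N}`; all
#' copies equal length.
#'
#' @param seqs character vector of haplotype copies (2 per individual),
#'   named `<individual>.1` / `<individual>.2`.
#' @param individual individual id per copy.
#' @param population optional population/country label per copy.
#' @param flagged ids of individuals whose phase fell back to the
#'   lexicographic rule.
#' @return object of class `haplotype_set`: list with `seq`,
#'   `individual`, `population`, `flagged`, `L`.
#' @export
haplotype_set <- function(seqs, individual, population = NULL,
                          flagged = character()) {
  stopifnot(length(seqs) == length(individual),
            length(seqs) %% 2 == 0)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("haplotype copies differ in length")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("haplotype sequences must be over {A,C,G,T,N}")
  if (is.null(population)) population <- rep(NA_character_, length(seqs))
  structure(list(seq = seqs, individual = individual,
                 population = population, flagged = flagged, L = L),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d copies (%d individuals), %d bp\n",
              length(x$seq), length(unique(x$individual)), x$L))
  invisible(x)
}

#' Haplotype multiplicity spectrum
#'
#' @param hs a [haplotype_set()] (or character vector of sequences).
#' @param region optional interval data.frame (`start`, `end`) to
#'   restrict to; default full length.
#' @param drop_n_columns exclude columns containing `N` in any copy
#'   before collapsing (complete deletion), the package default for all
#'   diversity statistics.
#' @return named integer vector: distinct haplotype -> copy count,
#'   decreasing.
#' @export
haplotype_spectrum <- function(hs, region = NULL, drop_n_columns = TRUE) {
  seqs <- region_sequences(hs, region, drop_n_columns)
  sort(table(seqs), decreasing = TRUE)
}

# restrict copies to a region (interval set) and optionally drop columns
# holding N in any copy; returns a character vector of (sub)sequences
region_sequences <- function(hs, region = NULL, drop_n_columns = TRUE) {
  seqs <- if (inherits(hs, "haplotype_set")) hs$seq else hs
  L <- nchar(seqs[[1]])
  cols <- region_columns(region, L)
  m <- seq_matrix(seqs)[, cols, drop = FALSE]
  if (drop_n_columns && ncol(m)) {
    keep <- colSums(m == "N") == 0
    m <- m[, keep, drop = FALSE]
  }
  apply(m, 1, paste, collapse = "")
}

region_columns <- function(region, L) {
  if (is.null(region)) return(seq_len(L))
  if (nrow(region) == 0) stop("empty region")
  cols <- unlist(mapply(seq, region$start, region$end, SIMPLIFY = FALSE))
  if (any(cols < 1 | cols > L)) stop("region outside [1, L]")
  sort(unique(cols))
}

seq_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

## ---- phasing ---------------------------------------------------------------

# split a consensus into the two alleles at each position; het sites get
# the two bases of the ambiguity code in alphabetical order
consensus_alleles <- function(res) {
  a1 <- a2 <- res
  het <- res %in% names(AMBIGUITY_MAP)
  for (code in unique(res[het])) {
    pair <- AMBIGUITY_MAP[[code]]
    a1[res == code] <- pair[1]
    a2[res == code] <- pair[2]
  }
  list(a1 = a1, a2 = a2, het = which(het))
}

# collapse two phased copies back to an ambiguity-coded consensus
collapse_to_consensus <- function(c1, c2) {
  r1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  r2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  out <- r1
  het <- which(r1 != r2)
  for (i in het) {
    pair <- sort(c(r1[i], r2[i]))
    if ("N" %in% pair) { out[i] <- "N"; next }
    out[i] <- AMBIGUITY_CODE[[paste0(pair[1], pair[2])]]
  }
  paste(out, collapse = "")
}

#' Phase ambiguity-coded consensus sequences (Clark parsimony)
#'
#' Individuals with at most one heterozygous site phase exactly.
#' Multi-heterozygote individuals are resolved against the pool of
#' already-known haplotypes: known haplotypes are tried in descending
#' count then lexicographic order, and the first one compatible with the
#' consensus (matching everywhere, carrying one of the two alleles at
#' each het site) fixes the phase; its complement joins the pool.
#' Individuals are processed in sorted-id order; passes repeat until no
#' progress; any individual still unresolved falls back to the
#' lexicographically minimal assignment (smaller allele on copy 1 at
#' every het site) and is flagged. Re-collapsing each phased pair with
#' ambiguity codes reproduces the input consensus exactly.
#'
#' @param ss an aligned [sequence_set()] of diploid consensus sequences
#'   (one per individual) with only two-fold ambiguity codes.
#' @param population optional named vector: individual -> population.
#' @return A [haplotype_set()].
#' @export
phase_sequences <- function(ss, population = NULL) {
  stopifnot(inherits(ss, "sequence_set"), ss$aligned)
  ids <- sort(names(ss$seq))
  alle <- lapply(ss$seq[ids], function(s)
    consensus_alleles(strsplit(s, "", fixed = TRUE)[[1]]))
  nhet <- vapply(alle, function(a) length(a$het), 0L)

  known <- character()  # haplotype -> count (named numeric)
  counts <- numeric()
  add_known <- function(h) {
    i <- match(h, known)
    if (is.na(i)) { known <<- c(known, h); counts <<- c(counts, 1) }
    else counts[i] <<- counts[i] + 1
  }
  phased <- vector("list", length(ids))
  names(phased) <- ids

  # pass 0: unambiguous individuals (<= 1 het site)
  for (id in ids[nhet <= 1]) {
    a <- alle[[id]]
    phased[[id]] <- c(paste(a$a1, collapse = ""), paste(a$a2, collapse = ""))
    add_known(phased[[id]][1]); add_known(phased[[id]][2])
  }

  complement_of <- function(a, hap) {
    hr <- strsplit(hap, "", fixed = TRUE)[[1]]
    comp <- hr
    for (i in a$het) comp[i] <- if (hr[i] == a$a1[i]) a$a2[i] else a$a1[i]
    paste(comp, collapse = "")
  }
  compatible <- function(a, hap) {
    hr <- strsplit(hap, "", fixed = TRUE)[[1]]
    hom <- setdiff(seq_along(hr), a$het)
    all(hr[hom] == a$a1[hom]) &&
      all(hr[a$het] == a$a1[a$het] | hr[a$het] == a$a2[a$het])
  }

  todo <- ids[nhet > 1]
  repeat {
    progress <- FALSE
    for (id in todo) {
      if (!is.null(phased[[id]])) next
      a <- alle[[id]]
      ord <- order(-counts, known)
      hit <- NA_character_
      for (k in ord) {
        if (compatible(a, known[k])) { hit <- known[k]; break }
      }
      if (!is.na(hit)) {
        pair <- sort(c(hit, complement_of(a, hit)))
        phased[[id]] <- pair
        add_known(pair[1]); add_known(pair[2])
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  flagged <- character()
  for (id in todo) {
    if (!is.null(phased[[id]])) next
    a <- alle[[id]]
    phased[[id]] <- c(paste(a$a1, collapse = ""), paste(a$a2, collapse = ""))
    add_known(phased[[id]][1]); add_known(phased[[id]][2])
    flagged <- c(flagged, id)
  }
  seqs <- unlist(phased, use.names = FALSE)
  names(seqs) <- paste0(rep(ids, each = 2), ".", 1:2)
  pop <- if (is.null(population)) NULL else rep(unname(population[ids]),
                                                each = 2)
  haplotype_set(seqs, individual = rep(ids, each = 2), population = pop,
                flagged = flagged)
}

## ---- diversity statistics ---------------------------------------------------

#' Segregating sites in a region
#'
#' Number of alignment columns in the region with at least two distinct
#' bases across all copies; columns containing `N` in any copy are
#' excluded first (complete deletion).
#'
#' @param hs a [haplotype_set()].
#' @param region optional interval data.frame (`start`, `end`).
#' @return integer count.
#' @export
segregating_sites <- function(hs, region = NULL) {
  m <- seq_matrix(hs$seq)[, region_columns(region, hs$L), drop = FALSE]
  keep <- colSums(m == "N") == 0
  m <- m[, keep, drop = FALSE]
  sum(apply(m, 2, function(col) length(unique(col))) >= 2)
}

#' Haplotype diversity
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)` over the multiplicity spectrum of
#' region-restricted haplotypes (N columns removed first); 0 when
#' monomorphic, exactly 1 when all copies are distinct.
#'
#' @inheritParams segregating_sites
#' @return numeric in `[0, 1]`.
#' @export
haplotype_diversity <- function(hs, region = NULL) {
  spec <- haplotype_spectrum(hs, region)
  n <- sum(spec)
  if (n < 2) stop("need at least 2 haplotype copies")
  p <- as.numeric(spec) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity per site
#'
#' `pi = sum_{i<j} d_ij / (C(n,2) * L)` with `d_ij` the Hamming distance
#' between copies over the retained (non-`N`) columns of the region and
#' `L` the number of retained columns. Computed column-wise from allele
#' counts, which equals the all-pairs definition.
#'
#' @inheritParams segregating_sites
#' @return numeric `>= 0`.
#' @export
nucleotide_diversity <- function(hs, region = NULL) {
  m <- seq_matrix(hs$seq)[, region_columns(region, hs$L), drop = FALSE]
  keep <- colSums(m == "N") == 0
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 haplotype copies")
  L <- ncol(m)
  if (L == 0) return(0)
  diffs <- sum(apply(m, 2, function(col) {
    tab <- tabulate(factor(col, levels = c("A", "C", "G", "T")))
    (n^2 - sum(tab^2)) / 2
  }))
  diffs / (choose(n, 2) * L)
}

#' Diversity statistics for full / coding / noncoding gene regions
#'
#' @param hs a [haplotype_set()] whose length equals the gene model's
#'   total length.
#' @param gm a [gene_model()].
#' @return data.frame with rows `full`, `coding`, `noncoding`:
#'   `region`, `L`, `n`, `S`, `h`, `Hd`, `pi`.
#' @export
partition_stats <- function(hs, gm) {
  stopifnot(inherits(hs, "haplotype_set"), inherits(gm, "gene_model"))
  if (hs$L != gm$total_length)
    stop("alignment length ", hs$L, " != gene model length ",
         gm$total_length)
  coding <- gm$cds_intervals
  noncoding <- interval_setdiff(
    data.frame(start = 1L, end = gm$total_length), coding)
  regions <- list(full = NULL, coding = coding, noncoding = noncoding)
  lens <- c(full = gm$total_length, coding = gm$coding_length,
            noncoding = gm$noncoding_length)
  rows <- lapply(names(regions), function(r) {
    spec <- haplotype_spectrum(hs, regions[[r]])
    data.frame(region = r, L = unname(lens[r]), n = length(hs$seq),
               S = segregating_sites(hs, regions[[r]]),
               h = length(spec),
               Hd = haplotype_diversity(hs, regions[[r]]),
               pi = nucleotide_diversity(hs, regions[[r]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- amino-acid scan --------------------------------------------------------

#' Scan haplotypes for amino-acid variants
#'
#' Translates each haplotype's coding sequence (standard genetic code,
#' strand-aware) and reports residues differing from the reference
#' translation as `<ref><pos><alt>` (1-based on the translated coding
#' sequence, e.g., `G454A`), with copy counts overall and per population.
#' Premature stops appear as nonsense variants (`*` alt). Codons made
#' ambiguous by `N` translate to `X` and are skipped.
#'
#' @param hs a [haplotype_set()].
#' @param gm a [gene_model()].
#' @param reference full-gene reference sequence.
#' @return data.frame: `change`, `codon`, `ref_aa`, `alt_aa`, `n_copies`,
#'   `frequency`, then one count column per population present.
#' @export
amino_acid_scan <- function(hs, gm, reference) {
  stopifnot(inherits(hs, "haplotype_set"), inherits(gm, "gene_model"),
            nchar(reference) == gm$total_length)
  aa_ref <- strsplit(translate_dna(coding_sequence(toupper(reference), gm)),
                     "", fixed = TRUE)[[1]]
  cds_all <- vapply(hs$seq, coding_sequence, "", gm = gm)
  aa_all <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds_all), if.fuzzy.codon = "X"))
  am <- seq_matrix(aa_all)
  pops <- unique(hs$population[!is.na(hs$population)])
  rows <- list()
  for (codon in seq_along(aa_ref)) {
    col <- am[, codon]
    alt <- setdiff(unique(col), c(aa_ref[codon], "X"))
    for (a in alt) {
      hitrows <- col == a
      row <- data.frame(
        change = paste0(aa_ref[codon], codon, a), codon = codon,
        ref_aa = aa_ref[codon], alt_aa = a,
        n_copies = sum(hitrows),
        frequency = sum(hitrows) / length(col))
      for (p in pops)
        row[[p]] <- sum(hitrows & hs$population == p)
      rows[[length(rows) + 1]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(change = character(), codon = integer(),
                      ref_aa = character(), alt_aa = character(),
                      n_copies = integer(), frequency = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$codon, out$alt_aa), , drop = FALSE]
}

## ---- parsimony network ------------------------------------------------------

#' Approximate statistical-parsimony connection limit
#'
#' Largest number of steps `j` for which the probability that all `j`
#' observed differences between two sequences of length `L` are single
#' substitutions is at least `conf`. Multiple-hit probability per
#' observed difference is taken from the Jukes-Cantor correction:
#' with `p = j/L` and `d = -3/4 log(1 - 4p/3)`, each difference is a
#' single hit with probability `p/d`, so the parsimony probability is
#' `(p/d)^j`. This reproduces the order of magnitude of the classical
#' TCS 95% limits and is user-overridable wherever it is consumed.
#'
#' @param L alignment length (bp).
#' @param conf required parsimony probability (default 0.95).
#' @return integer step limit (>= 1).
#' @export
parsimony_limit <- function(L, conf = 0.95) {
  j <- 1
  repeat {
    p <- (j + 1) / L
    if (p >= 0.75) break
    d <- -0.75 * log(1 - 4 * p / 3)
    if ((p / d)^(j + 1) < conf) break
    j <- j + 1
  }
  as.integer(j)
}

#' Statistical-parsimony haplotype network
#'
#' Minimum-spanning network over distinct haplotypes: candidate edges are
#' processed in ascending Hamming distance; within each distance class
#' every edge joining two distinct components (as of the start of the
#' class) is retained, so ties yield reticulations. Edges longer than
#' `connection_limit` are omitted, which can leave the network
#' disconnected — distant singletons then form their own components.
#'
#' @param hs a [haplotype_set()] (or character vector of sequences).
#' @param connection_limit maximum steps, or `"auto"` for the
#'   [parsimony_limit()] of the alignment length.
#' @return object of class `haplotype_network`: list with `nodes`
#'   (data.frame `hap_id`, `count`, population composition columns,
#'   `sequence`), `edges` (data.frame `from`, `to`, `steps`),
#'   `connection_limit`, `n_components`, `component` (per node).
#' @export
parsimony_network <- function(hs, connection_limit = "auto") {
  seqs <- if (inherits(hs, "haplotype_set")) hs$seq else hs
  L <- nchar(seqs[[1]])
  if (identical(connection_limit, "auto"))
    connection_limit <- parsimony_limit(L)
  m <- seq_matrix(seqs)
  keep <- colSums(m == "N") == 0
  m <- m[, keep, drop = FALSE]
  collapsed <- apply(m, 1, paste, collapse = "")
  uniq <- unique(collapsed)
  h <- length(uniq)
  idx <- match(collapsed, uniq)
  counts <- tabulate(idx, h)
  nodes <- data.frame(hap_id = paste0("H", seq_len(h)), count = counts,
                      sequence = uniq)
  if (inherits(hs, "haplotype_set") && any(!is.na(hs$population))) {
    for (p in unique(hs$population[!is.na(hs$population)]))
      nodes[[p]] <- vapply(seq_len(h), function(i)
        sum(idx == i & hs$population == p), 0L)
  }
  if (h == 1)
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(),
                                             to = character(),
                                             steps = integer()),
                          connection_limit = connection_limit,
                          n_components = 1L, component = 1L),
                     class = "haplotype_network"))
  um <- seq_matrix(uniq)
  d <- matrix(0L, h, h)
  for (i in 1:(h - 1)) for (j in (i + 1):h)
    d[i, j] <- d[j, i] <- sum(um[i, ] != um[j, ])
  comp <- seq_len(h)
  edges <- list()
  for (w in sort(unique(d[upper.tri(d)]))) {
    if (w > connection_limit) break
    cand <- which(upper.tri(d) & d == w, arr.ind = TRUE)
    comp_before <- comp
    for (e in seq_len(nrow(cand))) {
      i <- cand[e, 1]; j <- cand[e, 2]
      if (comp_before[i] != comp_before[j])
        edges[[length(edges) + 1]] <- data.frame(
          from = nodes$hap_id[i], to = nodes$hap_id[j], steps = w)
    }
    for (e in seq_len(nrow(cand))) {
      i <- cand[e, 1]; j <- cand[e, 2]
      if (comp_before[i] != comp_before[j] && comp[i] != comp[j])
        comp[comp == comp[j]] <- comp[i]
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(from = character(), to = character(), steps = integer())
  comp <- match(comp, unique(comp))
  structure(list(nodes = nodes, edges = edges,
                 connection_limit = connection_limit,
                 n_components = length(unique(comp)), component = comp),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype_network: %d haplotype(s), %d edge(s), %d component(s), limit %d\n",
    nrow(x$nodes), nrow(x$edges), x$n_components, x$connection_limit))
  invisible(x)
}

#' Write a haplotype network as an edge-list TSV
#' @param x a [parsimony_network()] result.
#' @param path output path (a `.nodes.tsv` companion is written too).
#' @export
write_network <- function(x, path) {
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$nodes[, setdiff(names(x$nodes), "sequence")],
                     sub("(\\.tsv)?$", ".nodes.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- distance tree ----------------------------------------------------------

#' Neighbor-joining tree on p-distances
#'
#' Builds an unrooted tree from pairwise p-distances (proportion of
#' differing non-`N` columns) with `ape::nj`; negative branch lengths are
#' clamped to zero with a warning. Supply a precomputed distance matrix
#' to control the metric (the three-point example uses raw step counts).
#'
#' @param x a [haplotype_set()], named character vector of sequences, or
#'   a `dist`/symmetric matrix of distances.
#' @return an `ape` `phylo` tree.
#' @export
distance_tree <- function(x) {
  if (inherits(x, "dist") || is.matrix(x)) {
    d <- stats::as.dist(x)
  } else {
    seqs <- if (inherits(x, "haplotype_set")) x$seq else x
    if (length(seqs) < 3) stop("need at least 3 sequences")
    m <- seq_matrix(seqs)
    keep <- colSums(m == "N") == 0
    m <- m[, keep, drop = FALSE]
    n <- nrow(m)
    dm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      dm[i, j] <- dm[j, i] <- mean(m[i, ] != m[j, ])
    d <- stats::as.dist(dm)
  }
  if (attr(d, "Size") < 3) stop("need at least 3 sequences")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a tree in newick format
#' @param tree an `ape` `phylo` object.
#' @param path output path.
#' @export
write_tree_file <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
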