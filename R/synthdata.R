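# Seeded generators producing pooled count tables and individual cohorts
# with the statistical structure the analyses assume: replicated
# alive/dead pools with planted allele-frequency differentials, and
# 10+10+10 targeted-enrichment cohorts over a 2707-bp candidate gene
# under a hard-sweep or diverse regime with a planted resistance variant.

# run code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# documented per-component substream derivation from the single global
# seed: substream k of seed s is (s * 48271 + k) mod (2^31 - 1), kept
# positive and below 2^31
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k) %% 2147483647 + 1)
}

## ---- pooled counts ----------------------------------------------------------

#' Configuration for the pooled-count generator
#'
#' Defaults reproduce the replicated design the scan targets: three alive
#' and two dead pools of 40 individuals each (80 chromosomes), mean
#' coverage 50x.
#'
#' @param n_sites number of variant sites.
#' @param chrom,chrom_length chromosome name and length (bp).
#' @param selected_loci data.frame `pos`, `delta`: allele-frequency
#'   differential added to the alive-group mean at those positions;
#'   `baseline + delta` must stay within `[0, 1]`.
#' @param baseline_range uniform range the per-site baseline alternate
#'   allele frequency is drawn from.
#' @param n_alive,n_dead pools per phenotype group.
#' @param n_individuals diploid individuals per pool (haploid size is
#'   twice this).
#' @param depth_mean mean per-pool coverage (Poisson by default).
#' @param depth_dispersion negative-binomial size parameter; `Inf` (the
#'   default) gives Poisson depths, finite values add overdispersion.
#' @param n_indels indel anchors to scatter for filter testing.
#' @param seed integer seed; all randomness derives from it through
#'   documented substreams.
#' @return list of class `pool_sim_config`.
#' @export
pool_sim_config <- function(n_sites = 2000, chrom = "2L",
                            chrom_length = 2e6,
                            selected_loci = data.frame(pos = integer(),
                                                       delta = numeric()),
                            baseline_range = c(0.05, 0.95),
                            n_alive = 3, n_dead = 2, n_individuals = 40,
                            depth_mean = 50, depth_dispersion = Inf,
                            n_indels = 0, seed = 1) {
  stopifnot(n_sites >= 1, n_alive >= 1, n_dead >= 1,
            all(selected_loci$delta >= 0), all(selected_loci$delta <= 1),
            all(selected_loci$pos >= 1),
            all(selected_loci$pos <= chrom_length))
  structure(list(n_sites = n_sites, chrom = chrom,
                 chrom_length = chrom_length, selected_loci = selected_loci,
                 baseline_range = baseline_range, n_alive = n_alive,
                 n_dead = n_dead, n_individuals = n_individuals,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 n_indels = n_indels, seed = seed),
            class = "pool_sim_config")
}

rdepth <- function(n, mean, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mean)
  else stats::rnbinom(n, size = dispersion, mu = mean)
}

#' Simulate replicated pooled read counts
#'
#' Per pool and site, a realized pool allele frequency is drawn by
#' binomial sampling of the pool's chromosomes around the group mean
#' (alive mean = baseline + delta at selected loci, baseline elsewhere),
#' then read counts by binomial sampling at a simulated depth.
#' Bit-identical output for identical seeds.
#'
#' @param config a [pool_sim_config()].
#' @return list: `sync` ([sync_table()]), `samples` ([sample_sheet()]),
#'   `truth` (data.frame chrom, pos, baseline, delta), `indels`
#'   (positions usable as a [variant_table()] of indel anchors).
#' @export
simulate_pool_counts <- function(config) {
  stopifnot(inherits(config, "pool_sim_config"))
  with_seed(substream_seed(config$seed, 1), {
    nsel <- nrow(config$selected_loci)
    bgpos <- sample(setdiff(seq_len(config$chrom_length),
                            config$selected_loci$pos),
                    config$n_sites - nsel)
    pos <- sort(c(bgpos, config$selected_loci$pos))
    n <- length(pos)
    nuc <- c("A", "T", "C", "G")
    ref <- sample(nuc, n, replace = TRUE)
    alt <- nuc[(match(ref, nuc) - 1L + sample.int(3, n, replace = TRUE)) %% 4L + 1L]
    baseline <- stats::runif(n, config$baseline_range[1],
                             config$baseline_range[2])
    delta <- numeric(n)
    if (nsel) {
      i <- match(config$selected_loci$pos, pos)
      delta[i] <- config$selected_loci$delta
      baseline[i] <- pmin(baseline[i], 1 - delta[i])
    }
    H <- 2 * config$n_individuals
    pool_ids <- c(paste0("alive", seq_len(config$n_alive)),
                  paste0("dead", seq_len(config$n_dead)))
    groups <- rep(c("alive", "dead"), c(config$n_alive, config$n_dead))
    counts <- array(0L, dim = c(n, 6, length(pool_ids)))
    for (j in seq_along(pool_ids)) {
      mu <- if (groups[j] == "alive") pmin(baseline + delta, 1) else baseline
      ptrue <- stats::rbinom(n, H, mu) / H
      dp <- rdepth(n, config$depth_mean, config$depth_dispersion)
      a <- stats::rbinom(n, dp, ptrue)
      r <- dp - a
      for (b in seq_along(nuc)) {
        counts[, b, j] <- counts[, b, j] +
          ifelse(ref == nuc[b], r, 0L) + ifelse(alt == nuc[b], a, 0L)
      }
    }
    sync <- sync_table(data.frame(chrom = config$chrom, pos = pos, ref = ref),
                       counts, pool_ids)
    samples <- sample_sheet(data.frame(
      sample_id = pool_ids, country = "SIM", group = groups, role = "pool",
      pool_haploid_size = H))
    indel_pos <- if (config$n_indels > 0)
      sort(sample(setdiff(seq_len(config$chrom_length), pos),
                  config$n_indels))
    else integer()
    indels <- variant_table(
      data.frame(chrom = rep(config$chrom, length(indel_pos)),
                 pos = indel_pos,
                 ref = rep("AT", length(indel_pos)),
                 alt = rep("A", length(indel_pos)),
                 kind = rep("indel", length(indel_pos))),
      matrix(0L, length(indel_pos), 0), matrix(0L, length(indel_pos), 0),
      character())
    list(sync = sync, samples = samples,
         truth = data.frame(chrom = config$chrom, pos = pos,
                            baseline = baseline, delta = delta),
         indels = indels)
  })
}

## ---- gene fixture -----------------------------------------------------------

#' Deterministic candidate-gene fixture model
#'
#' A plus-strand five-feature gene mirroring the architecture of the
#' CYP9K1 gene body: 5'UTR (1-100), coding exon (101-700), intron
#' (701-1200), coding exon (1201-2214), 3'UTR (2215-2707); 2707 bp in
#' total, 1614 bp coding, 1093 bp noncoding.
#'
#' @return A [gene_model()].
#' @export
make_fixture_gene <- function() {
  gene_model("CYP9K1", "+", data.frame(
    kind = c("five_prime_utr", "exon", "intron", "exon", "three_prime_utr"),
    start = c(1, 101, 701, 1201, 2215),
    end = c(100, 700, 1200, 2214, 2707)))
}

# genomic position of a 1-based coding index (plus-strand models)
genomic_pos_of_coding <- function(gm, ci) {
  stopifnot(gm$strand == "+")
  cds <- gm$cds_intervals
  widths <- cds$end - cds$start + 1
  offs <- cumsum(c(0, widths[-length(widths)]))
  i <- findInterval(ci - 1, offs)
  cds$start[i] + (ci - offs[i] - 1)
}

## ---- cohorts ----------------------------------------------------------------

#' Configuration for the targeted-enrichment cohort generator
#'
#' Defaults reproduce the study design: 10 alive (R), 10 dead (C) and 10
#' laboratory-susceptible (S) individuals over the 2707-bp fixture gene,
#' mean depth 50x, and a planted nonsynonymous resistance variant at
#' codon 454 (GGC -> GCC, i.e., G454A). In the `swept` regime one core
#' haplotype carrying the planted variant dominates the field population
#' at frequency `dominant_haplotype_freq` and the remaining copies are
#' singletons 1-3 mutations away; in the `diverse` regime haplotypes are
#' drawn from independent background-site frequencies so expected
#' haplotype diversity is near 1, and the planted variant is assigned to
#' exactly `round(freq * n)` carrier individuals per group so its
#' realized group frequencies equal the configured R/C/S values.
#'
#' @param regime `"swept"` or `"diverse"`.
#' @param n_alive,n_dead,n_lab individuals per group.
#' @param gm gene model (default [make_fixture_gene()]).
#' @param dominant_haplotype_freq swept-regime core haplotype frequency.
#' @param n_background_sites segregating background sites.
#' @param background_freq_range uniform range of background alternate
#'   allele frequencies.
#' @param planted_codon codon of the planted nonsynonymous variant.
#' @param planted_freqs named numeric `c(R=, C=, S=)`: realized carrier
#'   fractions per group (diverse regime; in the swept regime the variant
#'   is fixed in the field groups and absent from S).
#' @param depth_mean mean sequencing depth per individual and site.
#' @param error_rate per-read miscall probability toward the alternate
#'   allele.
#' @param singleton_steps possible numbers of extra mutations on swept
#'   singleton copies.
#' @param seed integer seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(regime = c("diverse", "swept"),
                              n_alive = 10, n_dead = 10, n_lab = 10,
                              gm = make_fixture_gene(),
                              dominant_haplotype_freq = 0.9,
                              n_background_sites = 40,
                              background_freq_range = c(0.05, 0.5),
                              planted_codon = 454,
                              planted_freqs = c(R = 0.8, C = 0.1, S = 0.0),
                              depth_mean = 50, error_rate = 0.005,
                              singleton_steps = 1:3, seed = 1) {
  regime <- match.arg(regime)
  stopifnot(all(planted_freqs >= 0), all(planted_freqs <= 1),
            dominant_haplotype_freq >= 0, dominant_haplotype_freq <= 1,
            planted_codon >= 1, planted_codon * 3 <= gm$coding_length)
  structure(list(regime = regime, n_alive = n_alive, n_dead = n_dead,
                 n_lab = n_lab, gm = gm,
                 dominant_haplotype_freq = dominant_haplotype_freq,
                 n_background_sites = n_background_sites,
                 background_freq_range = background_freq_range,
                 planted_codon = planted_codon,
                 planted_freqs = planted_freqs, depth_mean = depth_mean,
                 error_rate = error_rate, singleton_steps = singleton_steps,
                 seed = seed),
            class = "cohort_sim_config")
}

# random full-gene reference: no internal stop codons in the CDS and the
# planted codon set to GGC (glycine) so the planted change is G -> A
make_reference <- function(gm, planted_codon) {
  nuc <- c("A", "C", "G", "T")
  res <- sample(nuc, gm$total_length, replace = TRUE)
  ref <- paste(res, collapse = "")
  cds <- coding_sequence(ref, gm)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  ncod <- length(codons)
  stop_cod <- codons %in% c("TAA", "TAG", "TGA") & seq_len(ncod) < ncod
  codons[stop_cod] <- sub(".$", "C", codons[stop_cod])
  codons[planted_codon] <- "GGC"
  cds_fixed <- paste(codons, collapse = "")
  # write the fixed CDS back into the genomic sequence (plus strand)
  ci <- 1
  for (i in seq_len(nrow(gm$cds_intervals))) {
    s <- gm$cds_intervals$start[i]; e <- gm$cds_intervals$end[i]
    w <- e - s + 1
    substr(ref, s, e) <- substr(cds_fixed, ci, ci + w - 1)
    ci <- ci + w
  }
  ref
}

#' Simulate a targeted-enrichment cohort over the candidate gene
#'
#' Produces the three linked artifacts every downstream stage consumes:
#' an ambiguity-coded consensus alignment (one record per individual), a
#' per-individual variant table with simulated depths, and a sample
#' sheet; plus a truth list sufficient to score recovery.
#'
#' @param config a [cohort_sim_config()].
#' @return list: `consensus` ([sequence_set()]), `variants`
#'   ([variant_table()]), `samples` ([sample_sheet()]), `reference`
#'   (full-gene string), `gm`, `truth` (list with `planted` data.frame,
#'   `haplotypes`, `copy_group`, `carriers`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  gm <- config$gm
  with_seed(substream_seed(config$seed, 2), {
    reference <- make_reference(gm, config$planted_codon)
    planted_ci <- config$planted_codon * 3 - 1  # middle base of the codon
    planted_pos <- genomic_pos_of_coding(gm, planted_ci)
    planted_ref <- substr(reference, planted_pos, planted_pos)  # "G"
    planted_alt <- "C"                                          # GGC -> GCC

    ids <- c(sprintf("R%02d", seq_len(config$n_alive)),
             sprintf("C%02d", seq_len(config$n_dead)),
             sprintf("S%02d", seq_len(config$n_lab)))
    grp <- rep(c("alive", "dead", "lab_susceptible"),
               c(config$n_alive, config$n_dead, config$n_lab))
    code <- rep(c("R", "C", "S"), c(config$n_alive, config$n_dead,
                                    config$n_lab))
    n_ind <- length(ids)
    nuc <- c("A", "C", "G", "T")
    ref_res <- strsplit(reference, "", fixed = TRUE)[[1]]

    # background diversity sites shared by all groups
    bg_pos <- sort(sample(setdiff(seq_len(gm$total_length), planted_pos),
                          config$n_background_sites))
    bg_freq <- stats::runif(config$n_background_sites,
                            config$background_freq_range[1],
                            config$background_freq_range[2])
    bg_alt <- nuc[(match(ref_res[bg_pos], nuc) - 1L +
                     sample.int(3, length(bg_pos), replace = TRUE)) %% 4L + 1L]

    draw_background_copy <- function() {
      res <- ref_res
      hit <- stats::runif(length(bg_pos)) < bg_freq
      res[bg_pos[hit]] <- bg_alt[hit]
      res
    }

    field <- code != "S"
    copies <- vector("list", 2 * n_ind)  # residue vectors
    if (config$regime == "swept") {
      core <- ref_res
      core[planted_pos] <- planted_alt
      mut_pool <- setdiff(seq_len(gm$total_length), planted_pos)
      for (k in seq_len(2 * n_ind)) {
        ind <- (k + 1) %/% 2
        if (field[ind]) {
          res <- core
          if (stats::runif(1) >= config$dominant_haplotype_freq) {
            nm <- sample(config$singleton_steps, 1)
            at <- sample(mut_pool, nm)
            res[at] <- vapply(res[at],
                              function(r) sample(setdiff(nuc, r), 1), "")
          }
          copies[[k]] <- res
        } else {
          copies[[k]] <- draw_background_copy()
        }
      }
      carriers <- stats::setNames(list(ids[code == "R"], ids[code == "C"],
                                       character()), c("R", "C", "S"))
    } else {
      for (k in seq_len(2 * n_ind)) copies[[k]] <- draw_background_copy()
      carriers <- list()
      for (g in c("R", "C", "S")) {
        gids <- ids[code == g]
        nc <- round(config$planted_freqs[[g]] * length(gids))
        carriers[[g]] <- sample(gids, nc)
      }
      # zygosity among carriers follows Hardy-Weinberg conditional on
      # carrying: with carrier fraction c the allele frequency is
      # q = 1 - sqrt(1 - c) and a carrier is homozygous with q^2 / c
      for (g in c("R", "C", "S")) {
        cfrac <- config$planted_freqs[[g]]
        if (cfrac <= 0) next
        q <- 1 - sqrt(1 - min(cfrac, 1))
        p_hom <- if (cfrac < 1) q^2 / cfrac else 1
        for (id in carriers[[g]]) {
          k <- 2 * match(id, ids) - 1
          copies[[k]][planted_pos] <- planted_alt
          if (stats::runif(1) < p_hom)
            copies[[k + 1]][planted_pos] <- planted_alt
        }
      }
    }

    hap_seqs <- vapply(copies, paste, "", collapse = "")
    consensus <- vapply(seq_len(n_ind), function(i)
      collapse_to_consensus(hap_seqs[2 * i - 1], hap_seqs[2 * i]), "")
    names(consensus) <- ids
    ss <- sequence_set(consensus, aligned = TRUE)

    # variant table over all positions segregating against the reference
    hap_mat <- seq_matrix(hap_seqs)
    diff_mat <- hap_mat != matrix(ref_res, nrow(hap_mat),
                                  gm$total_length, byrow = TRUE)
    seg <- which(colSums(diff_mat) > 0)
    var_alt <- vapply(seg, function(j) {
      d <- hap_mat[hap_mat[, j] != ref_res[j], j]
      names(sort(table(d), decreasing = TRUE))[1]
    }, "")
    nv <- length(seg)
    supp <- dep <- matrix(0L, nv, n_ind, dimnames = list(NULL, ids))
    for (i in seq_len(n_ind)) {
      two <- hap_mat[c(2 * i - 1, 2 * i), seg, drop = FALSE]
      f <- colSums(two == matrix(var_alt, 2, nv, byrow = TRUE)) / 2
      d <- rdepth(nv, config$depth_mean, Inf)
      pr <- f * (1 - config$error_rate) + (1 - f) * config$error_rate
      supp[, i] <- stats::rbinom(nv, d, pr)
      dep[, i] <- d
    }
    vt <- variant_table(
      data.frame(chrom = gm$gene_id, pos = seg, ref = ref_res[seg],
                 alt = var_alt, kind = "SNP"),
      supp, dep, ids)
    samples <- sample_sheet(data.frame(
      sample_id = ids, country = "SIM", group = grp, role = "individual",
      pool_haploid_size = NA_real_))
    planted_change <- paste0(
      translate_dna(paste0("G", planted_ref, "C")), config$planted_codon,
      translate_dna(paste0("G", planted_alt, "C")))
    list(consensus = ss, variants = vt, samples = samples,
         reference = reference, gm = gm,
         truth = list(
           planted = data.frame(pos = planted_pos, ref = planted_ref,
                                alt = planted_alt,
                                codon = config$planted_codon,
                                change = planted_change),
           haplotypes = hap_seqs,
           copy_group = rep(code, each = 2),
           copy_individual = rep(ids, each = 2),
           carriers = carriers))
  })
}
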