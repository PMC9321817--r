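# Targeted association: presence calls, group frequencies, the
# frequency-differential filter, the t-test arm and effect classification.

make_sheet <- function(n = 10) {
  sample_sheet(data.frame(
    sample_id = c(sprintf("R%02d", 1:n), sprintf("C%02d", 1:n),
                  sprintf("S%02d", 1:n)),
    country = "SIM",
    group = rep(c("alive", "dead", "lab_susceptible"), each = n),
    role = "individual", pool_haploid_size = NA_real_))
}

# variant_table with given supporting/depth per sample vector
vt_from <- function(supp, dep, samples) {
  variant_table(
    data.frame(chrom = "g", pos = seq_len(nrow(supp)) * 5L,
               ref = rep("A", nrow(supp)), alt = rep("C", nrow(supp)),
               kind = rep("SNP", nrow(supp))),
    supp, dep, samples)
}

test_that("presence calls follow the read-support, fraction and depth rules", {
  supp <- matrix(c(0L, 10L, 1L), 1)
  dep <- matrix(c(0L, 20L, 100L), 1)
  vt <- vt_from(supp, dep, c("s1", "s2", "s3"))
  pm <- build_presence_matrix(vt)
  expect_identical(unname(pm$calls[1, ]),
                   c("missing",   # depth 0
                     "present",   # 10/20
                     "absent"))   # fraction 0.01 < 0.05 despite support
  # depth below the call threshold is missing even with support
  pm2 <- build_presence_matrix(vt_from(matrix(2L), matrix(4L), "s1"))
  expect_identical(unname(pm2$calls[1, 1]), "missing")
})

test_that("group frequencies count present over called individuals", {
  sheet <- make_sheet()
  ids <- sheet$sample_id
  # variant 1: 4 present / 10 called in R; variant 2: 3 present, 4 missing
  supp <- matrix(0L, 2, 30, dimnames = list(NULL, ids))
  dep <- matrix(20L, 2, 30, dimnames = list(NULL, ids))
  supp[1, sprintf("R%02d", 1:4)] <- 10L
  supp[2, sprintf("R%02d", 1:3)] <- 10L
  dep[2, sprintf("R%02d", 7:10)] <- 0L
  pm <- build_presence_matrix(vt_from(supp, dep, ids))
  fr <- group_frequencies(pm, sheet)
  r <- fr[fr$group == "R", ]
  expect_equal(r$freq[r$variant == 1], 0.40)
  expect_equal(r$freq[r$variant == 2], 0.50)
  expect_identical(r$n_called[r$variant == 2], 6)
  # zero called individuals -> undefined
  dep[1, sprintf("C%02d", 1:10)] <- 0L
  pm2 <- build_presence_matrix(vt_from(supp, dep, ids))
  fr2 <- group_frequencies(pm2, sheet)
  expect_true(is.na(fr2$freq[fr2$group == "C" & fr2$variant == 1]))
})

# helper: frequencies frame for a single variant with given R/C/S freqs
freqs_of <- function(r, c, s, n_called = 10) {
  data.frame(variant = 1L, chrom = "g", pos = 5L, alt = "C",
             group = c("R", "C", "S"), n_called = n_called,
             n_present = round(c(r, c, s) * n_called),
             freq = c(r, c, s))
}

test_that("frequency filter applies the documented bounds per comparison", {
  # R 0.40 / C 0.30 significant in R-C
  hit <- frequency_filter(freqs_of(0.40, 0.30, 0), "R-C")
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$direction, "R-high")
  # R below the 35% lower bound never qualifies
  expect_identical(nrow(frequency_filter(freqs_of(0.30, 0.05, 0), "R-C")), 0L)
  # no differential: both fixed
  expect_identical(nrow(frequency_filter(freqs_of(1, 1, 0), "R-C")), 0L)
  # dead-group floor: C = 0 fails the printed [0.01, 0.35) interval ...
  expect_identical(nrow(frequency_filter(freqs_of(0.8, 0, 0), "R-C")), 0L)
  # ... unless the floor is relaxed
  expect_identical(nrow(frequency_filter(freqs_of(0.8, 0, 0), "R-C",
                                         low_bounds = c(0, 0.35))), 1L)
  # reversed polarity is picked up by direction = auto
  rev <- frequency_filter(freqs_of(0.10, 0.80, 0), "R-C")
  expect_identical(rev$direction, "C-high")
  expect_identical(nrow(frequency_filter(freqs_of(0.10, 0.80, 0), "R-C",
                                         direction = "R-high")), 0L)
  # S comparisons: field strictly > 0.35, colony < 0.35
  expect_identical(nrow(frequency_filter(freqs_of(0.36, 0, 0.34), "R-S")), 1L)
  expect_identical(nrow(frequency_filter(freqs_of(0.35, 0, 0.0), "R-S")), 0L)
  expect_identical(nrow(frequency_filter(freqs_of(0, 0.5, 0.1), "C-S")), 1L)
  # the call-rate requirement: five of ten per group
  expect_identical(nrow(frequency_filter(freqs_of(0.4, 0.3, 0,
                                                  n_called = 4), "R-C")), 0L)
})

test_that("frequency filter is monotone in its bounds", {
  set.seed(21)
  base <- do.call(rbind, lapply(1:40, function(v) {
    f <- freqs_of(runif(1), runif(1), runif(1))
    f$variant <- v; f$pos <- v * 5L; f
  }))
  n_at <- function(lo) nrow(frequency_filter(base, "R-C",
                                             high_bounds = c(lo, 1)))
  # raising the high-group lower bound never enlarges the set
  bounds <- seq(0.2, 0.8, by = 0.1)
  expect_true(all(diff(vapply(bounds, n_at, 0)) <= 0))
  # widening the low-group interval never shrinks it
  n_low <- function(up) nrow(frequency_filter(base, "R-C",
                                              low_bounds = c(0.01, up)))
  ups <- seq(0.1, 0.6, by = 0.1)
  expect_true(all(diff(vapply(ups, n_low, 0)) >= 0))
})

test_that("intersection is contained in every per-comparison set", {
  set.seed(22)
  mk <- function(n, off) data.frame(
    variant = seq_len(n), chrom = "g", pos = (seq_len(n) + off) * 3L,
    alt = "C", comparison = "x", direction = "R-high",
    freq_high = 0.5, freq_low = 0.1)
  a <- mk(10, 0); b <- mk(10, 4); c3 <- mk(10, 8)
  common <- intersect_comparisons(list(a, b, c3))
  for (s in list(a, b, c3))
    expect_true(all(common$variants$pos %in% s$pos))
  # disjoint sets -> empty
  expect_identical(nrow(intersect_comparisons(list(mk(3, 0),
                                                   mk(3, 100)))$variants), 0L)
  # gene annotation of a common variant
  one <- mk(1, 0)
  res <- intersect_comparisons(list(one, one, one),
                               genes = data.frame(gene_id = "gX", chrom = "g",
                                                  start = 1, end = 10))
  expect_identical(res$genes, "gX")
})

test_that("t-test equals the textbook pooled formula and stats::t.test", {
  sheet <- make_sheet(5)
  ids <- sheet$sample_id
  r <- c(0.9, 0.8, 1.0, 0.85, 0.95); cc <- c(0.1, 0.0, 0.2, 0.05, 0.15)
  dep <- matrix(100L, 1, 15, dimnames = list(NULL, ids))
  supp <- matrix(0L, 1, 15, dimnames = list(NULL, ids))
  supp[1, 1:5] <- as.integer(r * 100); supp[1, 6:10] <- as.integer(cc * 100)
  pm <- build_presence_matrix(vt_from(supp, dep, ids))
  out <- ttest_association(pm, sheet, "R-C")
  # closed form
  sp2 <- (4 * var(r) + 4 * var(cc)) / 8
  t_hand <- (mean(r) - mean(cc)) / sqrt(sp2 * (2 / 5))
  expect_equal(out$t, t_hand, tolerance = 1e-9)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-9)
  # reference implementation agrees
  ref <- t.test(r, cc, var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(out$p, ref$p.value, tolerance = 1e-9)
  # symmetry under group swap
  out2 <- ttest_association(pm, sheet, "R-C")
  expect_equal(out2$p, out$p)

  # identical fractions in both groups -> t = 0, p = 1
  supp0 <- matrix(50L, 1, 15, dimnames = list(NULL, ids))
  pm0 <- build_presence_matrix(vt_from(supp0, dep, ids))
  out0 <- ttest_association(pm0, sheet, "R-C")
  expect_identical(out0$t, 0)
  expect_identical(out0$p, 1)

  # fewer than two individuals with data in a group -> skipped with reason
  dep_na <- dep; dep_na[1, 1:4] <- 0L
  supp_na <- supp; supp_na[dep_na == 0] <- 0L
  pmna <- build_presence_matrix(vt_from(supp_na, dep_na, ids))
  outna <- ttest_association(pmna, sheet, "R-C", min_samples_with_data = 3)
  expect_identical(nrow(outna), 0L)
  skipped <- attr(outna, "skipped")
  expect_identical(nrow(skipped), 1L)
  expect_match(skipped$reason, "group")
})

test_that("t-test matches the oracle on random inputs and Bonferroni scales", {
  set.seed(23)
  sheet <- make_sheet()
  ids <- sheet$sample_id
  n <- 30
  dep <- matrix(50L, n, 30, dimnames = list(NULL, ids))
  supp <- matrix(rbinom(n * 30, 50, runif(n * 30, 0.05, 0.9)), n,
                 dimnames = list(NULL, ids))
  pm <- build_presence_matrix(vt_from(supp, dep, ids))
  out <- ttest_association(pm, sheet, "R-S")
  expect_identical(attr(out, "m_tests"), as.integer(n))
  f <- pm$fraction
  for (i in sample(n, 8)) {
    ref <- t.test(f[i, 1:10], f[i, 21:30], var.equal = TRUE)
    j <- which(out$variant == i)
    expect_equal(out$t[j], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(out$p[j], ref$p.value, tolerance = 1e-9)
    expect_equal(out$p_bonferroni[j], min(1, ref$p.value * n))
  }
  expect_identical(attr(out, "threshold"), 5e-22)
  expect_identical(attr(ttest_association(pm, sheet, "R-C"), "threshold"),
                   5e-5)
})

test_that("effect classification: degeneracy, G454A, splice windows, UTRs", {
  gm <- make_fixture_gene()
  set.seed(24)
  ref <- poolsweep:::make_reference(gm, 454)
  # third-position change inside a glycine codon is synonymous
  p454 <- poolsweep:::genomic_pos_of_coding(gm, 454 * 3)  # third base, GGC
  eff_syn <- classify_effect(data.frame(pos = p454, ref = "C", alt = "G"),
                             gm, ref)
  expect_identical(eff_syn$category, "Syn")  # GGC -> GGG, both glycine
  # middle-base change gives the canonical G454A label
  p_mid <- poolsweep:::genomic_pos_of_coding(gm, 454 * 3 - 1)
  eff <- classify_effect(data.frame(pos = p_mid, ref = "G", alt = "C"),
                         gm, ref)
  expect_identical(eff$category, "Nsyn")
  expect_identical(eff$amino_acid_change, "G454A")
  # splice window: intron spans 701..1200
  eff2 <- classify_effect(
    data.frame(pos = c(701, 703, 1200, 1198), ref = "A", alt = "C"), gm, ref)
  expect_identical(eff2$category, c("SpS", "Int", "SpS", "Int"))
  # UTRs and outside the model
  eff3 <- classify_effect(
    data.frame(pos = c(50, 2500, 2800), ref = "A", alt = "C"), gm, ref)
  expect_identical(eff3$category, c("5'UTR", "3'UTR", "intergenic"))
})

test_that("on a coding-only model every SNP is Syn or Nsyn; strand flip preserves counts", {
  set.seed(25)
  L <- 300
  gm_plus <- coding_only_gene(L)
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  pos <- sample(L, 40)
  alt <- vapply(pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), substr(ref, p, p)), 1), "")
  vars <- data.frame(pos = pos, ref = substring(ref, pos, pos), alt = alt)
  eff_p <- classify_effect(vars, gm_plus, ref)
  expect_true(all(eff_p$category %in% c("Syn", "Nsyn")))

  # flip the whole fixture to the minus strand: reverse-complement the
  # reference and variant alleles, mirror the positions
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  gm_minus <- gene_model("toy", "-",
                         data.frame(kind = "exon", start = 1, end = L))
  ref_rc <- rc(ref)
  vars_rc <- data.frame(pos = L - pos + 1,
                        ref = vapply(vars$ref, rc, ""),
                        alt = vapply(vars$alt, rc, ""))
  eff_m <- classify_effect(vars_rc, gm_minus, ref_rc)
  expect_identical(table(eff_p$category), table(eff_m$category))
  expect_identical(sort(eff_m$amino_acid_change),
                   sort(eff_p$amino_acid_change))
})

test_that("category summaries count planted categories exactly", {
  expect_identical(sum(summarize_by_category(
    data.frame(category = character()))), 0L)
  one_each <- data.frame(category = c("Nsyn", "SpS", "Syn", "Int",
                                      "5'UTR", "3'UTR"))
  s <- summarize_by_category(one_each)
  expect_true(all(s[, c("Nsyn", "SpS", "Syn", "Int", "5'UTR", "3'UTR")] == 1))
  expect_identical(s$intergenic, 0L)

  # planted variants of each category on the fixture gene
  gm <- make_fixture_gene()
  set.seed(26)
  ref <- poolsweep:::make_reference(gm, 454)
  vars <- data.frame(pos = c(50, 701, 950, 2500,
                             poolsweep:::genomic_pos_of_coding(gm, 1361)),
                     ref = "G", alt = "C")
  eff <- classify_effect(vars, gm, ref)
  counts <- summarize_by_category(eff)
  expect_identical(counts$`5'UTR`, 1L)
  expect_identical(counts$SpS, 1L)
  expect_identical(counts$Int, 1L)
  expect_identical(counts$`3'UTR`, 1L)
  expect_identical(counts$Nsyn + counts$Syn, 1L)
})
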