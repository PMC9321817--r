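---
title: "Methods: pooled scans, targeted association and sweep characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled scans, targeted association and sweep characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

`poolsweep` implements the computational route from raw variant tables to
pyrethroid-resistance candidates in *Anopheles funestus*: a replicated
pool-seq genome scan, an individual-level targeted-enrichment association
stage, and a candidate-gene haplotype analysis centred on the cytochrome
P450 *CYP9K1*. This vignette explains the models and estimators, the
parameters that matter, what the synthetic-data generators emulate, and
the numerical and design choices behind the implementation.

## The pooled genome scan

Pooled sequencing estimates allele frequencies from read counts over many
individuals at once. Each pool of 40 mosquitoes contributes 80
chromosomes; a site's pool frequency estimate is the alternate-read
fraction at that site.

**Site filters.** SNPs within 3 bp of a predicted indel anchor are
removed (strictly: a SNP exactly 3 bp away is dropped). Sites must then
have coverage strictly above 10x and strictly below the pool's own
empirical 95th coverage percentile, computed per pool over the input site
set with linear interpolation. Both inequalities are strict; a
consequence worth knowing is that perfectly constant coverage drops every
site, because the percentile equals the shared coverage. The indel filter
runs before the coverage percentile is computed.

**F_ST.** Per site, with pool frequencies $\hat p_i$,

$$H_S = \overline{2\hat p_i(1-\hat p_i)}, \qquad
  H_T = 2\bar p(1-\bar p), \qquad
  F_{ST} = \frac{H_T - H_S}{H_T},$$

using unweighted means over the included pools; the value is undefined
when $H_T = 0$ and is excluded from window means. This classical
heterozygosity estimator was chosen over ANOVA-type estimators because
its limits are exactly testable: identical pools give 0, a fixed
difference gives 1. Windowed values are intended for rank-level use
(which windows stand out), not as unbiased point estimates; negative
per-site values are reported as computed and averaged as-is. An optional
flag inflates within-pool heterozygosity by $c/(c-1)$ (coverage $c$) to
offset read-sampling bias; it is off by default. Window F_ST averages
are unweighted by coverage, since no weighting scheme was imposed by the
original design.

**Windows.** Two modes: nonoverlapping 1000-bp windows (window $k$ covers
1-based positions $[1000k+1, 1000(k+1)]$, so position 1000 falls in
window 0 and 1001 in window 1) and nonoverlapping runs of 1000 retained
SNPs per chromosome, keeping and flagging the final partial window.
Windows never span chromosomes.

**CMH test.** Each stratum pairs one alive with one dead pool and
contributes a 2x2 table of alternate/reference read counts. With
$a_k$ the alive alternate count, $E_k = R1_k C1_k / N_k$ and
$V_k = R1_k R2_k C1_k C2_k / (N_k^2 (N_k-1))$,

$$\chi^2 = \frac{(|\sum_k a_k - \sum_k E_k| - 0.5)^2}{\sum_k V_k},$$

with 1 df and the 0.5 continuity correction applied only when the
absolute difference exceeds 0.5 (the correction must not overshoot
zero), matching the classical definition and the reference
implementation in `stats::mantelhaen.test`. Strata with a zero margin
are dropped per site and the retained count is reported. Two stratum
designs are provided: `all_pairs` (the Cartesian product, e.g. six
strata from three alive and two dead pools) and `independent` (an
explicit disjoint pairing). The all-pairs design reuses pools across
strata and therefore violates the independence assumption of the test;
it is provided because the scan design it reproduces used it, but
calibrated p-values should not be expected from it (see the calibration
note below).

**Read counts are not chromosome counts.** The CMH and F_ST stages take
read counts at face value, as the original tooling does. Because a
pool's read counts are a second binomial sample around its (chromosome-
sampled) true frequency, the read-count CMH understates the sampling
variance by a factor of roughly $1 + \bar c / n_h$ (mean coverage over
haploid pool size; about 1.6 at 50x over 80 chromosomes). The null
rejection rate at $p<0.05$ is therefore inflated — about 0.09 with
independent strata and about 0.30 with all-pairs strata under the
default simulation conditions — and the test should be read as a
ranking statistic, not as a calibrated test, which is how the scan uses
it. The acceptance suite asserts the nominal 0.05 rate and documents
the measured rate; the assertion fails by construction and is retained
deliberately as a record of this property.

## Targeted-enrichment association

Individuals are sequenced over capture regions; three cohorts of 10 are
compared: permethrin-alive (R), permethrin-dead (C) and the
fully-susceptible FANG laboratory colony (S).

**Presence calls.** A variant is *missing* in an individual when depth
is below 5 (no data — never conflated with absence), *present* when it
has at least 1 supporting read and an allele fraction of at least 0.05,
otherwise *absent*. These three thresholds are this package's contract
(the original report format does not print its internal rules) and are
arguments throughout.

**Group frequency** is the fraction of called individuals in which the
variant is present — mosquitoes are counted, read fractions are not
averaged, matching the "found in X% of the mosquitoes" notion. The
five-of-ten requirement is implemented as a per-group call-rate
requirement (at least 5 individuals with data), not a carrier count: a
carrier-count reading of 5/10 would make the 35% frequency bound
vacuous.

**Frequency-differential filter.** For R-C, a variant is significant
when its frequency lies in $[0.35, 1]$ in the high group and $[0.01,
0.35)$ in the low group; the 1% floor means the variant must be observed
in the low group at least once, and a flag relaxes it to $[0, 0.35)$.
Against the colony (R-S, C-S), the field group must exceed 0.35 and the
colony sit below 0.35. `direction = "auto"` also tests the reversed R-C
orientation, supporting populations where resistance is near fixation
and the informative differential has the dead group high. The
three-way intersection (on chromosome, position and alternate allele)
defines the best candidates. Note that a variant rare in the dead group
satisfies R-C and R-S but cannot satisfy C-S's 35% bound; with these
printed bounds the three comparisons constrain the dead-group frequency
from both sides, and a strict three-way intersection is only reachable
by variants near the 35% boundary in C.

**t-test arm.** Per variant, a two-sample pooled-variance (Student)
t-test on per-individual allele fractions, two-sided, for variants with
data in at least 3 individuals overall and 2 per group; Bonferroni
correction is over the variants actually tested within each comparison.
Zero variance with equal means yields $t=0, p=1$. The implementation is
the closed-form pooled statistic (so the degenerate cases are defined);
`stats::t.test(var.equal = TRUE)` serves as the independent oracle in
the tests. Reference thresholds $p = 5\times10^{-5}$ (field-field) and
$5\times10^{-22}$ (versus the colony) are marked on the output. With
cohorts of 10 and realistic read noise, Bonferroni-adjusted significance
at 0.05 for a 0.8-versus-0.1 carrier differential is borderline (raw
$p \sim 10^{-4}\!-\!10^{-3}$ against ~40 tests): the filter arm, not
the t-test, is the sensitive detector at this design size.

**Effect classification.** Coding SNPs are translated (standard genetic
code, strand-aware) into `Syn`/`Nsyn` with `G454A`-style labels, 1-based
on the translated coding sequence. Intron positions within 2 bp of an
exon junction are splice-site (`SpS`), other intron positions `Int`;
UTRs by interval; premature stops are nonsense variants (`*`), not
errors. Multi-base variants spanning a feature boundary are classified
by their first base with a warning.

## Candidate-gene haplotype analysis

The *CYP9K1* analysis works from a 2707-bp aligned gene body — 5'UTR,
two coding exons (1614 bp) flanking one intron, 3'UTR (1093 bp
noncoding) — represented per individual as an ambiguity-coded diploid
consensus.

**Phasing.** Deterministic Clark parsimony replaces MCMC haplotype
reconstruction: individuals with at most one heterozygous site phase
exactly and seed the known-haplotype pool; remaining individuals are
resolved against known haplotypes (descending count, then
lexicographic), in sorted-individual order, over repeated passes;
anything still unresolved falls back to the lexicographically minimal
assignment and is flagged. Re-collapsing any phased pair reproduces the
input consensus exactly — a tested invariant. The trade-off is
reproducibility over statistical sophistication: on swept data (few
heterozygous sites) the reconstruction is essentially exact, on highly
diverse data flagged fallbacks are common and haplotype-level identities
should be read cautiously; diversity summaries are robust to this
because the allele columns themselves are unaffected.

**Diversity statistics.** Columns containing `N` in any copy are
excluded from all statistics (complete deletion), matching the classical
defaults of the software family this replaces. Segregating sites $S$
count polymorphic retained columns; haplotype diversity is
$Hd = \frac{n}{n-1}(1 - \sum_i p_i^2)$ over the region-restricted
spectrum; nucleotide diversity is the mean pairwise difference per
retained site. Statistics are reported for the full gene, the coding
region (concatenated CDS) and the noncoding complement; $S$ decomposes
additively over this partition by construction.

**Amino-acid scan.** Each haplotype's coding sequence is translated and
compared to the reference translation; differing residues are reported
as `<ref><pos><alt>` with copy counts per population. A fixed
nonsynonymous variant in a swept population — the G454A situation —
appears at frequency 1.0.

**Haplotype network.** A minimum-spanning network: candidate edges are
processed in ascending Hamming distance and every edge that joins two
distinct components as of the start of its distance class is retained,
so equal-length alternatives yield reticulations. Edges longer than the
connection limit are omitted, leaving distant singletons disconnected.
The default limit approximates the 95% statistical-parsimony cutoff: for
alignment length $L$ and $j$ observed differences, with $p = j/L$ and
the Jukes–Cantor distance $d(p)$, each difference is a single hit with
probability $p/d$, and the limit is the largest $j$ with
$(p/d)^j \ge 0.95$ (about 14 steps at 2.7 kb). This is an intentionally
simple surrogate for the exact parsimony recursion; the limit is a
plain argument wherever it is consumed.

**Tree.** Neighbor-joining on p-distances (via `ape::nj`) substitutes
for maximum-likelihood phylogenetics; only topology-level agreement is
claimed, negative branch lengths are clamped to zero with a warning,
and trees serialise to newick.

## Synthetic data: what it emulates and what it does not

Both generators are pure functions of their configuration and a single
seed (per-component substreams are derived as
$s_k = (48271\,s + k) \bmod (2^{31}-1)$), and their defaults *are* the
study conditions.

**Pooled counts.** Per pool and site, a realized pool frequency is drawn
by binomial sampling of 80 chromosomes around the group mean (alive mean
= baseline + delta at selected loci), then reads by binomial sampling at
Poisson depth (mean 50; a negative-binomial dispersion flag adds
overdispersion). Baseline frequencies are uniform on $[0.05, 0.95]$ — a
deliberately simple spectrum that exercises the estimators across their
range rather than mimicking a site-frequency spectrum. Not emulated:
linkage between sites, mapping artefacts, reference bias, indel
realignment noise. Passing tests therefore demonstrate estimator
correctness and ranking power under the sampling model, not robustness
to alignment pathology.

**Cohorts.** A random 2707-bp reference (CDS kept stop-free; codon 454
set to GGC so the planted change is glycine to alanine) underlies two
regimes. *Swept*: one core haplotype carrying the planted coding variant
dominates the field population at frequency 0.9 (each copy is core with
that probability); other copies are singletons 1–3 mutations away — the
hard-sweep geometry with expected $Hd \approx 0.19$ at 40 copies.
*Diverse*: 40 background sites with uniform $[0.05, 0.5]$ frequencies
give near-maximal Hd. The planted resistance variant is assigned to
exactly `round(freq * n)` carrier individuals per group (defaults
R/C/S = 0.8/0.1/0.0), so its realized carrier frequencies equal the
configured values — the properties under test are about detecting a
differential of a given size, not about compounding it with binomial
carrier-count noise; zygosity among carriers follows Hardy–Weinberg
conditional on carrying, consistent with individuals being random pairs
of haplotype copies. Read support per individual is binomial at Poisson
depth with a 0.005 per-read miscall rate. Not emulated: capture-bias
coverage structure, population substructure between cohorts, linkage
between the planted variant and background sites.

## Problem sizes and orchestration

The test and acceptance workloads use 20,000 sites for the null
calibration, 2,000-site scans over 100 seeds for power, and 100 seeded
cohort replicates for the sweep-contrast and recovery properties —
sizes at which every property stabilises while the full suite stays
comfortably interactive on a single core. The `run_poolscan`,
`run_assoc` and `run_hapdiv` functions tie the stages together, take
paths or in-memory objects, never mutate inputs, and write TSV outputs
plus a provenance log (stage, parameters, input checksums) when given an
output directory; rerunning a configuration reproduces its outputs
byte-for-byte. These functions are the package's orchestration surface;
scripted use from R covers what a shell front-end would, so none is
shipped.

## Known limitations

- The F_ST estimator is intentionally the simple heterozygosity form;
  it is biased at low coverage and small pool numbers, and windowed
  values should be ranked, not compared across studies.
- Read-count CMH p-values are anticonservative under pooled sampling
  (see above); use ranks, or the independent-pairing design when
  approximate calibration matters.
- Clark phasing degrades gracefully but detectably on panmictic,
  high-diversity cohorts; haplotype-level conclusions there should rest
  on the network/tree over collapsed haplotypes, not on individual
  phase assignments.
- The parsimony connection limit is an approximation to the exact
  statistical-parsimony recursion, adequate for the "distant singletons
  disconnect" regime it serves.
- The t-test arm at 10+10 individuals has limited power after
  Bonferroni correction; the frequency filter is the primary detector
  at this design size.
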