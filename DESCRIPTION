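Package: poolsweep
Title: Pooled-Template Genome Scans, Targeted Association and
    Candidate-Gene Sweep Characterisation for Insecticide Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting insecticide-resistance candidates in
    mosquito populations from three complementary designs: a replicated
    pool-seq genome scan (site filters, heterozygosity-based F_ST in
    base-pair or SNP-count windows, and Cochran-Mantel-Haenszel tests
    across replicate alive/dead pool pairings); an individual-level
    targeted-enrichment association stage (presence/absence frequency
    differentials between phenotype groups, three-way comparison
    intersection, unpaired t-tests with Bonferroni correction, and
    codon-level variant effect classification); and a candidate-gene
    haplotype analysis (deterministic parsimony phasing of
    ambiguity-coded consensus sequences, haplotype and nucleotide
    diversity, amino-acid scans, statistical-parsimony haplotype
    networks and neighbor-joining trees) aimed at characterising
    selective sweeps at cytochrome P450 loci. Seeded generators produce
    pooled count tables and individual cohorts with planted resistance
    variants so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
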