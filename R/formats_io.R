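# Readers, writers and validated in-memory models for the external formats
# the pipeline touches: aligned FASTA (ambiguity-coded consensus sequences),
# popoolation2-style sync tables, a minimal tab-separated variant table,
# a GFF3-like gene model and a TSV sample sheet.
#
# Coordinate convention: 1-based inclusive throughout, both at the file
# boundary (VCF/GFF convention) and in memory, matching base R and IRanges
# indexing. Window arithmetic that needs half-open logic does the conversion
# locally and is tested in both directions.

## ---- sequence sets -------------------------------------------------------

# Allowed residues: the four bases, N, and the six two-fold IUPAC ambiguity
# codes a diploid consensus can produce. Three/four-fold codes are rejected.
SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M")

# two-fold ambiguity code -> the unordered base pair it encodes
AMBIGUITY_MAP <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

# unordered base pair -> ambiguity code (names are sorted pairs, e.g. "AG")
AMBIGUITY_CODE <- local({
  x <- vapply(AMBIGUITY_MAP, paste0, "", collapse = "")
  stats::setNames(names(x), unname(x))
})

#' Construct a validated sequence set
#'
#' A `sequence_set` holds named DNA sequences over the alphabet
#' `A,C,G,T,N` plus the six two-fold IUPAC ambiguity codes
#' (`R,Y,S,W,K,M`) used to mark heterozygous positions in diploid
#' consensus sequences. Three- and four-fold codes are rejected because a
#' diploid consensus cannot produce them.
#'
#' @param seqs named character vector of sequences (upper case enforced).
#' @param aligned logical; when `TRUE` all sequences must have equal length.
#' @return An object of class `sequence_set`: a list with elements `seq`
#'   (named character vector) and `aligned`.
#' @export
sequence_set <- function(seqs, aligned = TRUE) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!res %in% SEQ_ALPHABET)
    if (length(bad))
      stop(sprintf("illegal residue '%s' in record '%s' at column %d",
                   res[bad[1]], names(seqs)[i], bad[1]))
  }
  if (aligned && length(seqs) > 1 && length(unique(nchar(seqs))) != 1)
    stop("sequences are not aligned: lengths differ (",
         paste(range(nchar(seqs)), collapse = "-"), ")")
  structure(list(seq = seqs, aligned = aligned), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d record(s)%s\n", length(x$seq),
              if (x$aligned) sprintf(", aligned, width %d",
                                     if (length(x$seq)) nchar(x$seq[[1]]) else 0L)
              else ""))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$seq)

#' Read a (multi-)FASTA alignment
#'
#' Ambiguity codes are preserved verbatim; validation follows
#' [sequence_set()].
#'
#' @param path FASTA file.
#' @param expect_aligned require equal sequence lengths.
#' @return A [sequence_set()].
#' @export
read_alignment <- function(path, expect_aligned = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  sequence_set(seqs, aligned = expect_aligned)
}

#' Write a sequence set as FASTA
#'
#' @param x a [sequence_set()].
#' @param path output file (UTF-8, LF endings).
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "sequence_set"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x$seq), path)
  invisible(path)
}

## ---- sync tables ---------------------------------------------------------

SYNC_NUC <- c("A", "T", "C", "G", "N", "del")

#' Construct a sync table of per-site, per-pool nucleotide counts
#'
#' The sync layout follows the popoolation2 dialect: one row per genomic
#' site with a colon-separated `A:T:C:G:N:del` count block per pool.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`.
#' @param counts integer array `n_sites x 6 x n_pools`; the middle dimension
#'   is ordered `A,T,C,G,N,del`.
#' @param pool_ids character vector naming the pools.
#' @return An object of class `sync_table`.
#' @export
sync_table <- function(sites, counts, pool_ids) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref") %in% names(sites)))
  n <- nrow(sites)
  if (n == 0) {
    counts <- array(0L, dim = c(0L, 6L, length(pool_ids)),
                    dimnames = list(NULL, SYNC_NUC, pool_ids))
  }
  stopifnot(length(dim(counts)) == 3, dim(counts)[1] == n,
            dim(counts)[2] == 6, dim(counts)[3] == length(pool_ids))
  if (any(counts < 0)) stop("negative count in sync table")
  if (any(counts != round(counts))) stop("non-integer count in sync table")
  dimnames(counts) <- list(NULL, SYNC_NUC, pool_ids)
  # positions strictly increasing within chrom
  if (n > 1) {
    by_chrom <- split(sites$pos, sites$chrom)
    if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), TRUE)))
      stop("positions must be strictly increasing within each chromosome")
  }
  structure(list(sites = sites, counts = counts, pool_ids = pool_ids),
            class = "sync_table")
}

#' @export
print.sync_table <- function(x, ...) {
  cat(sprintf("sync_table: %d site(s) x %d pool(s) [%s]\n",
              nrow(x$sites), length(x$pool_ids),
              paste(x$pool_ids, collapse = ", ")))
  invisible(x)
}

#' Per-site, per-pool coverage of a sync table
#'
#' Coverage is the sum of the six nucleotide counts of a pool at a site.
#'
#' @param x a [sync_table()].
#' @return numeric matrix, sites x pools.
#' @export
sync_coverage <- function(x) {
  stopifnot(inherits(x, "sync_table"))
  out <- apply(x$counts, c(1, 3), sum)
  if (nrow(x$sites) == 0)
    out <- matrix(0, 0, length(x$pool_ids), dimnames = list(NULL, x$pool_ids))
  out
}

#' Read a popoolation2-style sync file
#'
#' @param path tab-separated file: `chrom pos ref` then one
#'   `A:T:C:G:N:del` block per pool.
#' @param pool_ids pool names, one per count block.
#' @return A [sync_table()].
#' @export
read_sync <- function(path, pool_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  npool <- length(pool_ids)
  if (!length(lines)) {
    return(sync_table(data.frame(chrom = character(), pos = integer(),
                                 ref = character()),
                      array(0L, c(0, 6, npool)), pool_ids))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3 + npool))
    stop(sprintf("line %d has %d count block(s); expected %d pools",
                 which(nf != 3 + npool)[1], nf[which(nf != 3 + npool)[1]] - 3,
                 npool))
  m <- do.call(rbind, fields)
  sites <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 3])
  counts <- array(0L, dim = c(nrow(m), 6, npool))
  for (j in seq_len(npool)) {
    blk <- strsplit(m[, 3 + j], ":", fixed = TRUE)
    if (any(lengths(blk) != 6))
      stop("malformed count block (need 6 colon-separated counts) at line ",
           which(lengths(blk) != 6)[1])
    v <- suppressWarnings(as.numeric(unlist(blk)))
    if (anyNA(v) || any(v < 0) || any(v != round(v)))
      stop("counts must be nonnegative integers (pool ", pool_ids[j], ")")
    counts[, , j] <- matrix(as.integer(v), ncol = 6, byrow = TRUE)
  }
  sync_table(sites, counts, pool_ids)
}

#' Write a sync table
#'
#' @param x a [sync_table()].
#' @param path output path.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync_table"))
  n <- nrow(x$sites)
  blocks <- vapply(seq_along(x$pool_ids), function(j) {
    apply(x$counts[, , j, drop = FALSE], 1, paste, collapse = ":")
  }, character(n))
  if (n == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (is.null(dim(blocks))) blocks <- matrix(blocks, nrow = n)
  lines <- paste(x$sites$chrom, x$sites$pos, x$sites$ref,
                 apply(blocks, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---- gene models ---------------------------------------------------------

GENE_FEATURES <- c("five_prime_utr", "exon", "intron", "three_prime_utr")

#' Construct a validated gene model
#'
#' Features are 1-based inclusive intervals in gene-local coordinates.
#' Coding intervals (CDS) are derived as the exon intervals minus any UTR
#' overlap. The union of UTRs, introns and CDS must tile `1..total_length`
#' contiguously without overlap, and the coding length must be divisible
#' by three.
#'
#' @param gene_id gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param features data.frame with columns `kind`
#'   (`five_prime_utr`/`exon`/`intron`/`three_prime_utr`), `start`, `end`.
#' @return An object of class `gene_model` with elements `gene_id`,
#'   `strand`, `features`, `cds_intervals`, `total_length`,
#'   `coding_length`, `noncoding_length`.
#' @export
gene_model <- function(gene_id, strand, features) {
  stopifnot(strand %in% c("+", "-"),
            all(c("kind", "start", "end") %in% names(features)))
  features$kind <- tolower(features$kind)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!all(features$kind %in% GENE_FEATURES))
    stop("unknown feature kind(s): ",
         paste(setdiff(features$kind, GENE_FEATURES), collapse = ", "))
  if (any(features$end < features$start)) stop("feature with end < start")
  features <- features[order(features$start), , drop = FALSE]
  total <- max(features$end)

  utr <- features[features$kind %in% c("five_prime_utr", "three_prime_utr"), ]
  exon <- features[features$kind == "exon", ]
  cds <- interval_setdiff(exon[, c("start", "end")], utr[, c("start", "end")])
  tiles <- rbind(utr[, c("start", "end")],
                 features[features$kind == "intron", c("start", "end")],
                 cds)
  tiles <- tiles[order(tiles$start), , drop = FALSE]
  if (nrow(tiles) == 0 || tiles$start[1] != 1 ||
      any(tiles$start[-1] != tiles$end[-nrow(tiles)] + 1))
    stop("features do not tile the gene contiguously without overlap")
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  coding <- as.integer(sum(cds$end - cds$start + 1))
  if (coding %% 3 != 0)
    stop("coding length ", coding, " is not divisible by 3")
  structure(list(gene_id = gene_id, strand = strand,
                 features = features, cds_intervals = cds,
                 total_length = total, coding_length = coding,
                 noncoding_length = total - coding),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s): %d bp total, %d coding, %d noncoding\n",
              x$gene_id, x$strand, x$total_length, x$coding_length,
              x$noncoding_length))
  invisible(x)
}

# set difference of 1-based inclusive interval lists (data.frames start/end)
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a[0, , drop = FALSE])
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    segs <- data.frame(start = a$start[i], end = a$end[i])
    for (j in seq_len(nrow(b))) {
      keep <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        bs <- b$start[j]; be <- b$end[j]
        if (be < s || bs > e) { keep[[length(keep) + 1]] <- c(s, e); next }
        if (bs > s) keep[[length(keep) + 1]] <- c(s, bs - 1)
        if (be < e) keep[[length(keep) + 1]] <- c(be + 1, e)
      }
      segs <- if (length(keep))
        data.frame(start = vapply(keep, `[`, 0, 1),
                   end = vapply(keep, `[`, 0, 2))
      else data.frame(start = integer(), end = integer())
      if (nrow(segs) == 0) break
    }
    pieces[[i]] <- segs
  }
  out <- do.call(rbind, pieces)
  out[order(out$start), , drop = FALSE]
}

#' Read a GFF3-like gene model
#'
#' Expects the standard nine tab-separated GFF columns; feature types
#' `five_prime_UTR`, `exon`, `intron` and `three_prime_UTR` (case
#' insensitive) are used, everything else is ignored. Coordinates are
#' gene-local, 1-based inclusive.
#'
#' @param path GFF3-like file.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) stop("expected 9 tab-separated GFF columns")
  m <- do.call(rbind, f)
  kind <- tolower(m[, 3])
  keep <- kind %in% GENE_FEATURES
  if (!any(keep)) stop("no gene features found in ", path)
  gid <- sub(".*ID=([^;]+).*", "\\1", m[keep, 9][1])
  gene_model(gene_id = gid, strand = m[keep, 7][1],
             features = data.frame(kind = kind[keep],
                                   start = as.integer(m[keep, 4]),
                                   end = as.integer(m[keep, 5])))
}

#' Write a gene model as GFF3-like text
#'
#' @param x a [gene_model()].
#' @param path output path.
#' @export
write_gene_model <- function(x, path) {
  stopifnot(inherits(x, "gene_model"))
  lines <- c("##gff-version 3",
             sprintf("%s\tpoolsweep\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     x$gene_id, x$features$kind, x$features$start,
                     x$features$end, x$strand, x$gene_id))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---- variant tables ------------------------------------------------------

#' Construct a per-individual variant table
#'
#' Holds one row per variant and, per sample, the number of reads
#' supporting the alternate allele and the total depth. The allele
#' fraction is always derived as `supporting/depth` and is missing
#' (`NA`) wherever depth is zero — "no data" is never conflated with
#' "allele absent".
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `kind` (`SNP`/`MNP`/`indel`).
#' @param supporting,depth integer matrices, variants x samples.
#' @param samples sample identifiers (column names).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(variants, supporting, depth, samples) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "kind") %in% names(variants)))
  supporting <- as.matrix(supporting); depth <- as.matrix(depth)
  stopifnot(nrow(supporting) == nrow(variants),
            all(dim(supporting) == dim(depth)),
            ncol(supporting) == length(samples))
  if (any(supporting > depth)) stop("supporting reads exceed depth")
  if (any(supporting < 0) || any(depth < 0)) stop("negative read counts")
  kind_ok <- with(variants, ifelse(
    kind == "SNP", nchar(ref) == 1 & nchar(alt) == 1,
    ifelse(kind == "MNP", nchar(ref) == nchar(alt) & nchar(ref) > 1,
           nchar(ref) != nchar(alt))))
  if (!all(kind_ok))
    stop("variant_kind inconsistent with allele lengths at row ",
         which(!kind_ok)[1])
  colnames(supporting) <- colnames(depth) <- samples
  structure(list(variants = variants, supporting = supporting,
                 depth = depth, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variant(s) x %d sample(s)\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' Per-sample allele fractions of a variant table
#'
#' @param x a [variant_table()].
#' @return numeric matrix with `NA` where depth is zero.
#' @export
allele_fractions <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  f <- x$supporting / x$depth
  f[x$depth == 0] <- NA_real_
  f
}

#' Write a variant table (optionally with annotations)
#'
#' Tab-separated: `chrom pos ref alt kind` then one column per sample
#' holding `supporting:depth:fraction`; fraction is `.` when depth is 0.
#' Extra annotation columns are appended verbatim. Round-trips through
#' [read_variant_table()].
#'
#' @param x a [variant_table()].
#' @param path output path.
#' @param annotations optional data.frame (one row per variant).
#' @export
write_variant_report <- function(x, path, annotations = NULL) {
  stopifnot(inherits(x, "variant_table"))
  frac <- allele_fractions(x)
  n <- nrow(x$variants)
  cells <- matrix("", n, length(x$samples))
  for (j in seq_along(x$samples)) {
    fj <- ifelse(is.na(frac[, j]), ".",
                 format(frac[, j], digits = 17, trim = TRUE,
                        scientific = FALSE))
    cells[, j] <- paste(x$supporting[, j], x$depth[, j], fj, sep = ":")
  }
  header <- c("chrom", "pos", "ref", "alt", "kind", x$samples,
              if (!is.null(annotations)) names(annotations))
  body <- cbind(x$variants$chrom, x$variants$pos, x$variants$ref,
                x$variants$alt, x$variants$kind, cells)
  if (!is.null(annotations)) {
    stopifnot(nrow(annotations) == n)
    body <- cbind(body, as.matrix(format(annotations, trim = TRUE)))
  }
  lines <- c(paste(header, collapse = "\t"),
             if (n) apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a variant table written by [write_variant_report()]
#'
#' @param path input path.
#' @return A [variant_table()]; annotation columns, if present, are
#'   attached as attribute `"annotations"`.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fixed <- c("chrom", "pos", "ref", "alt", "kind")
  stopifnot(identical(header[1:5], fixed))
  body <- lines[-1]
  # sample columns are those matching the supporting:depth:fraction triplet
  if (!length(body)) {
    is_sample <- rep(TRUE, length(header) - 5)
  } else {
    probe <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    is_sample <- grepl("^[0-9]+:[0-9]+:", probe[-(1:5)])
  }
  samples <- header[-(1:5)][is_sample]
  ann_cols <- header[-(1:5)][!is_sample]
  if (!length(body)) {
    return(variant_table(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), kind = character()),
      matrix(0L, 0, length(samples)), matrix(0L, 0, length(samples)),
      samples))
  }
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  variants <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                         ref = m[, 3], alt = m[, 4], kind = m[, 5])
  ns <- length(samples)
  supp <- dep <- matrix(0L, nrow(m), ns)
  for (j in seq_len(ns)) {
    trip <- strsplit(m[, 5 + j], ":", fixed = TRUE)
    supp[, j] <- as.integer(vapply(trip, `[`, "", 1))
    dep[, j] <- as.integer(vapply(trip, `[`, "", 2))
  }
  vt <- variant_table(variants, supp, dep, samples)
  if (length(ann_cols)) {
    ann <- as.data.frame(m[, 5 + ns + seq_along(ann_cols), drop = FALSE])
    names(ann) <- ann_cols
    attr(vt, "annotations") <- ann
  }
  vt
}

## ---- sample sheets -------------------------------------------------------

SAMPLE_GROUPS <- c("alive", "dead", "lab_susceptible")

#' Construct a validated sample sheet
#'
#' @param df data.frame with columns `sample_id`, `country`, `group`
#'   (`alive` = R, `dead` = C, `lab_susceptible` = S), `role`
#'   (`pool`/`individual`) and `pool_haploid_size` (number of chromosomes:
#'   2 x individuals, 80 for pools of 40; `NA` for individuals).
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "country", "group", "role", "pool_haploid_size")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$group %in% SAMPLE_GROUPS))
    stop("group must be one of: ", paste(SAMPLE_GROUPS, collapse = ", "))
  if (!all(df$role %in% c("pool", "individual")))
    stop("role must be 'pool' or 'individual'")
  df$pool_haploid_size <- as.numeric(df$pool_haploid_size)
  pools <- df$role == "pool"
  if (any(pools & (is.na(df$pool_haploid_size) | df$pool_haploid_size < 2)))
    stop("pool_haploid_size must be >= 2 for pools")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet TSV
#' @param path tab-separated file with the [sample_sheet()] headers.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' Write a sample sheet TSV
#' @param x a [sample_sheet()].
#' @param path output path.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
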