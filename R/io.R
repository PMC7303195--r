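## Readers/writers for the plain-text interchange formats used throughout.
## Coordinate conventions: variants are 1-based (VCF-style), gene models
## 1-based inclusive on disk, fragments/marks BED-style 0-based half-open.

#' Read a genome from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per chromosome.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read gene models from a GTF-like TSV
#'
#' Expected columns: `gene_id`, `name`, `chrom`, `start`, `end` (1-based
#' inclusive), `strand` (+/-), `feature` (one of `gene`, `exon`, `UTR5`,
#' `UTR3`), `coding` (logical or 0/1), and optionally `pli`.
#'
#' @param path Path to the TSV file.
#' @return A validated `gene_models` object (see [gene_models()]).
#' @export
read_gene_models <- function(path) {
  gene_models(data.table::fread(path, sep = "\t"))
}

#' Construct a gene-model table
#'
#' Validates feature rows and derives the strand-aware transcription start
#' site (TSS) for each gene: `start` on `+`, `end` on `-` (1-based).
#'
#' @param df A data.frame of feature rows (see [read_gene_models()]).
#' @return A `gene_models` object: a data.table of feature rows with a
#'   `genes` attribute holding one row per gene (including `tss`).
#' @export
gene_models <- function(df) {
  dt <- data.table::as.data.table(df)
  req <- c("gene_id", "chrom", "start", "end", "strand", "feature")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop("gene model table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (!"name" %in% names(dt)) dt[, name := gene_id]
  if (!"coding" %in% names(dt)) dt[, coding := TRUE]
  dt[, coding := as.logical(coding)]
  if (any(dt$start > dt$end)) stop("gene model rows with start > end")
  bad <- setdiff(unique(dt$feature), c("gene", "exon", "UTR5", "UTR3"))
  if (length(bad)) stop("unknown gene-model features: ", paste(bad, collapse = ", "))
  genes <- dt[feature == "gene"]
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene rows")
  sub <- dt[feature != "gene"]
  if (nrow(sub)) {
    j <- merge(sub, genes[, .(gene_id, gstart = start, gend = end)],
               by = "gene_id")
    if (nrow(j) < nrow(sub)) stop("feature rows for unknown gene_id")
    if (any(j$start < j$gstart | j$end > j$gend)) {
      stop("exon/UTR outside gene bounds")
    }
  }
  genes[, tss := data.table::fifelse(strand == "+", start, end)]
  data.table::setattr(dt, "genes", genes[])
  data.table::setattr(dt, "class", c("gene_models", class(dt)))
  dt[]
}

#' One-row-per-gene view of a gene-model table
#'
#' @param gm A `gene_models` object.
#' @return data.table with one row per gene, including `tss`.
#' @export
gene_table <- function(gm) {
  g <- attr(gm, "genes")
  if (is.null(g)) stop("not a gene_models object")
  g
}

#' Read a variant table
#'
#' Columns: `rsid`, `chrom`, `pos` (1-based), `ref`, `alt`.
#'
#' @param path Path to the TSV file.
#' @return data.table of variants.
#' @export
read_variants <- function(path) {
  v <- data.table::fread(path, sep = "\t")
  req <- c("rsid", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(v))
  if (length(miss)) stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  v
}

#' Read Hi-C fragment-pair contact records
#'
#' Columns: `library_id`, `chrom_a`, `frag_a`, `chrom_b`, `frag_b`
#' (fragment indices are 0-based ordinals along the chromosome).
#'
#' @param path Path to the TSV file.
#' @return data.table of contact records.
#' @export
read_contacts <- function(path) {
  ct <- data.table::fread(path, sep = "\t")
  req <- c("library_id", "chrom_a", "frag_a", "chrom_b", "frag_b")
  miss <- setdiff(req, names(ct))
  if (length(miss)) stop("contact table lacks columns: ", paste(miss, collapse = ", "))
  ct
}

#' Read a tissue-stratified eQTL association table
#'
#' Columns: `tissue`, `rsid`, `gene_id`, `slope`, `pval`.
#'
#' @param path Path to the TSV file.
#' @return data.table of association records.
#' @export
read_eqtl_table <- function(path) {
  e <- data.table::fread(path, sep = "\t")
  req <- c("tissue", "rsid", "gene_id", "slope", "pval")
  miss <- setdiff(req, names(e))
  if (length(miss)) stop("eQTL table lacks columns: ", paste(miss, collapse = ", "))
  e
}

#' Read histone-mark intervals
#'
#' BED-like TSV: `chrom`, `start`, `end` (0-based half-open), `tissue`, `mark`.
#'
#' @param path Path to the TSV file.
#' @return data.table of mark intervals.
#' @export
read_marks <- function(path) {
  m <- data.table::fread(path, sep = "\t")
  req <- c("chrom", "start", "end", "tissue", "mark")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("mark table lacks columns: ", paste(miss, collapse = ", "))
  if (any(m$start >= m$end)) stop("mark intervals must satisfy start < end")
  m
}

#' Read a phased haplotype panel
#'
#' TSV with one column per variant (header = rsIDs) and one row per
#' haplotype; entries are 0 (reference allele) or 1 (alternate allele).
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, columns named by rsID.
#' @export
read_haplotypes <- function(path) {
  h <- data.table::fread(path, sep = "\t")
  m <- as.matrix(h)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    stop("haplotype panel must be binary 0/1 with no missing values")
  }
  m
}

#' Write restriction fragments as BED
#'
#' BED is 0-based half-open, matching the internal fragment representation;
#' the fragment ordinal is written in the name column.
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- fragments[, .(chrom, start, end, name = paste0("frag_", index))]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read restriction fragments from BED
#'
#' @param path BED path as written by [write_fragments_bed()].
#' @return Fragment data.table (`chrom`, `start`, `end`, `index`).
#' @export
read_fragments_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  out <- bed[, .(chrom, start, end,
                 index = as.integer(sub("^frag_", "", name)))]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Read position weight matrices from MEME-like text
#'
#' Grammar: each motif starts with a line `MOTIF <name>`, followed by L
#' whitespace-separated rows of 4 probabilities in column order A C G T.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the PWM text file.
#' @return Named list of `pwm` objects (see [pwm()]).
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    nm <- sub("^MOTIF\\s+", "", lines[starts[i]])
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(strsplit(body, "\\s+"), as.numeric)
    if (!all(lengths(rows) == 4L)) stop("PWM rows must have 4 columns: ", nm)
    probs <- do.call(rbind, rows)
    colnames(probs) <- c("A", "C", "G", "T")
    out[[nm]] <- pwm(nm, probs)
  }
  out
}

#' Write position weight matrices to MEME-like text
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste("MOTIF", p$motif_name), con)
    writeLines(apply(p$probs, 1L, function(r) paste(format(r, digits = 6), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: term id, term description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; names are term ids, with term
#'   descriptions in the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("GMT lines need id, description, >=1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

## Deterministic TSV writer used by the pipeline (fixed eol, no scipen drift)
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", eol = "\n", scipen = 50)
  invisible(path)
}
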