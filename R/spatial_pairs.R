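## Fragment-pair contact indexing and spatial SNP-gene pair derivation.

#' Build a symmetric index over Hi-C fragment-pair contacts
#'
#' Contact records have unordered pair semantics: a record (a, b) is
#' retrievable from either endpoint. Self-pairs (a == b) are retained in the
#' index but never contribute to spatial pair calling. Records that
#' reference fragments absent from the digestion table are skipped with a
#' warning and counted in the QC attribute.
#'
#' @param contacts Contact data.table (`library_id`, `chrom_a`, `frag_a`,
#'   `chrom_b`, `frag_b`).
#' @param fragments Fragment table from [digest_genome()]; used to validate
#'   fragment keys.
#' @return A `contact_index` object. Attribute `qc` records the number of
#'   skipped records and per-library contact counts.
#' @export
build_contact_index <- function(contacts, fragments) {
  ct <- data.table::as.data.table(contacts)
  keys <- fragments[, paste(chrom, index)]
  ok <- paste(ct$chrom_a, ct$frag_a) %in% keys &
    paste(ct$chrom_b, ct$frag_b) %in% keys
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(n_skipped, " contact record(s) reference unknown fragments; skipped")
    ct <- ct[ok]
  }
  ct[, rec_id := seq_len(.N)]
  fwd <- ct[, .(chrom = chrom_a, frag = frag_a, p_chrom = chrom_b,
                p_frag = frag_b, library_id, rec_id)]
  rev <- ct[, .(chrom = chrom_b, frag = frag_b, p_chrom = chrom_a,
                p_frag = frag_a, library_id, rec_id)]
  edges <- data.table::rbindlist(list(fwd, rev))
  data.table::setkey(edges, chrom, frag)
  qc <- list(
    n_records = nrow(ct), n_skipped = n_skipped,
    per_library = if (nrow(ct)) ct[, .N, by = library_id] else
      data.table::data.table(library_id = character(0), N = integer(0))
  )
  structure(list(edges = edges, records = ct, qc = qc),
            class = "contact_index")
}

#' @export
print.contact_index <- function(x, ...) {
  cat("contact_index:", nrow(x$records), "records,",
      length(unique(x$records$library_id)), "libraries,",
      x$qc$n_skipped, "skipped\n")
  invisible(x)
}

#' Partner fragments of a given fragment
#'
#' @param index A `contact_index`.
#' @param chrom,frag_index Fragment key (chromosome, 0-based ordinal).
#' @param min_libraries Keep partners supported by at least this many
#'   distinct libraries (default 1).
#' @return data.table of partners: `p_chrom`, `p_frag`, `n_libraries`,
#'   `n_contacts`, `libraries` (list column). Self-partners are excluded.
#' @export
interacting_fragments <- function(index, chrom, frag_index, min_libraries = 1L) {
  stopifnot(inherits(index, "contact_index"), length(chrom) == 1L,
            length(frag_index) == 1L)
  ## the query key must live outside the data.table scope: the edge table
  ## itself has a `chrom` column which would shadow the argument
  qkey <- data.table::data.table(chrom = as.character(chrom),
                                 frag = as.integer(frag_index))
  hits <- index$edges[qkey, nomatch = NULL, on = c("chrom", "frag")]
  hits <- hits[!(p_chrom == qkey$chrom & p_frag == qkey$frag)]
  if (!nrow(hits)) {
    return(data.table::data.table(p_chrom = character(0), p_frag = integer(0),
                                  n_libraries = integer(0), n_contacts = integer(0),
                                  libraries = list()))
  }
  out <- hits[, .(n_libraries = data.table::uniqueN(library_id),
                  n_contacts = data.table::uniqueN(rec_id),
                  libraries = list(sort(unique(library_id)))),
              by = .(p_chrom, p_frag)]
  out[n_libraries >= min_libraries]
}

#' Map restriction fragments to overlapping genes
#'
#' A gene is assigned to a fragment iff its gene-body interval (converted to
#' 0-based half-open) overlaps the fragment interval by at least 1 bp.
#'
#' @param fragments Fragment table (0-based half-open).
#' @param gm A `gene_models` object.
#' @return data.table `chrom`, `index`, `gene_id` (one row per overlap).
#' @export
map_fragments_to_genes <- function(fragments, gm) {
  genes <- gene_table(gm)
  out <- vector("list", 0L)
  for (ch in unique(fragments$chrom)) {
    fr <- fragments[chrom == ch]
    g <- genes[chrom == ch]
    if (!nrow(g)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(fr$start + 1L, fr$end),        # to 1-based inclusive
      IRanges::IRanges(g$start, g$end),
      minoverlap = 1L)
    if (!length(ov)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = ch,
      index = fr$index[S4Vectors::queryHits(ov)],
      gene_id = g$gene_id[S4Vectors::subjectHits(ov)])
  }
  if (!length(out)) {
    return(data.table::data.table(chrom = character(0), index = integer(0),
                                  gene_id = character(0)))
  }
  data.table::rbindlist(out)
}

#' Derive spatial SNP-gene pairs from fragment contacts
#'
#' For every fragment-assigned variant, partner fragments across all
#' libraries are looked up in the contact index and intersected with gene
#' bodies; each (variant, gene) combination supported by at least one
#' contact becomes a spatial pair, with supporting libraries unioned over
#' all partner fragments overlapping the gene. A variant whose own fragment
#' overlaps a gene does not create a pair by containment alone unless
#' `include_self_fragment_pairs = TRUE` (such rows carry zero contacts and
#' are flagged).
#'
#' @param variants Variant table with `fragment_index` set
#'   (see [assign_variants_to_fragments()]).
#' @param index A `contact_index`.
#' @param fragments Fragment table.
#' @param gm A `gene_models` object.
#' @param min_libraries Minimum distinct supporting libraries (default 1).
#' @param include_self_fragment_pairs Also emit containment-only pairs
#'   (default FALSE).
#' @return data.table of pairs: `rsid`, `gene_id`, `n_libraries`,
#'   `n_contacts`, `libraries` (list column), `self_fragment` flag.
#' @export
spatial_snp_gene_pairs <- function(variants, index, fragments, gm,
                                   min_libraries = 1L,
                                   include_self_fragment_pairs = FALSE) {
  stopifnot(inherits(index, "contact_index"))
  if (!"fragment_index" %in% names(variants)) {
    stop("variants must be fragment-assigned first")
  }
  frag2gene <- map_fragments_to_genes(fragments, gm)
  v <- data.table::as.data.table(variants)[!is.na(fragment_index)]
  acc <- vector("list", 0L)
  for (i in seq_len(nrow(v))) {
    partners <- interacting_fragments(index, v$chrom[i], v$fragment_index[i],
                                      min_libraries = 1L)
    if (nrow(partners)) {
      hits <- merge(partners, frag2gene,
                    by.x = c("p_chrom", "p_frag"), by.y = c("chrom", "index"))
      if (nrow(hits)) {
        pair <- hits[, .(
          n_libraries = data.table::uniqueN(unlist(libraries)),
          n_contacts = sum(n_contacts),
          libraries = list(sort(unique(unlist(libraries)))),
          self_fragment = FALSE), by = gene_id]
        pair[, rsid := v$rsid[i]]
        acc[[length(acc) + 1L]] <- pair
      }
    }
    if (include_self_fragment_pairs) {
      own <- frag2gene[chrom == v$chrom[i] & index == v$fragment_index[i]]
      if (nrow(own)) {
        acc[[length(acc) + 1L]] <- data.table::data.table(
          gene_id = own$gene_id, n_libraries = 0L, n_contacts = 0L,
          libraries = list(character(0)), self_fragment = TRUE,
          rsid = v$rsid[i])
      }
    }
  }
  if (!length(acc)) {
    return(data.table::data.table(rsid = character(0), gene_id = character(0),
                                  n_libraries = integer(0), n_contacts = integer(0),
                                  libraries = list(), self_fragment = logical(0)))
  }
  pairs <- data.table::rbindlist(acc, use.names = TRUE)
  ## containment-only rows are superseded by contact-supported rows
  pairs <- pairs[order(rsid, gene_id, self_fragment)]
  pairs <- unique(pairs, by = c("rsid", "gene_id"))
  pairs <- pairs[self_fragment | n_libraries >= min_libraries]
  data.table::setcolorder(pairs, c("rsid", "gene_id"))
  data.table::setorder(pairs, rsid, gene_id)
  pairs[]
}
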