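## Reporting: tissue x gene interaction summaries, direction tallies,
## shared-regulation sets, and hypergeometric gene-set enrichment.

#' Validate a table of regulatory interaction records
#'
#' One record is one (tissue, gene, SNP) triple with a signed effect size;
#' duplicate triples are a validation error.
#'
#' @param df data.frame with `tissue`, `gene`, `rsid`, `effect_size`.
#' @return data.table of validated records.
#' @export
interaction_records <- function(df) {
  dt <- data.table::as.data.table(df)
  req <- c("tissue", "gene", "rsid", "effect_size")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("interaction records lack columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(dt[, .(tissue, gene, rsid)])) {
    stop("duplicate (tissue, gene, rsid) triples")
  }
  if (!is.numeric(dt$effect_size)) stop("effect_size must be numeric")
  dt
}

#' Summarise interaction records
#'
#' Computes the report-level counts: total records (one per tissue x gene x
#' SNP), distinct SNP-gene pairs, tissues, SNPs, genes, per-tissue record
#' counts, per-SNP gene sets, and per-tissue up-/down-regulating SNP sets.
#' Also builds a tissue x gene matrix of "rsid:effect" strings mirroring the
#' wide reporting layout.
#'
#' @param records Interaction records (validated with
#'   [interaction_records()]).
#' @return A `summary_counts` list.
#' @export
summarise_interactions <- function(records) {
  r <- interaction_records(records)
  per_tissue <- r[, .N, by = tissue][order(tissue)]
  per_snp <- r[, .(genes = list(sort(unique(gene)))), by = rsid][order(rsid)]
  tallies <- lapply(stats::setNames(nm = sort(unique(r$tissue))),
                    function(tt) direction_tally(r, tt))
  tissues <- sort(unique(r$tissue))
  genes <- sort(unique(r$gene))
  mat <- matrix("", nrow = length(tissues), ncol = length(genes),
                dimnames = list(tissues, genes))
  cells <- r[order(tissue, gene, rsid),
             .(cell = paste(sprintf("%s:%g", rsid, effect_size),
                            collapse = ";")),
             by = .(tissue, gene)]
  mat[cbind(cells$tissue, cells$gene)] <- cells$cell
  structure(list(
    n_records = nrow(r),
    n_pairs = data.table::uniqueN(r[, .(rsid, gene)]),
    n_tissues = length(tissues),
    n_snps = data.table::uniqueN(r$rsid),
    n_genes = length(genes),
    per_tissue = stats::setNames(per_tissue$N, per_tissue$tissue),
    per_snp_genes = stats::setNames(per_snp$genes, per_snp$rsid),
    direction = tallies,
    matrix = mat
  ), class = "summary_counts")
}

#' @export
print.summary_counts <- function(x, ...) {
  cat("interaction summary:", x$n_records, "records |", x$n_pairs,
      "SNP-gene pairs |", x$n_snps, "SNPs |", x$n_genes, "genes |",
      x$n_tissues, "tissues\n")
  invisible(x)
}

#' Up-/down-regulating SNP sets for one tissue
#'
#' A SNP is in the down-set iff it has at least one record with a negative
#' effect size in the tissue; the up-set analogously for positive effects.
#' A SNP with both signs appears in both sets.
#'
#' @param records Interaction records.
#' @param tissue_name Tissue to tally.
#' @return list(up, down) of sorted rsID vectors.
#' @export
direction_tally <- function(records, tissue_name) {
  r <- data.table::as.data.table(records)
  if (!tissue_name %in% r$tissue) stop("tissue not present: ", tissue_name)
  rt <- r[tissue == tissue_name]
  list(up = sort(unique(rt$rsid[rt$effect_size > 0])),
       down = sort(unique(rt$rsid[rt$effect_size < 0])))
}

#' Per-SNP gene sets and the gene co-regulation graph
#'
#' Maps every SNP to the distinct genes it regulates and derives edges
#' (geneA, geneB, shared SNPs) between genes co-regulated by at least one
#' common SNP.
#'
#' @param records Interaction records.
#' @return list with `gene_sets` (named list rsid -> sorted gene vector) and
#'   `edges` (data.table `gene_a`, `gene_b`, `shared_snps` list column,
#'   `n_shared`).
#' @export
shared_regulation <- function(records) {
  r <- interaction_records(records)
  per_snp <- r[, .(genes = list(sort(unique(gene)))), by = rsid][order(rsid)]
  gene_sets <- stats::setNames(per_snp$genes, per_snp$rsid)
  acc <- vector("list", 0L)
  for (i in seq_along(gene_sets)) {
    gs <- gene_sets[[i]]
    if (length(gs) < 2L) next
    cmb <- utils::combn(gs, 2L)
    acc[[length(acc) + 1L]] <- data.table::data.table(
      gene_a = cmb[1L, ], gene_b = cmb[2L, ], rsid = names(gene_sets)[i])
  }
  edges <- if (length(acc)) {
    data.table::rbindlist(acc)[, .(shared_snps = list(sort(unique(rsid))),
                                   n_shared = data.table::uniqueN(rsid)),
                               by = .(gene_a, gene_b)]
  } else {
    data.table::data.table(gene_a = character(0), gene_b = character(0),
                           shared_snps = list(), n_shared = integer(0))
  }
  list(gene_sets = gene_sets, edges = edges[])
}

#' Hypergeometric gene-set enrichment
#'
#' For a query of n genes drawn from a universe of N, a term with K members
#' and overlap k gets the upper-tail probability P(X >= k) of the
#' hypergeometric distribution. Multiple testing is corrected with
#' Benjamini-Hochberg by default (Bonferroni available); results are sorted
#' by adjusted p.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param term_sets Named list of term gene sets (subsets of the universe).
#' @param universe Character vector, the statistical domain.
#' @param correction "BH" (default) or "bonferroni".
#' @return data.table: `term_id`, `k`, `K`, `n`, `N`, `pval`, `adj_p`.
#' @export
enrichment <- function(query, term_sets, universe,
                       correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  query <- unique(query)
  universe <- unique(universe)
  off <- setdiff(query, universe)
  if (length(off)) stop("query genes outside universe: ",
                        paste(off, collapse = ", "))
  bad <- names(term_sets)[vapply(term_sets,
                                 function(s) length(setdiff(s, universe)) > 0,
                                 logical(1))]
  if (length(bad)) stop("term sets outside universe: ",
                        paste(bad, collapse = ", "))
  N <- length(universe)
  n <- length(query)
  res <- data.table::rbindlist(lapply(names(term_sets), function(id) {
    K <- length(unique(term_sets[[id]]))
    k <- length(intersect(query, term_sets[[id]]))
    data.table::data.table(
      term_id = id, k = k, K = K, n = n, N = N,
      pval = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  }))
  if (!nrow(res)) return(res)
  res[, adj_p := if (correction == "BH") bh_fdr(pval)$qval
                 else pmin(1, pval * .N)]
  data.table::setorder(res, adj_p, pval, term_id)
  res[]
}

#' Write a wide tissue-by-gene interaction table
#'
#' One row per tissue, one column per gene; cells are semicolon-joined
#' "rsID:effect" entries.
#'
#' @param summary A `summary_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(summary, path) {
  stopifnot(inherits(summary, "summary_counts"))
  m <- summary$matrix
  dt <- data.table::data.table(tissue = rownames(m))
  for (g in colnames(m)) dt[[g]] <- m[, g]
  write_tsv(dt, path)
}
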