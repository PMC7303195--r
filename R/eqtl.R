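## eQTL join, Benjamini-Hochberg FDR control, cis/trans classification.

#' Retrieve eQTL associations for spatial SNP-gene pairs
#'
#' Returns every (tissue, rsid, gene) row of the association table whose
#' (rsid, gene) is a spatial pair. Pairs with no row in any tissue are
#' reported in the `untested` attribute.
#'
#' @param pairs Spatial pair table (`rsid`, `gene_id`, ...).
#' @param eqtl_table Association table (`tissue`, `rsid`, `gene_id`,
#'   `slope`, `pval`).
#' @return data.table of matched association records; attribute `untested`
#'   holds the pairs with no association anywhere.
#' @export
lookup_associations <- function(pairs, eqtl_table) {
  p <- data.table::as.data.table(pairs)[, .(rsid, gene_id)]
  e <- data.table::as.data.table(eqtl_table)
  hits <- merge(e, unique(p), by = c("rsid", "gene_id"))
  tested <- unique(hits[, .(rsid, gene_id)])
  untested <- data.table::fsetdiff(unique(p), tested)
  data.table::setcolorder(hits, c("tissue", "rsid", "gene_id"))
  data.table::setorder(hits, tissue, rsid, gene_id)
  data.table::setattr(hits, "untested", untested[])
  hits[]
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Computes adjusted p-values `q_(i) = min_{j >= i} m * p_(j) / j` over the
#' ascending-sorted p-values (capped at 1), mapped back to input order; tied
#' p-values share a q-value. Significance is `q < alpha` by default,
#' switchable to `q <= alpha`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param alpha FDR level in (0, 1) (default 0.05).
#' @param strict Use strict `q < alpha` (default TRUE, matching an
#'   "FDR < 0.05" report); `FALSE` uses `q <= alpha`.
#' @return list with `qval` (numeric) and `significant` (logical), both in
#'   input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))$qval  # all 0.05
#' @export
bh_fdr <- function(pvals, alpha = 0.05, strict = TRUE) {
  if (!length(pvals)) {
    return(list(qval = numeric(0), significant = logical(0)))
  }
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stopifnot(alpha >= 0, alpha < 1)  # alpha = 0: nothing can be significant
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  ## guard against float noise at the alpha boundary (e.g. 5*0.03/3):
  ## q is only meaningful to ~12 significant digits
  q_sorted <- signif(pmin(q_sorted, 1), 12)
  qval <- numeric(m)
  qval[o] <- q_sorted
  sig <- if (strict) qval < alpha else qval <= alpha
  list(qval = qval, significant = sig)
}

#' Classify variant-gene associations as cis or trans
#'
#' An association is cis iff variant and gene share a chromosome and the
#' variant lies within `window` bp of the gene's TSS; otherwise trans
#' (different chromosome, or same chromosome beyond the window). The window
#' is anchored at the TSS by convention.
#'
#' @param var_chrom,var_pos Variant chromosome and 1-based position
#'   (vectorised).
#' @param gene_chrom,gene_tss Gene chromosome and 1-based TSS (vectorised).
#' @param window Cis window in bp (default 1e6).
#' @return Character vector of "cis"/"trans".
#' @export
classify_cis_trans <- function(var_chrom, var_pos, gene_chrom, gene_tss,
                               window = 1e6) {
  if (anyNA(gene_tss)) stop("gene without TSS")
  data.table::fifelse(
    var_chrom == gene_chrom & abs(as.numeric(var_pos) - as.numeric(gene_tss)) <= window,
    "cis", "trans")
}

#' Significant spatial eQTLs: join, FDR control, classification
#'
#' Retrieves associations for the spatial pairs, applies Benjamini-Hochberg
#' over all retrieved records jointly (one family across tissues, SNPs and
#' genes), keeps the significant subset, and attaches the cis/trans class
#' and regulation direction (sign of the slope).
#'
#' @param pairs Spatial pair table.
#' @param eqtl_table Association table.
#' @param variants Variant table (`rsid`, `chrom`, `pos`).
#' @param gm A `gene_models` object (TSS source).
#' @param alpha FDR level (default 0.05).
#' @param window Cis window in bp (default 1e6).
#' @param strict Strict `q < alpha` semantics (default TRUE).
#' @return list with `all` (every retrieved record with `qval`,
#'   `significant`, `regulation_class`, `direction`) and `significant`
#'   (the significant subset).
#' @export
significant_spatial_eqtls <- function(pairs, eqtl_table, variants, gm,
                                      alpha = 0.05, window = 1e6,
                                      strict = TRUE) {
  recs <- lookup_associations(pairs, eqtl_table)
  if (!nrow(recs)) {
    warning("no eQTL associations retrieved for the spatial pairs")
    empty <- recs[, `:=`(qval = numeric(0), significant = logical(0),
                         regulation_class = character(0),
                         direction = character(0))]
    return(list(all = empty[], significant = empty[]))
  }
  adj <- bh_fdr(recs$pval, alpha = alpha, strict = strict)
  recs[, `:=`(qval = adj$qval, significant = adj$significant)]
  v <- data.table::as.data.table(variants)[, .(rsid, vchrom = chrom, pos)]
  g <- gene_table(gm)[, .(gene_id, gchrom = chrom, tss)]
  recs <- merge(recs, v, by = "rsid")
  recs <- merge(recs, g, by = "gene_id")
  recs[, regulation_class := classify_cis_trans(vchrom, pos, gchrom, tss,
                                                window = window)]
  recs[, direction := data.table::fifelse(slope > 0, "up", "down")]
  recs[, c("vchrom", "pos", "gchrom", "tss") := NULL]
  data.table::setcolorder(recs, c("tissue", "rsid", "gene_id", "slope",
                                  "pval", "qval", "significant",
                                  "regulation_class", "direction"))
  data.table::setorder(recs, tissue, rsid, gene_id)
  list(all = recs[], significant = recs[significant == TRUE][])
}

#' Ordinary least-squares eQTL fit
#'
#' Regresses expression on an additively coded genotype (0/1/2) and returns
#' the OLS slope with a two-sided p-value from the t statistic on n - 2
#' degrees of freedom. Stand-in for an external association store in
#' synthetic end-to-end runs.
#'
#' @param genotype Numeric vector coded 0/1/2.
#' @param expression Numeric vector, same length, n >= 3.
#' @return list(slope, pval), or NULL (with a warning) when the genotype has
#'   zero variance.
#' @export
fit_eqtl <- function(genotype, expression) {
  n <- length(genotype)
  stopifnot(n == length(expression), n >= 3L)
  gv <- stats::var(genotype)
  if (gv == 0) {
    warning("zero genotype variance; association undefined, record dropped")
    return(NULL)
  }
  syy <- sum((expression - mean(expression))^2)
  if (syy == 0) return(list(slope = 0, pval = 1))  # constant expression
  gx <- genotype - mean(genotype)
  slope <- sum(gx * expression) / sum(gx^2)
  resid <- expression - mean(expression) - slope * gx
  rss <- sum(resid^2)
  if (rss <= 1e-12 * syy) {
    return(list(slope = slope, pval = 0))          # numerically perfect fit
  }
  se <- sqrt(rss / (n - 2) / sum(gx^2))
  tstat <- slope / se
  list(slope = slope, pval = 2 * stats::pt(-abs(tstat), df = n - 2))
}
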