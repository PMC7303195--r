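## Regulatory annotation: histone marks, PWM allele scoring, LD statistics.

#' Default histone-mark grouping
#'
#' Shipped grouping: H3K4ac, H3K4me1 and H3K27ac as enhancer-class marks;
#' H3K4me3 and H3K9ac as promoter-class marks. Marks outside the grouping
#' are classed "other". Fully overridable.
#'
#' @return list with character vectors `enhancer` and `promoter`.
#' @export
default_mark_grouping <- function() {
  list(enhancer = c("H3K4ac", "H3K4me1", "H3K27ac"),
       promoter = c("H3K4me3", "H3K9ac"))
}

#' Overlap variants with histone-mark intervals
#'
#' A mark overlaps a variant when its half-open interval contains the
#' variant's 0-based position. A variant is enhancer-marked in a tissue iff
#' at least one enhancer-class mark overlaps it there; promoter analogously.
#'
#' @param variants Variant table (`rsid`, `chrom`, `pos`).
#' @param marks Mark table (`chrom`, `start`, `end`, `tissue`, `mark`;
#'   0-based half-open).
#' @param grouping Mark-to-class map (default [default_mark_grouping()]);
#'   unknown marks are classed "other" and logged via message.
#' @param tissues Optional tissue filter (character vector).
#' @return data.table per (rsid, tissue): `marks` (list column),
#'   `enhancer`, `promoter` (logical).
#' @export
histone_overlap <- function(variants, marks, grouping = default_mark_grouping(),
                            tissues = NULL) {
  v <- data.table::as.data.table(variants)
  m <- data.table::as.data.table(marks)
  if (!is.null(tissues)) m <- m[tissue %in% tissues]
  known <- unlist(grouping, use.names = FALSE)
  unknown <- setdiff(unique(m$mark), known)
  if (length(unknown)) {
    message("marks classed 'other': ", paste(unknown, collapse = ", "))
  }
  acc <- vector("list", 0L)
  for (i in seq_len(nrow(v))) {
    pos0 <- v$pos[i] - 1L
    hit <- m[chrom == v$chrom[i] & start <= pos0 & pos0 < end]
    if (!nrow(hit)) next
    res <- hit[, .(marks = list(sort(unique(mark))),
                   enhancer = any(mark %in% grouping$enhancer),
                   promoter = any(mark %in% grouping$promoter)),
               by = tissue]
    res[, rsid := v$rsid[i]]
    acc[[length(acc) + 1L]] <- res
  }
  if (!length(acc)) {
    return(data.table::data.table(rsid = character(0), tissue = character(0),
                                  marks = list(), enhancer = logical(0),
                                  promoter = logical(0)))
  }
  out <- data.table::rbindlist(acc, use.names = TRUE)
  data.table::setcolorder(out, c("rsid", "tissue"))
  data.table::setorder(out, rsid, tissue)
  out[]
}

#' Construct a position weight matrix object
#'
#' @param motif_name Motif name.
#' @param probs L x 4 matrix of base probabilities, column order A, C, G, T;
#'   each row must sum to 1 within 1e-6.
#' @param background Background base frequencies (default uniform).
#' @return A `pwm` object.
#' @export
pwm <- function(motif_name, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L, nrow(probs) >= 1L,
            length(background) == 4L, all(background > 0))
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("PWM rows must sum to 1: ", motif_name)
  }
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_name = motif_name, probs = probs,
                 background = background), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$motif_name, "length", nrow(x$probs), "\n")
  invisible(x)
}

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(s) {
  paste(rev(.COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

## score one exact placement (1-based window start) of pwm on sequence chars
.score_window <- function(chars, s, pwm_obj, pseudocount) {
  L <- nrow(pwm_obj$probs)
  idx <- .BASE_IDX[chars[s:(s + L - 1L)]]
  pr <- pwm_obj$probs[cbind(seq_len(L), idx)] + pseudocount
  sum(log2(pr / pwm_obj$background[idx]))
}

## best placement covering position `offset`, over both strands
.pwm_best <- function(context, offset, pwm_obj, pseudocount) {
  chars <- strsplit(context, "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(.BASE_IDX))) {
    stop("context contains non-ACGT characters")
  }
  n <- length(chars)
  L <- nrow(pwm_obj$probs)
  s_min <- max(1L, offset - L + 1L)
  s_max <- min(offset, n - L + 1L)
  if (s_min > s_max) stop("context too short for motif placements covering the variant")
  rc_chars <- strsplit(.revcomp(context), "", fixed = TRUE)[[1]]
  best <- -Inf; best_off <- NA_integer_; best_strand <- NA_character_
  for (s in s_min:s_max) {
    sc <- .score_window(chars, s, pwm_obj, pseudocount)
    if (sc > best) { best <- sc; best_off <- s; best_strand <- "+" }
    ## minus strand: the same genomic window read on the reverse complement
    s_rc <- n - (s + L - 1L) + 1L
    sc_rc <- .score_window(rc_chars, s_rc, pwm_obj, pseudocount)
    if (sc_rc > best) { best <- sc_rc; best_off <- s; best_strand <- "-" }
  }
  list(score = best, offset = best_off, strand = best_strand)
}

#' Score an allele against a PWM
#'
#' Substitutes `allele` at `offset` (1-based within the context), then
#' maximises the log2-odds score (motif probabilities vs background) over
#' every motif placement whose window covers the variant position and over
#' both strands.
#'
#' @param context DNA context string (A/C/G/T only).
#' @param offset 1-based position of the variant within `context`.
#' @param allele Single base to substitute.
#' @param pwm_obj A `pwm` object.
#' @param pseudocount Added to each looked-up probability before the
#'   log-ratio (default 0; set small positive to guard zero cells).
#' @return Best score in bits (numeric scalar).
#' @export
score_allele_against_pwm <- function(context, offset, allele, pwm_obj,
                                     pseudocount = 0) {
  stopifnot(inherits(pwm_obj, "pwm"), nchar(allele) == 1L)
  ctx <- sub_base(context, offset, allele)
  .pwm_best(ctx, offset, pwm_obj, pseudocount)$score
}

## substitute one base in a string
sub_base <- function(s, at, base) {
  stopifnot(at >= 1L, at <= nchar(s))
  paste0(substr(s, 1L, at - 1L), base, substr(s, at + 1L, nchar(s)))
}

#' Reference vs alternate allele motif scores
#'
#' For each variant context and each PWM, computes the best reference-allele
#' and alternate-allele scores (maximised independently over placements and
#' strands, so the two maxima may sit at different offsets) and their
#' difference `delta = alt - ref`. `delta < 0` predicts decreased binding
#' affinity for the alternate allele; `delta > 0` increased.
#'
#' @param contexts data.table with `rsid`, `context`, `offset`, `ref`, `alt`
#'   (see [extract_variant_contexts()]).
#' @param pwms Named list of `pwm` objects.
#' @param pseudocount Passed to the scorer (default 0).
#' @return data.table of motif hits: `rsid`, `motif_name`, `ref_score`,
#'   `alt_score`, `delta`, offsets/strands of each per-allele maximum.
#' @export
motif_delta <- function(contexts, pwms, pseudocount = 0) {
  ctx <- data.table::as.data.table(contexts)
  acc <- vector("list", 0L)
  for (i in seq_len(nrow(ctx))) {
    for (p in pwms) {
      refb <- .pwm_best(sub_base(ctx$context[i], ctx$offset[i], ctx$ref[i]),
                        ctx$offset[i], p, pseudocount)
      altb <- .pwm_best(sub_base(ctx$context[i], ctx$offset[i], ctx$alt[i]),
                        ctx$offset[i], p, pseudocount)
      acc[[length(acc) + 1L]] <- data.table::data.table(
        rsid = ctx$rsid[i], motif_name = p$motif_name,
        ref_score = refb$score, alt_score = altb$score,
        delta = altb$score - refb$score,
        ref_offset = refb$offset, ref_strand = refb$strand,
        alt_offset = altb$offset, alt_strand = altb$strand)
    }
  }
  if (!length(acc)) {
    return(data.table::data.table(rsid = character(0), motif_name = character(0),
                                  ref_score = numeric(0), alt_score = numeric(0),
                                  delta = numeric(0), ref_offset = integer(0),
                                  ref_strand = character(0),
                                  alt_offset = integer(0),
                                  alt_strand = character(0)))
  }
  data.table::rbindlist(acc)
}

#' Extract flanking sequence contexts for variants
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param variants Variant table (`rsid`, `chrom`, `pos`, `ref`, `alt`).
#' @param flank Bases of flank on each side (default 14).
#' @return data.table `rsid`, `context`, `offset` (variant position within
#'   the context, 1-based), `ref`, `alt`.
#' @export
extract_variant_contexts <- function(genome, variants, flank = 14L) {
  v <- data.table::as.data.table(variants)
  out <- v[, {
    len <- Biostrings::width(genome[chrom])
    lo <- pmax(1L, pos - flank)
    hi <- pmin(len, pos + flank)
    ctx <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
    .(context = ctx, offset = pos - lo + 1L)
  }, by = .(rsid, chrom, pos, ref, alt)]
  bad <- out[substr(context, offset, offset) != ref]
  if (nrow(bad)) {
    stop("reference allele mismatch for: ", paste(bad$rsid, collapse = ", "))
  }
  out[, .(rsid, context, offset, ref, alt)]
}

#' Pairwise linkage disequilibrium from a phased haplotype panel
#'
#' For loci A, B with allele-1 frequencies pA, pB and joint frequency pAB:
#' D = pAB - pA*pB; r^2 = D^2 / (pA(1-pA) pB(1-pB)); D' = |D| / Dmax, where
#' Dmax = min(pA(1-pB), (1-pA)pB) for D > 0 and min(pA pB, (1-pA)(1-pB)) for
#' D < 0; D = 0 gives D' = 0.
#'
#' @param haplotypes Binary matrix (rows = haplotypes, columns = variants,
#'   colnames = rsIDs); no missing values.
#' @param rsids Variants to include (default all columns).
#' @return data.table of all unordered pairs (including the diagonal):
#'   `rsid_a`, `rsid_b`, `d`, `r2`, `d_prime`.
#' @export
ld_matrix <- function(haplotypes, rsids = colnames(haplotypes)) {
  stopifnot(is.matrix(haplotypes), !is.null(colnames(haplotypes)))
  if (any(is.na(haplotypes)) || !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype panel must be binary with no missing values")
  }
  miss <- setdiff(rsids, colnames(haplotypes))
  if (length(miss)) stop("variants absent from panel: ", paste(miss, collapse = ", "))
  h <- haplotypes[, rsids, drop = FALSE]
  freqs <- colMeans(h)
  mono <- rsids[freqs == 0 | freqs == 1]
  if (length(mono)) stop("monomorphic variant(s): ", paste(mono, collapse = ", "))
  k <- length(rsids)
  acc <- vector("list", 0L)
  for (i in seq_len(k)) {
    for (j in i:k) {
      pA <- freqs[i]; pB <- freqs[j]
      pAB <- mean(h[, i] == 1L & h[, j] == 1L)
      D <- pAB - pA * pB
      r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
      dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
              else min(pA * pB, (1 - pA) * (1 - pB))
      dprime <- if (D == 0) 0 else abs(D) / dmax
      acc[[length(acc) + 1L]] <- data.table::data.table(
        rsid_a = rsids[i], rsid_b = rsids[j], d = D, r2 = r2,
        d_prime = dprime)
    }
  }
  data.table::rbindlist(acc)
}
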