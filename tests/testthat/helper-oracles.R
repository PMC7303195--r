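## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (and Biostrings) so that agreement is evidence.

## position-by-position scan for all (overlapping) site occurrences,
## then interval split - the digestion oracle
oracle_digest <- function(seq, site, cut_offset) {
  n <- nchar(seq)
  L <- nchar(site)
  r <- charToRaw(seq)
  s <- charToRaw(site)
  if (n < L) {
    hits <- integer(0)
  } else {
    ok <- rep(TRUE, n - L + 1L)
    for (k in seq_len(L)) {
      ok <- ok & (r[k:(n - L + k)] == s[k])
    }
    hits <- which(ok) - 1L                     # 0-based site starts
  }
  cuts <- sort(unique(hits + cut_offset))
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < n], n))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

## literal evaluation of q_(i) = min_{j >= i} m p_(j) / j, mapped back
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

## brute-force triple join: contacts x variant fragments x gene overlaps
oracle_spatial_pairs <- function(variants, contacts, fragments, genes_df,
                                 min_libraries = 1L) {
  out <- list()
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    if (is.na(v$fragment_index)) next
    for (ci in seq_len(nrow(contacts))) {
      ct <- contacts[ci, ]
      partner <- NULL
      if (ct$chrom_a == v$chrom && ct$frag_a == v$fragment_index) {
        partner <- c(ct$chrom_b, ct$frag_b)
      } else if (ct$chrom_b == v$chrom && ct$frag_b == v$fragment_index) {
        partner <- c(ct$chrom_a, ct$frag_a)
      }
      if (is.null(partner)) next
      if (partner[1] == v$chrom && as.integer(partner[2]) == v$fragment_index) next
      fr <- fragments[fragments$chrom == partner[1] &
                        fragments$index == as.integer(partner[2]), ]
      for (gi in seq_len(nrow(genes_df))) {
        g <- genes_df[gi, ]
        if (g$chrom == fr$chrom && fr$start < g$end && fr$end > g$start - 1) {
          out[[length(out) + 1L]] <- data.frame(
            rsid = v$rsid, gene_id = g$gene_id, library_id = ct$library_id,
            rec = ci)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(rsid = character(0), gene_id = character(0),
                      n_libraries = integer(0), n_contacts = integer(0)))
  }
  df <- do.call(rbind, out)
  key <- paste(df$rsid, df$gene_id, sep = "\r")
  agg <- do.call(rbind, lapply(split(df, key), function(grp) {
    data.frame(rsid = grp$rsid[1], gene_id = grp$gene_id[1],
               n_libraries = length(unique(grp$library_id)),
               n_contacts = length(unique(grp$rec)))
  }))
  agg <- agg[agg$n_libraries >= min_libraries, ]
  agg <- agg[order(agg$rsid, agg$gene_id), ]
  rownames(agg) <- NULL
  agg
}

## exhaustive hypergeometric upper tail by enumerating all draws (N <= 12)
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_term <- seq_len(K)                        # wlog first K are the term
  hits <- apply(draws, 2L, function(d) sum(d %in% in_term))
  mean(hits >= k)
}

## a tiny hand-built world shared by several tests:
## chr: one 60 bp sequence digested by MboI
tiny_world <- function() {
  seq <- paste0("TTTTGATCAAAA",        # cut at 4
                "CCCCGATCGGGG",        # cut at 16
                "TTTTTTTTTTTT",
                "AAAAGATCTTTT",        # cut at 40
                "GGGGCCCCAAAA")
  genome <- c(chrT = seq)
  frags <- digest_genome(genome, "MboI")
  ## gene over [41, 55] 1-based (0-based [40,55)) on the last fragment
  genes <- gene_models(data.frame(
    gene_id = c("G1", "G1", "G2"), name = c("G1", "G1", "G2"),
    chrom = "chrT", start = c(41L, 44L, 6L), end = c(55L, 50L, 14L),
    strand = "+", feature = c("gene", "exon", "gene"),
    coding = c(TRUE, TRUE, FALSE)))
  variants <- data.frame(rsid = c("rsA", "rsB"), chrom = "chrT",
                         pos = c(2L, 20L),
                         ref = c("T", "C"), alt = c("A", "A"))
  list(genome = genome, fragments = frags, genes = genes,
       variants = variants)
}
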