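## In-silico restriction digestion and variant placement.
## All internal intervals are 0-based half-open; variant positions are 1-based.

#' Built-in restriction enzyme registry
#'
#' MboI cuts `^GATC` (blunt offset 0); HindIII cuts `A^AGCTT` (offset 1).
#' User-defined enzymes may be added as `list(site = , cut_offset = )`.
#'
#' @return Named list of enzyme definitions.
#' @export
restriction_enzymes <- function() {
  list(
    MboI    = list(name = "MboI",    site = "GATC",   cut_offset = 0L),
    HindIII = list(name = "HindIII", site = "AAGCTT", cut_offset = 1L)
  )
}

#' Look up a restriction enzyme by name
#'
#' @param name Enzyme name.
#' @param registry Enzyme registry; defaults to [restriction_enzymes()].
#' @return Enzyme definition list (`name`, `site`, `cut_offset`).
#' @export
get_enzyme <- function(name, registry = restriction_enzymes()) {
  enz <- registry[[name]]
  if (is.null(enz)) stop("unknown restriction enzyme: ", name)
  stopifnot(nchar(enz$site) >= 1L,
            enz$cut_offset >= 0L, enz$cut_offset <= nchar(enz$site))
  enz$name <- name
  enz
}

#' Digest a genome into restriction fragments
#'
#' Scans every chromosome for all (including overlapping) occurrences of the
#' enzyme recognition site; each occurrence contributes one cut at
#' `site_start + cut_offset` (0-based). Fragments are the intervals between
#' consecutive cuts plus the leading/trailing intervals; zero-length
#' intervals arising from cuts at position 0 or the sequence end are dropped.
#' Per chromosome the fragments are disjoint, contiguous and cover
#' `[0, chromosome length)`.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector over
#'   A/C/G/T.
#' @param enzyme Enzyme definition (see [get_enzyme()]) or enzyme name.
#' @return data.table with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `index` (0-based ordinal along the chromosome).
#' @examples
#' frags <- digest_genome(c(chrX = "AAGATCCGATCTT"), "MboI")
#' frags  # fragments [0,2), [2,7), [7,13)
#' @export
digest_genome <- function(genome, enzyme = "MboI") {
  if (is.character(enzyme)) enzyme <- get_enzyme(enzyme)
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome sequences must be named")
  }
  if (any(Biostrings::width(genome) == 0L)) stop("empty sequence in genome")
  site <- Biostrings::DNAString(enzyme$site)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    seq_i <- genome[[i]]
    len <- length(seq_i)
    ## matchPattern reports all occurrences, overlapping included
    hits <- Biostrings::start(Biostrings::matchPattern(site, seq_i)) - 1L
    cuts <- sort(unique(hits + enzyme$cut_offset))
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < len], len))
    out[[i]] <- data.table::data.table(
      chrom = names(genome)[i],
      start = bounds[-length(bounds)],
      end   = bounds[-1L]
    )
  }
  frags <- data.table::rbindlist(out)
  frags[, index := seq_len(.N) - 1L, by = chrom]
  data.table::setkey(frags, chrom, start)
  frags[]
}

#' Assign variants to restriction fragments
#'
#' A variant with 1-based position `p` maps to the fragment whose half-open
#' interval contains `p - 1`; a variant at a cut coordinate therefore belongs
#' to the downstream fragment. Variants on chromosomes absent from the
#' fragment table are left unassigned (`NA`) and reported in the
#' `unmapped` attribute rather than raising an error.
#'
#' @param variants Variant data.table (`rsid`, `chrom`, `pos`, ...).
#' @param fragments Fragment table from [digest_genome()].
#' @return `variants` with a `fragment_index` column; attribute `unmapped`
#'   lists rsIDs that could not be placed.
#' @export
assign_variants_to_fragments <- function(variants, fragments) {
  v <- data.table::copy(data.table::as.data.table(variants))
  v[, fragment_index := NA_integer_]
  for (ch in unique(v$chrom)) {
    fr <- fragments[chrom == ch][order(start)]
    if (!nrow(fr)) next
    idx <- v$chrom == ch
    pos0 <- v$pos[idx] - 1L
    if (any(pos0 < 0L | pos0 >= max(fr$end))) {
      stop("variant position outside chromosome ", ch)
    }
    k <- findInterval(pos0, fr$start)
    v$fragment_index[idx] <- fr$index[k]
  }
  unmapped <- v$rsid[is.na(v$fragment_index)]
  data.table::setattr(v, "unmapped", unmapped)
  v[]
}

## category precedence, highest first
.category_rank <- c(exonic = 1, UTR5 = 2, UTR3 = 2, intronic = 3,
                    ncRNA_intronic = 3, upstream = 4, downstream = 4,
                    intergenic = 5)

#' Functionally annotate variants against gene models
#'
#' Assigns each variant one category from `exonic`, `UTR5`, `UTR3`,
#' `intronic`, `ncRNA_intronic`, `upstream`, `downstream`, `intergenic`,
#' with precedence exonic > UTR > intronic (ncRNA_intronic for non-coding
#' host genes) > upstream/downstream (within `upstream_window` of the gene,
#' strand-aware) > intergenic. Ties across overlapping genes resolve to the
#' highest-precedence category; for the flanking tier the nearest gene wins,
#' with upstream preferred on exact distance ties.
#'
#' @param variants Variant data.table.
#' @param gm A `gene_models` object.
#' @param upstream_window Flanking window in bp (default 1000).
#' @return `variants` with a `category` column.
#' @export
annotate_variants <- function(variants, gm, upstream_window = 1000L) {
  v <- data.table::copy(data.table::as.data.table(variants))
  genes <- gene_table(gm)
  feats <- gm[feature != "gene"]
  v[, category := vapply(seq_len(.N), function(i) {
    .annotate_one(v$chrom[i], v$pos[i], genes, feats, upstream_window)
  }, character(1))]
  v[]
}

.annotate_one <- function(ch, pos, genes, feats, window) {
  g <- genes[chrom == ch]
  if (!nrow(g)) return("intergenic")
  inside <- g[pos >= start & pos <= end]
  cats <- character(0)
  if (nrow(inside)) {
    for (j in seq_len(nrow(inside))) {
      f <- feats[gene_id == inside$gene_id[j] & pos >= start & pos <= end]
      cat_j <- if ("exon" %in% f$feature) {
        "exonic"
      } else if ("UTR5" %in% f$feature) {
        "UTR5"
      } else if ("UTR3" %in% f$feature) {
        "UTR3"
      } else if (isTRUE(inside$coding[j])) "intronic" else "ncRNA_intronic"
      cats <- c(cats, cat_j)
    }
    return(cats[which.min(.category_rank[cats])])
  }
  ## flanking tier: distance to gene body, strand-aware side
  d_start <- g$start - pos
  d_end <- pos - g$end
  before <- d_start > 0 & d_start <= window   # variant 5' of gene in + coords
  after <- d_end > 0 & d_end <= window
  side <- data.table::fifelse(
    before, data.table::fifelse(g$strand == "+", "upstream", "downstream"),
    data.table::fifelse(after,
      data.table::fifelse(g$strand == "+", "downstream", "upstream"),
      NA_character_))
  dist <- data.table::fifelse(before, d_start,
                              data.table::fifelse(after, d_end, NA_integer_))
  ok <- !is.na(side)
  if (!any(ok)) return("intergenic")
  cand <- data.table::data.table(side = side[ok], dist = dist[ok])
  cand <- cand[order(dist, side != "upstream")]
  cand$side[1L]
}
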