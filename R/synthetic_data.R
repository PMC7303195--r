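## Synthetic pipeline inputs with planted ground truth, plus the packaged
## ADH interaction fixture. Every artifact draws from its own RNG substream
## derived from the master seed, so adding one artifact never perturbs the
## others.

#' Synthetic study configuration
#'
#' Defaults describe the shipped desk-scale world: 2 chromosomes of 100 kb
#' digested with MboI (~1 cut per 256 bp, hence hundreds of fragments per
#' chromosome), 10 genes, 20 variants, 5 tissues, 4 Hi-C libraries, three
#' planted (variant, gene, tissue, slope) regulatory links, background
#' contact rate 1e-3 per fragment pair, uniform(0,1) null p-values and a
#' 100-haplotype panel.
#'
#' @param seed Master seed (integer).
#' @param n_chromosomes,chrom_length Genome shape; `chrom_length` must be at
#'   least 10 expected fragment lengths.
#' @param enzyme_name Restriction enzyme (see [restriction_enzymes()]).
#' @param n_genes,n_variants,n_tissues,n_libraries World sizes.
#' @param planted_links data.frame (`variant`, `gene`, `tissue`, `slope`):
#'   1-based variant/gene/tissue indices and the nonzero planted slope.
#' @param background_contact_rate Per-fragment-pair Bernoulli rate of
#'   background contacts, in [0, 1].
#' @param n_decoy_pairs Non-spatial (variant, gene) pairs added to the eQTL
#'   table with null associations, exercising the spatial-pair filter.
#' @param planted_marks data.frame (`variant`, `tissue`, `mark`) of histone
#'   marks planted over variants.
#' @param planted_ld_blocks list of integer vectors (variant indices); each
#'   block's haplotype columns are duplicated, giving within-block r^2 = 1.
#' @param planted_motif_disruptions data.frame (`variant`, `motif`, `sign`)
#'   with sign "+"/"-": the sign the PWM delta (alt - ref) must take.
#' @param n_haplotypes Haplotype panel depth.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_length = 100000L,
                             enzyme_name = "MboI",
                             n_genes = 10L,
                             n_variants = 20L,
                             n_tissues = 5L,
                             n_libraries = 4L,
                             planted_links = data.frame(
                               variant = c(1L, 2L, 3L),
                               gene = c(1L, 2L, 3L),
                               tissue = c(1L, 2L, 1L),
                               slope = c(0.8, -0.7, 0.5)),
                             background_contact_rate = 1e-3,
                             n_decoy_pairs = 2L,
                             planted_marks = data.frame(
                               variant = c(1L, 1L, 2L),
                               tissue = c("tissue_1", "tissue_1", "tissue_2"),
                               mark = c("H3K27ac", "H3K4me3", "H3K4me1")),
                             planted_ld_blocks = list(1:3),
                             planted_motif_disruptions = data.frame(
                               variant = c(1L, 2L),
                               motif = c("motif_down", "motif_up"),
                               sign = c("-", "+")),
                             n_haplotypes = 100L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), enzyme_name = enzyme_name,
              n_genes = as.integer(n_genes), n_variants = as.integer(n_variants),
              n_tissues = as.integer(n_tissues), n_libraries = as.integer(n_libraries),
              planted_links = data.table::as.data.table(planted_links),
              background_contact_rate = background_contact_rate,
              n_decoy_pairs = as.integer(n_decoy_pairs),
              planted_marks = data.table::as.data.table(planted_marks),
              planted_ld_blocks = planted_ld_blocks,
              planted_motif_disruptions =
                data.table::as.data.table(planted_motif_disruptions),
              n_haplotypes = as.integer(n_haplotypes))
  enz <- get_enzyme(cfg$enzyme_name)
  expected_fraglen <- 4^nchar(enz$site)
  if (cfg$chrom_length < 10 * expected_fraglen) {
    stop("chrom_length must be >= 10 expected fragment lengths (",
         10 * expected_fraglen, " bp for ", cfg$enzyme_name, ")")
  }
  if (nrow(cfg$planted_links)) {
    stopifnot(all(cfg$planted_links$slope != 0),
              all(cfg$planted_links$variant >= 1L),
              all(cfg$planted_links$variant <= cfg$n_variants),
              all(cfg$planted_links$gene >= 1L),
              all(cfg$planted_links$gene <= cfg$n_genes),
              all(cfg$planted_links$tissue >= 1L),
              all(cfg$planted_links$tissue <= cfg$n_tissues))
  }
  stopifnot(cfg$background_contact_rate >= 0, cfg$background_contact_rate <= 1,
            cfg$n_chromosomes >= 1L, cfg$n_genes >= 1L, cfg$n_variants >= 1L,
            cfg$n_tissues >= 1L, cfg$n_libraries >= 1L, cfg$n_haplotypes >= 2L)
  structure(cfg, class = "synthetic_config")
}

## deterministic per-artifact RNG substream: label hashed into [0, 2^31-2]
substream_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

.tissue_names <- function(n) sprintf("tissue_%d", seq_len(n))

#' Generate a toy genome with gene models and variants
#'
#' Draws iid A/C/G/T chromosomes (the configured enzyme site occurs at its
#' natural density; sites are injected at regular spacing if a chromosome
#' would digest into fewer than 20 fragments), places non-overlapping
#' multi-exon genes round-robin across chromosomes (one designated
#' non-coding), and places variants at distinct intergenic-or-genic
#' positions with `ref` equal to the reference base. Variants referenced by
#' planted links are placed on the same chromosome as, but outside of, the
#' fragment(s) spanning their target gene, so that spatial support must come
#' from a contact.
#'
#' @param config A `synthetic_config`.
#' @return list: `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (`gene_models`), `variants` (data.table).
#' @export
generate_toy_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  enz <- get_enzyme(config$enzyme_name)
  genome <- with_substream(config$seed, "genome", {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                        replace = TRUE), collapse = "")
      ## guarantee >= 20 fragments: inject sites at regular spacing if sparse
      n_sites <- length(gregexpr(enz$site, s, fixed = TRUE)[[1]])
      if (n_sites < 20L) {
        step <- config$chrom_length %/% 25L
        for (at in seq(step, by = step, length.out = 24L)) {
          s <- paste0(substr(s, 1L, at - 1L), enz$site,
                      substr(s, at + nchar(enz$site), nchar(s)))
        }
      }
      s
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs,
      sprintf("chr%d", seq_len(config$n_chromosomes))))
  })
  chroms <- names(genome)

  genes <- with_substream(config$seed, "genes", {
    rows <- vector("list", 0L)
    ## per-chromosome non-overlapping slots
    per_chrom <- table(factor(rep(chroms, length.out = config$n_genes),
                              levels = chroms))
    gi <- 0L
    for (ch in chroms) {
      ng <- per_chrom[[ch]]
      if (ng == 0L) next
      slot <- config$chrom_length %/% (ng + 1L)
      for (k in seq_len(ng)) {
        gi <- gi + 1L
        glen <- sample(2000:min(6000L, slot - 200L), 1L)
        gstart <- (k - 1L) * slot + sample(100:(slot - glen - 100L), 1L)
        gend <- gstart + glen - 1L
        strand <- sample(c("+", "-"), 1L)
        gene_id <- sprintf("GENE%03d", gi)
        coding <- gi != config$n_genes || config$n_genes == 1L
        rows[[length(rows) + 1L]] <- data.table::data.table(
          gene_id = gene_id, name = gene_id, chrom = ch,
          start = gstart, end = gend, strand = strand,
          feature = "gene", coding = coding,
          pli = round(stats::runif(1L), 3))
        ## 2-3 exons inside the gene body
        n_ex <- sample(2:3, 1L)
        bounds <- sort(sample(seq(gstart + 50L, gend - 50L), 2L * n_ex))
        for (e in seq_len(n_ex)) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            gene_id = gene_id, name = gene_id, chrom = ch,
            start = bounds[2L * e - 1L], end = bounds[2L * e],
            strand = strand, feature = "exon", coding = coding, pli = NA_real_)
        }
      }
    }
    gene_models(data.table::rbindlist(rows))
  })

  gtab <- gene_table(genes)
  fragments <- digest_genome(genome, enz)
  variants <- with_substream(config$seed, "variants", {
    planted_v <- sort(unique(config$planted_links$variant))
    pos <- integer(config$n_variants)
    chrom <- character(config$n_variants)
    taken <- list()
    for (i in seq_len(config$n_variants)) {
      if (i %in% planted_v) {
        ## same chromosome as the (first) target gene, outside the fragments
        ## spanning the gene body, so pairing requires a real contact
        g <- gtab[config$planted_links[variant == i]$gene[1L]]
        fr <- fragments[chrom == g$chrom]
        gene_frags <- fr[start < g$end & end > (g$start - 1L)]
        repeat {
          p <- sample.int(config$chrom_length, 1L)
          in_gene_frag <- any(p - 1L >= gene_frags$start & p - 1L < gene_frags$end)
          if (!in_gene_frag && !p %in% unlist(taken)) break
        }
        chrom[i] <- g$chrom
      } else {
        repeat {
          chrom[i] <- sample(chroms, 1L)
          p <- sample.int(config$chrom_length, 1L)
          if (!p %in% unlist(taken)) break
        }
      }
      pos[i] <- p
      taken[[length(taken) + 1L]] <- p
    }
    ref <- vapply(seq_len(config$n_variants), function(i) {
      as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i], pos[i]))
    }, character(1))
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1))
    data.table::data.table(
      rsid = sprintf("rs%06d", seq_len(config$n_variants)),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt))
  })
  list(genome = genome, genes = genes, variants = variants)
}

#' Generate Hi-C contact records and the ground-truth manifest
#'
#' Every planted (variant, gene) link receives one contact pairing the
#' variant's fragment with a fragment overlapping the gene body (libraries
#' assigned round-robin); background contacts are Bernoulli draws over all
#' unordered fragment pairs at `background_contact_rate`, with uniformly
#' assigned libraries.
#'
#' @param fragments Fragment table for the toy genome.
#' @param toy Output of [generate_toy_genome()].
#' @param config The `synthetic_config`.
#' @return list: `contacts` (data.table), `manifest` (ground truth: planted
#'   spatial pairs, planted significant eQTL triples, LD blocks, motif
#'   disruptions).
#' @export
generate_hic_contacts <- function(fragments, toy, config) {
  stopifnot(inherits(config, "synthetic_config"))
  v <- assign_variants_to_fragments(toy$variants, fragments)
  gtab <- gene_table(toy$genes)
  links <- config$planted_links
  tiss <- .tissue_names(config$n_tissues)
  planted <- vector("list", 0L)
  if (nrow(links)) {
    for (i in seq_len(nrow(links))) {
      vi <- v[links$variant[i]]
      g <- gtab[links$gene[i]]
      if (!nrow(vi) || !nrow(g)) stop("planted link references unknown variant/gene")
      fr <- fragments[chrom == g$chrom]
      gene_frags <- fr[start < g$end & end > (g$start - 1L)]
      cand <- gene_frags[!(chrom == vi$chrom & index == vi$fragment_index)]
      if (!nrow(cand)) stop("no gene fragment distinct from the variant fragment")
      gf <- cand[1L]
      planted[[length(planted) + 1L]] <- data.table::data.table(
        library_id = sprintf("lib%d", ((i - 1L) %% config$n_libraries) + 1L),
        chrom_a = vi$chrom, frag_a = vi$fragment_index,
        chrom_b = gf$chrom, frag_b = gf$index)
    }
  }
  background <- with_substream(config$seed, "contacts", {
    glob <- data.table::copy(fragments)[, gid := .I]
    nf <- nrow(glob)
    npairs <- nf * (nf - 1) / 2
    k <- stats::rbinom(1L, size = npairs, prob = config$background_contact_rate)
    if (k == 0L) {
      data.table::data.table(library_id = character(0), chrom_a = character(0),
                             frag_a = integer(0), chrom_b = character(0),
                             frag_b = integer(0))
    } else {
      sel <- sample(npairs, k)
      ## unrank the condensed pair index into (i < j) over 1..nf
      s0 <- sel - 1
      i0 <- nf - 2 - floor(sqrt(-8 * s0 + 4 * nf * (nf - 1) - 7) / 2 - 0.5)
      j0 <- s0 + i0 + 1 - nf * (nf - 1) / 2 + (nf - i0) * ((nf - i0) - 1) / 2
      i <- as.integer(i0 + 1); j <- as.integer(j0 + 1)
      data.table::data.table(
        library_id = sprintf("lib%d", sample.int(config$n_libraries, k,
                                                 replace = TRUE)),
        chrom_a = glob$chrom[i], frag_a = glob$index[i],
        chrom_b = glob$chrom[j], frag_b = glob$index[j])
    }
  })
  contacts <- data.table::rbindlist(c(planted, list(background)),
                                    use.names = TRUE)
  manifest <- list(
    spatial_pairs = unique(data.table::data.table(
      rsid = v$rsid[links$variant], gene_id = gtab$gene_id[links$gene])),
    eqtls = data.table::data.table(
      rsid = v$rsid[links$variant], gene_id = gtab$gene_id[links$gene],
      tissue = tiss[links$tissue], slope = links$slope),
    ld_blocks = lapply(config$planted_ld_blocks,
                       function(b) v$rsid[b]),
    motif_disruptions = data.table::data.table(
      rsid = v$rsid[config$planted_motif_disruptions$variant],
      motif = config$planted_motif_disruptions$motif,
      sign = config$planted_motif_disruptions$sign)
  )
  list(contacts = contacts, manifest = manifest)
}

#' Generate the tissue-stratified eQTL association table
#'
#' Planted (variant, gene, tissue) triples receive the planted slope and a
#' p-value below 1e-6 (drawn uniformly from (1e-12, 1e-9)); every other
#' tested triple - planted spatial pairs in the remaining tissues plus decoy
#' (variant, gene) pairs - gets p ~ uniform(0, 1) and a small noise slope.
#'
#' @param manifest Ground-truth manifest from [generate_hic_contacts()].
#' @param toy Output of [generate_toy_genome()].
#' @param config The `synthetic_config`.
#' @return data.table: `tissue`, `rsid`, `gene_id`, `slope`, `pval`.
#' @export
generate_eqtl_table <- function(manifest, toy, config) {
  stopifnot(inherits(config, "synthetic_config"))
  tiss <- .tissue_names(config$n_tissues)
  gtab <- gene_table(toy$genes)
  with_substream(config$seed, "eqtl", {
    pairs <- data.table::copy(manifest$spatial_pairs)
    if (config$n_decoy_pairs > 0L) {
      cand <- data.table::CJ(rsid = toy$variants$rsid, gene_id = gtab$gene_id)
      cand <- cand[!pairs, on = c("rsid", "gene_id")]
      pairs <- rbind(pairs, cand[sample(.N, min(.N, config$n_decoy_pairs))])
    }
    grid <- pairs[, data.table::CJ(tissue = tiss), by = .(rsid, gene_id)]
    grid <- merge(grid, manifest$eqtls,
                  by = c("rsid", "gene_id", "tissue"), all.x = TRUE)
    n_null <- sum(is.na(grid$slope))
    grid[is.na(slope), `:=`(slope = stats::rnorm(n_null, 0, 0.05),
                            pval = stats::runif(n_null))]
    grid[is.na(pval), pval := stats::runif(.N, 1e-12, 1e-9)]
    out <- grid[, .(tissue, rsid, gene_id, slope, pval)]
    data.table::setorder(out, tissue, rsid, gene_id)
    out[]
  })
}

#' Generate regulatory annotation tracks
#'
#' Histone marks: each planted (variant, tissue, mark) is covered by a
#' 401 bp interval centred on the variant, plus a handful of background
#' intervals elsewhere. Haplotypes: per-variant Bernoulli columns with
#' allele-1 frequency ~ uniform(0.2, 0.8); columns inside a planted LD
#' block are duplicates of the block head, so within-block r^2 = 1. PWMs:
#' each planted motif disruption gets a 9-column matrix built from the
#' variant's reference context with the centre column favouring the
#' reference allele (sign "-") or the alternate allele (sign "+"), forcing
#' the recorded delta sign.
#'
#' @param manifest Ground-truth manifest.
#' @param toy Output of [generate_toy_genome()].
#' @param config The `synthetic_config`.
#' @return list: `marks` (data.table), `pwms` (named list of `pwm`),
#'   `haplotypes` (binary matrix).
#' @export
generate_annotation_tracks <- function(manifest, toy, config) {
  stopifnot(inherits(config, "synthetic_config"))
  v <- toy$variants
  marks <- with_substream(config$seed, "marks", {
    pm <- config$planted_marks
    rows <- vector("list", 0L)
    if (nrow(pm)) {
      for (i in seq_len(nrow(pm))) {
        vi <- v[pm$variant[i]]
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = vi$chrom, start = max(0L, vi$pos - 201L), end = vi$pos + 200L,
          tissue = pm$tissue[i], mark = pm$mark[i])
      }
    }
    for (b in seq_len(5L)) {
      ch <- sample(names(toy$genome), 1L)
      st <- sample.int(config$chrom_length - 500L, 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = ch, start = st, end = st + sample(200:500, 1L),
        tissue = sample(.tissue_names(config$n_tissues), 1L),
        mark = sample(c("H3K27ac", "H3K4me3", "H3K9me3"), 1L))
    }
    data.table::rbindlist(rows)
  })
  haplotypes <- with_substream(config$seed, "haplotypes", {
    h <- sapply(seq_len(config$n_variants), function(i) {
      f <- stats::runif(1L, 0.2, 0.8)
      col <- stats::rbinom(config$n_haplotypes, 1L, f)
      if (sum(col) == 0L) col[1L] <- 1L
      if (sum(col) == config$n_haplotypes) col[1L] <- 0L
      col
    })
    colnames(h) <- v$rsid
    for (b in config$planted_ld_blocks) {
      for (i in b[-1L]) h[, i] <- h[, b[1L]]
    }
    storage.mode(h) <- "integer"
    h
  })
  pwms <- list()
  dis <- config$planted_motif_disruptions
  if (nrow(dis)) {
    ctx <- extract_variant_contexts(toy$genome, v[dis$variant], flank = 4L)
    for (i in seq_len(nrow(dis))) {
      chars <- strsplit(ctx$context[i], "", fixed = TRUE)[[1]]
      centre <- ctx$offset[i]
      favoured <- chars
      if (dis$sign[i] == "+") favoured[centre] <- ctx$alt[i]
      probs <- t(vapply(favoured, function(b) {
        p <- rep(0.05, 4); p[.BASE_IDX[b]] <- 0.85; p
      }, numeric(4)))
      pwms[[dis$motif[i]]] <- pwm(dis$motif[i], probs)
    }
  }
  list(marks = marks, pwms = pwms, haplotypes = haplotypes)
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running the whole generator: genome, digestion,
#' contacts, eQTL table and annotation tracks, returned in memory together
#' with the ground-truth manifest.
#'
#' @param config A `synthetic_config` (default [synthetic_config()]).
#' @return list: `config`, `genome`, `genes`, `variants`, `fragments`,
#'   `contacts`, `eqtl_table`, `marks`, `pwms`, `haplotypes`, `manifest`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  toy <- generate_toy_genome(config)
  fragments <- digest_genome(toy$genome, config$enzyme_name)
  hic <- generate_hic_contacts(fragments, toy, config)
  eqtl_table <- generate_eqtl_table(hic$manifest, toy, config)
  tracks <- generate_annotation_tracks(hic$manifest, toy, config)
  c(list(config = config), toy,
    list(fragments = fragments, contacts = hic$contacts,
         eqtl_table = eqtl_table, manifest = hic$manifest),
    tracks)
}

#' Write a synthetic study to a directory of interchange files
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.tsv"),
    variants = file.path(dir, "variants.tsv"),
    contacts = file.path(dir, "contacts.tsv"),
    eqtl = file.path(dir, "eqtl.tsv"),
    marks = file.path(dir, "marks.tsv"),
    pwms = file.path(dir, "motifs.pwm"),
    haplotypes = file.path(dir, "haplotypes.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_genome(study$genome, paths[["genome"]])
  write_tsv(data.table::as.data.table(study$genes), paths[["genes"]])
  write_tsv(study$variants, paths[["variants"]])
  write_tsv(study$contacts, paths[["contacts"]])
  write_tsv(study$eqtl_table, paths[["eqtl"]])
  write_tsv(study$marks, paths[["marks"]])
  write_pwms(study$pwms, paths[["pwms"]])
  write_tsv(data.table::as.data.table(study$haplotypes), paths[["haplotypes"]])
  jsonlite::write_json(list(
    spatial_pairs = study$manifest$spatial_pairs,
    eqtls = study$manifest$eqtls,
    ld_blocks = study$manifest$ld_blocks,
    motif_disruptions = study$manifest$motif_disruptions),
    paths[["manifest"]], dataframe = "rows", auto_unbox = FALSE)
  invisible(paths)
}

#' Configuration for the FDR stress world
#'
#' A larger synthetic world used to measure realised false-discovery
#' proportions: 100 planted (variant, gene, tissue) links spread over 100
#' tissues, so the retrieved association family holds 10,000 records (100
#' planted, 9,900 null), with no background contacts.
#'
#' @param seed Master seed.
#' @return A `synthetic_config`.
#' @export
fdr_stress_config <- function(seed) {
  synthetic_config(
    seed = seed, n_chromosomes = 4L, chrom_length = 200000L,
    n_genes = 100L, n_variants = 100L, n_tissues = 100L,
    planted_links = data.frame(
      variant = 1:100, gene = 1:100,
      tissue = ((seq_len(100) - 1L) %% 100L) + 1L,
      slope = rep(c(0.8, -0.8), length.out = 100)),
    background_contact_rate = 0, n_decoy_pairs = 0L)
}

#' Score pipeline recovery of a synthetic study's planted truth
#'
#' Runs the in-memory pipeline (fragment assignment, contact indexing,
#' spatial pair calling, eQTL join with BH FDR) on a simulated study and
#' compares the significant set against the manifest's planted triples.
#'
#' @param study Output of [simulate_study()].
#' @param alpha FDR level (default 0.05).
#' @param min_libraries Minimum supporting libraries (default 1).
#' @return list: `sensitivity` (planted triples recovered / planted),
#'   `specificity` (true null triples not called / nulls), `fdp` (false
#'   discoveries / declared positives; 0 when nothing declared),
#'   `n_significant`, `n_tested`, and the significant table itself.
#' @export
evaluate_recovery <- function(study, alpha = 0.05, min_libraries = 1L) {
  v <- assign_variants_to_fragments(study$variants, study$fragments)
  idx <- build_contact_index(study$contacts, study$fragments)
  pairs <- spatial_snp_gene_pairs(v, idx, study$fragments, study$genes,
                                  min_libraries = min_libraries)
  res <- significant_spatial_eqtls(pairs, study$eqtl_table, v, study$genes,
                                   alpha = alpha)
  key <- function(d) paste(d$tissue, d$rsid, d$gene_id)
  planted <- key(study$manifest$eqtls)
  called <- key(res$significant)
  tested <- key(res$all)
  tp <- sum(called %in% planted)
  fp <- length(called) - tp
  n_null <- sum(!tested %in% planted)
  list(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       specificity = if (n_null) 1 - fp / n_null else NA_real_,
       fdp = if (length(called)) fp / length(called) else 0,
       n_significant = length(called), n_tested = length(tested),
       significant = res$significant)
}

#' Load the packaged ADH interaction fixture
#'
#' A transcription of the published table of significant eQTL-tissue
#' regulatory interactions for the alcohol dehydrogenase genes (ADH1A,
#' ADH1B, ADH1C, ADH4): one row per (tissue, gene, SNP) interaction with
#' its signed effect size, 119 rows over 24 tissues.
#'
#' @return data.table of interaction records (`tissue`, `gene`, `rsid`,
#'   `effect_size`), validated.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "adh_interactions_table1.tsv",
                      package = "spateqtl", mustWork = TRUE)
  rec <- data.table::fread(path, sep = "\t")
  interaction_records(rec)
}
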