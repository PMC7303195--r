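test_that("generator is deterministic in the seed and config-forced in shape", {
  cfg <- synthetic_config(seed = 1)
  a <- generate_toy_genome(cfg)
  b <- generate_toy_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$variants, b$variants)
  expect_identical(data.table::as.data.table(a$genes),
                   data.table::as.data.table(b$genes))
  expect_equal(unname(Biostrings::width(a$genome)), rep(100000L, 2L))
  expect_equal(names(a$genome), c("chr1", "chr2"))

  c2 <- generate_toy_genome(synthetic_config(seed = 2))
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("toy genome digests densely and variants carry the reference base", {
  cfg <- synthetic_config(seed = 3)
  toy <- generate_toy_genome(cfg)
  frags <- digest_genome(toy$genome, cfg$enzyme_name)
  expect_true(all(frags[, .N, by = chrom]$N >= 20L))
  for (i in seq_len(nrow(toy$variants))) {
    base <- as.character(Biostrings::subseq(
      toy$genome[[toy$variants$chrom[i]]],
      toy$variants$pos[i], toy$variants$pos[i]))
    expect_identical(base, toy$variants$ref[i])
    expect_false(toy$variants$ref[i] == toy$variants$alt[i])
  }
})

test_that("zero-noise contacts are exactly the planted ones", {
  cfg <- synthetic_config(seed = 5, background_contact_rate = 0)
  toy <- generate_toy_genome(cfg)
  frags <- digest_genome(toy$genome, cfg$enzyme_name)
  hic <- generate_hic_contacts(frags, toy, cfg)
  expect_equal(nrow(hic$contacts), nrow(cfg$planted_links))

  empty_cfg <- synthetic_config(seed = 5, background_contact_rate = 0,
                                planted_links = data.frame(
                                  variant = integer(0), gene = integer(0),
                                  tissue = integer(0), slope = numeric(0)))
  toy2 <- generate_toy_genome(empty_cfg)
  frags2 <- digest_genome(toy2$genome, empty_cfg$enzyme_name)
  hic2 <- generate_hic_contacts(frags2, toy2, empty_cfg)
  expect_equal(nrow(hic2$contacts), 0L)
})

test_that("contact counts are reproducible at fixed seed and nonzero rate", {
  cfg <- synthetic_config(seed = 11, background_contact_rate = 1e-3)
  toy <- generate_toy_genome(cfg)
  frags <- digest_genome(toy$genome, cfg$enzyme_name)
  h1 <- generate_hic_contacts(frags, toy, cfg)
  h2 <- generate_hic_contacts(frags, toy, cfg)
  expect_identical(h1$contacts, h2$contacts)
  expect_gt(nrow(h1$contacts), nrow(cfg$planted_links))
})

test_that("manifest invariants hold: planted pairs are contact-backed", {
  cfg <- synthetic_config(seed = 13)
  toy <- generate_toy_genome(cfg)
  frags <- digest_genome(toy$genome, cfg$enzyme_name)
  hic <- generate_hic_contacts(frags, toy, cfg)
  v <- assign_variants_to_fragments(toy$variants, frags)
  gtab <- gene_table(toy$genes)
  man <- hic$manifest
  ## every planted eQTL's (variant, gene) is a planted spatial pair
  expect_true(all(paste(man$eqtls$rsid, man$eqtls$gene_id) %in%
                    paste(man$spatial_pairs$rsid, man$spatial_pairs$gene_id)))
  for (i in seq_len(nrow(man$spatial_pairs))) {
    vf <- v[rsid == man$spatial_pairs$rsid[i]]
    g <- gtab[gene_id == man$spatial_pairs$gene_id[i]]
    gene_frags <- frags[chrom == g$chrom & start < g$end & end > g$start - 1L]
    hit <- hic$contacts[
      (chrom_a == vf$chrom & frag_a == vf$fragment_index &
         paste(chrom_b, frag_b) %in% paste(gene_frags$chrom, gene_frags$index)) |
      (chrom_b == vf$chrom & frag_b == vf$fragment_index &
         paste(chrom_a, frag_a) %in% paste(gene_frags$chrom, gene_frags$index))]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("eQTL table plants small p-values and the exact slopes", {
  cfg <- synthetic_config(seed = 17)
  study <- simulate_study(cfg)
  tab <- study$eqtl_table
  expect_equal(nrow(tab[pval < 1e-6]), nrow(cfg$planted_links))
  planted <- merge(tab, study$manifest$eqtls,
                   by = c("tissue", "rsid", "gene_id"))
  expect_equal(planted$slope.x, planted$slope.y)
  expect_true(any(abs(tab$slope + 0.7) < 1e-12))  # planted slope -0.7 verbatim
})

test_that("null p-values behave uniformly", {
  ## large null-only world: fraction with p < 0.05 inside the binomial 99% CI
  links <- data.frame(variant = 1L, gene = 1L, tissue = 1L, slope = 0.8)
  cfg <- synthetic_config(seed = 19, n_variants = 40L, n_genes = 10L,
                          n_tissues = 30L, planted_links = links,
                          n_decoy_pairs = 39L)
  study <- simulate_study(cfg)
  nulls <- study$eqtl_table[pval >= 1e-6]
  n <- nrow(nulls)
  expect_gte(n, 1000L)
  lo <- qbinom(0.005, n, 0.05) / n
  hi <- qbinom(0.995, n, 0.05) / n
  frac <- mean(nulls$pval < 0.05)
  expect_gte(frac, lo)
  expect_lte(frac, hi)
})

test_that("annotation tracks realise the planted ground truth", {
  cfg <- synthetic_config(seed = 23)
  study <- simulate_study(cfg)

  ## LD block of duplicated columns: pairwise r2 = 1
  block <- study$manifest$ld_blocks[[1]]
  ld <- ld_matrix(study$haplotypes, block)
  expect_true(all(abs(ld$r2 - 1) < 1e-12))
  expect_true(all(abs(ld$d_prime - 1) < 1e-12))

  ## planted histone mark is recovered by histone_overlap
  ho <- histone_overlap(study$variants, study$marks)
  v1 <- study$variants$rsid[1]
  row <- ho[rsid == v1 & tissue == "tissue_1"]
  expect_true("H3K27ac" %in% unlist(row$marks))
  expect_true(row$enhancer)

  ## planted motif-disruption signs agree with the scorer
  ctx <- extract_variant_contexts(study$genome, study$variants)
  dis <- study$manifest$motif_disruptions
  for (i in seq_len(nrow(dis))) {
    hits <- motif_delta(ctx[rsid == dis$rsid[i]],
                        study$pwms[dis$motif[i]])
    expected_sign <- if (dis$sign[i] == "-") -1 else 1
    expect_equal(sign(hits$delta), expected_sign)
  }
})

test_that("study round-trips through the interchange files", {
  cfg <- synthetic_config(seed = 29)
  study <- simulate_study(cfg)
  d <- withr::local_tempdir()
  paths <- write_study(study, d)
  expect_identical(as.character(read_genome(paths[["genome"]])),
                   as.character(study$genome))
  expect_equal(read_contacts(paths[["contacts"]]), study$contacts)
  expect_equal(read_eqtl_table(paths[["eqtl"]]), study$eqtl_table)
  hap <- read_haplotypes(paths[["haplotypes"]])
  expect_identical(unname(hap), unname(study$haplotypes))
  pw <- read_pwms(paths[["pwms"]])
  expect_equal(names(pw), names(study$pwms))
  expect_equal(pw[[1]]$probs, study$pwms[[1]]$probs, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("the packaged interaction fixture loads and matches its contract", {
  tab1 <- load_table1_fixture()
  expect_equal(nrow(tab1), 119L)
  expect_setequal(unique(tab1$gene), c("ADH1A", "ADH1B", "ADH1C", "ADH4"))
  r1 <- tab1[tissue == "Adipose Subcutaneous" & gene == "ADH1B"]
  expect_equal(r1$rsid, "rs1826907")
  expect_equal(r1$effect_size, -0.174)
  r2 <- tab1[tissue == "Small Intestine Terminal Ileum" & gene == "ADH1A" &
               rsid == "rs904092"]
  expect_equal(r2$effect_size, 0.74)
})
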