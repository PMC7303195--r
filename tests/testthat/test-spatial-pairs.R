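make_contacts <- function(...) {
  if (!...length()) {
    return(data.table::data.table(
      library_id = character(0), chrom_a = character(0), frag_a = integer(0),
      chrom_b = character(0), frag_b = integer(0)))
  }
  data.table::rbindlist(lapply(list(...), function(x) {
    data.table::data.table(library_id = x[[1]], chrom_a = x[[2]],
                           frag_a = as.integer(x[[3]]), chrom_b = x[[4]],
                           frag_b = as.integer(x[[5]]))
  }))
}

test_that("contact index is symmetric and counts library support", {
  w <- tiny_world()
  ct <- make_contacts(list("L1", "chrT", 0, "chrT", 3),
                      list("L2", "chrT", 0, "chrT", 3),
                      list("L1", "chrT", 2, "chrT", 1))
  idx <- build_contact_index(ct, w$fragments)
  a <- interacting_fragments(idx, "chrT", 0)
  expect_equal(a$p_frag, 3L)
  expect_equal(a$n_libraries, 2L)       # duplicate record in two libraries
  expect_equal(a$n_contacts, 2L)
  b <- interacting_fragments(idx, "chrT", 3)   # query the other endpoint
  expect_equal(b$p_frag, 0L)
  expect_equal(b$n_libraries, 2L)
  expect_equal(nrow(interacting_fragments(idx, "chrT", 0, min_libraries = 3)), 0L)
  expect_equal(interacting_fragments(idx, "chrT", 2)$p_frag, 1L)
})

test_that("contacts referencing unknown fragments are skipped with a warning", {
  w <- tiny_world()
  ct <- make_contacts(list("L1", "chrT", 0, "chrT", 3),
                      list("L1", "chrT", 0, "chrZ", 99))
  expect_warning(idx <- build_contact_index(ct, w$fragments), "skipped")
  expect_equal(idx$qc$n_skipped, 1L)
  expect_equal(nrow(idx$records), 1L)
})

test_that("fragment with no contacts yields an empty partner set", {
  w <- tiny_world()
  idx <- build_contact_index(make_contacts(list("L1", "chrT", 0, "chrT", 3)),
                             w$fragments)
  expect_equal(nrow(interacting_fragments(idx, "chrT", 1)), 0L)
})

test_that("fragment-gene overlap respects half-open abutment", {
  frags <- data.table::data.table(chrom = "c", start = c(100L, 200L),
                                  end = c(200L, 300L), index = 0:1)
  gm <- gene_models(data.frame(
    gene_id = c("Gin", "Gabut"), chrom = "c",
    start = c(151L, 201L), end = c(400L, 290L),   # 1-based inclusive
    strand = "+", feature = "gene", coding = TRUE))
  ov <- map_fragments_to_genes(frags, gm)
  ## gene body [150,400) overlaps [100,200); [200,290) abuts it exactly
  expect_setequal(ov[index == 0L]$gene_id, "Gin")
  expect_setequal(ov[index == 1L]$gene_id, c("Gin", "Gabut"))
})

test_that("a fragment spanning two genes returns both", {
  frags <- data.table::data.table(chrom = "c", start = 0L, end = 1000L,
                                  index = 0L)
  gm <- gene_models(data.frame(
    gene_id = c("A", "B"), chrom = "c", start = c(10L, 500L),
    end = c(100L, 900L), strand = "+", feature = "gene", coding = TRUE))
  expect_setequal(map_fragments_to_genes(frags, gm)$gene_id, c("A", "B"))
})

test_that("spatial pairs need a contact; self-containment is flag-gated", {
  w <- tiny_world()
  v <- assign_variants_to_fragments(w$variants, w$fragments)
  ## rsB sits on fragment 2; no contacts at all -> no pairs, even though
  ## fragment 1 overlaps gene G2 elsewhere
  idx0 <- build_contact_index(make_contacts(), w$fragments)
  expect_equal(nrow(spatial_snp_gene_pairs(v, idx0, w$fragments, w$genes)), 0L)

  ## put rsB's own fragment over a gene: still no pair without the flag
  vB <- data.frame(rsid = "rsG", chrom = "chrT", pos = 45L, ref = "A",
                   alt = "C")
  vB <- assign_variants_to_fragments(vB, w$fragments)
  p0 <- spatial_snp_gene_pairs(vB, idx0, w$fragments, w$genes)
  expect_equal(nrow(p0), 0L)
  p1 <- spatial_snp_gene_pairs(vB, idx0, w$fragments, w$genes,
                               include_self_fragment_pairs = TRUE)
  expect_equal(p1$gene_id, "G1")
  expect_true(p1$self_fragment)
})

test_that("libraries union across partner fragments hitting the same gene", {
  ## gene G2 spans fragments 1 and 2? (only 1) - craft two partners on G1
  frags <- data.table::data.table(chrom = "c", start = c(0L, 100L, 200L, 300L),
                                  end = c(100L, 200L, 300L, 400L), index = 0:3)
  gm <- gene_models(data.frame(
    gene_id = "G", chrom = "c", start = 150L, end = 350L, strand = "+",
    feature = "gene", coding = TRUE))
  ct <- make_contacts(list("L1", "c", 0, "c", 1),
                      list("L2", "c", 0, "c", 2),
                      list("L1", "c", 0, "c", 2))
  idx <- build_contact_index(ct, frags)
  v <- data.frame(rsid = "rsV", chrom = "c", pos = 50L, ref = "A", alt = "C",
                  fragment_index = 0L)
  p <- spatial_snp_gene_pairs(v, idx, frags, gm)
  expect_equal(nrow(p), 1L)
  expect_equal(p$gene_id, "G")
  expect_equal(p$n_libraries, 2L)
  expect_equal(p$n_contacts, 3L)
  expect_equal(unlist(p$libraries), c("L1", "L2"))
})

test_that("pair calling matches the brute-force triple join", {
  set.seed(99)
  for (rep in 1:5) {
    n_frag <- 30L
    frags <- data.table::data.table(chrom = "c",
                                    start = seq(0L, by = 100L, length.out = n_frag),
                                    end = seq(100L, by = 100L, length.out = n_frag),
                                    index = 0:(n_frag - 1L))
    genes_df <- data.frame(
      gene_id = sprintf("G%d", 1:5), chrom = "c",
      start = sort(sample.int(2500, 5)) , end = 0L, strand = "+",
      feature = "gene", coding = TRUE)
    genes_df$end <- genes_df$start + sample(50:400, 5)
    gm <- gene_models(genes_df)
    n_ct <- sample(50:300, 1)
    ct <- data.table::data.table(
      library_id = sprintf("L%d", sample.int(4, n_ct, replace = TRUE)),
      chrom_a = "c", frag_a = sample.int(n_frag, n_ct, TRUE) - 1L,
      chrom_b = "c", frag_b = sample.int(n_frag, n_ct, TRUE) - 1L)
    v <- data.frame(rsid = sprintf("rs%d", 1:6), chrom = "c",
                    pos = sample.int(n_frag * 100L, 6), ref = "A", alt = "C")
    v <- assign_variants_to_fragments(v, frags)
    idx <- build_contact_index(ct, frags)
    for (ml in c(1L, 2L)) {
      got <- spatial_snp_gene_pairs(v, idx, frags, gm, min_libraries = ml)
      exp <- oracle_spatial_pairs(as.data.frame(v), as.data.frame(ct),
                                  as.data.frame(frags), genes_df,
                                  min_libraries = ml)
      expect_equal(got$rsid, exp$rsid)
      expect_equal(got$gene_id, exp$gene_id)
      expect_equal(got$n_libraries, unname(exp$n_libraries))
      expect_equal(got$n_contacts, exp$n_contacts)
    }
    ## symmetry: swapping endpoints changes nothing
    ct_sw <- ct[, .(library_id, chrom_a = chrom_b, frag_a = frag_b,
                    chrom_b = chrom_a, frag_b = frag_a)]
    idx_sw <- build_contact_index(ct_sw, frags)
    expect_equal(
      spatial_snp_gene_pairs(v, idx_sw, frags, gm)[, .(rsid, gene_id, n_libraries, n_contacts)],
      spatial_snp_gene_pairs(v, idx, frags, gm)[, .(rsid, gene_id, n_libraries, n_contacts)])
    ## monotonicity: raising min_libraries never adds pairs
    p1 <- spatial_snp_gene_pairs(v, idx, frags, gm, min_libraries = 1L)
    p2 <- spatial_snp_gene_pairs(v, idx, frags, gm, min_libraries = 2L)
    expect_true(all(paste(p2$rsid, p2$gene_id) %in% paste(p1$rsid, p1$gene_id)))
  }
})
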