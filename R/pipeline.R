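## Pipeline orchestration: digest -> assign -> contacts -> pairs -> eQTL ->
## FDR -> classify -> annotate -> report, with provenance and stage counts.

#' Build a validated pipeline run configuration
#'
#' @param genome_fasta,genes_tsv,variants_tsv,contacts_tsv,eqtl_tsv Input
#'   paths (required).
#' @param marks_tsv,pwm_file,haplotypes_tsv Optional annotation inputs;
#'   stages depending on a missing input are skipped.
#' @param gwas_tsv Optional GWAS table with a `pval` column; when given,
#'   variants are filtered with [filter_gwas_snps()] before the pipeline.
#' @param out_dir Output directory.
#' @param enzyme Restriction enzyme name (default "MboI").
#' @param gwas_p_threshold GWAS inclusion threshold, strict `<`
#'   (default 1e-6).
#' @param fdr_alpha FDR level (default 0.05).
#' @param cis_window Cis window in bp (default 1e6).
#' @param min_libraries Minimum supporting Hi-C libraries (default 1).
#' @param upstream_window Flanking window for functional categories
#'   (default 1000).
#' @param include_self_fragment_pairs Containment-only pair calling
#'   (default FALSE).
#' @param strict_fdr Strict `q < alpha` semantics (default TRUE).
#' @param mark_grouping Histone-mark class map
#'   (default [default_mark_grouping()]).
#' @param seed Seed recorded in provenance (the pipeline itself draws no
#'   random numbers).
#' @return A `run_config` list.
#' @export
run_config <- function(genome_fasta, genes_tsv, variants_tsv, contacts_tsv,
                       eqtl_tsv, marks_tsv = NULL, pwm_file = NULL,
                       haplotypes_tsv = NULL, gwas_tsv = NULL,
                       out_dir = "spateqtl_run",
                       enzyme = "MboI", gwas_p_threshold = 1e-6,
                       fdr_alpha = 0.05, cis_window = 1e6,
                       min_libraries = 1L, upstream_window = 1000L,
                       include_self_fragment_pairs = FALSE,
                       strict_fdr = TRUE,
                       mark_grouping = default_mark_grouping(),
                       seed = 1L) {
  cfg <- list(genome_fasta = genome_fasta, genes_tsv = genes_tsv,
              variants_tsv = variants_tsv, contacts_tsv = contacts_tsv,
              eqtl_tsv = eqtl_tsv, marks_tsv = marks_tsv, pwm_file = pwm_file,
              haplotypes_tsv = haplotypes_tsv, gwas_tsv = gwas_tsv,
              out_dir = out_dir, enzyme = enzyme,
              gwas_p_threshold = gwas_p_threshold, fdr_alpha = fdr_alpha,
              cis_window = cis_window, min_libraries = as.integer(min_libraries),
              upstream_window = as.integer(upstream_window),
              include_self_fragment_pairs = include_self_fragment_pairs,
              strict_fdr = strict_fdr, mark_grouping = mark_grouping,
              seed = as.integer(seed))
  stopifnot(cfg$gwas_p_threshold > 0, cfg$gwas_p_threshold <= 1,
            cfg$fdr_alpha >= 0, cfg$fdr_alpha < 1,
            cfg$cis_window > 0, cfg$min_libraries >= 1L)
  req <- c("genome_fasta", "genes_tsv", "variants_tsv", "contacts_tsv",
           "eqtl_tsv")
  for (f in req) {
    if (!file.exists(cfg[[f]])) {
      stop("input path does not exist: ", f, " = ", cfg[[f]])
    }
  }
  for (f in c("marks_tsv", "pwm_file", "haplotypes_tsv", "gwas_tsv")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input path does not exist: ", f, " = ", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Keys match the arguments of [run_config()]; relative paths are resolved
#' against the JSON file's directory.
#'
#' @param path JSON config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("genome_fasta", "genes_tsv", "variants_tsv", "contacts_tsv",
              "eqtl_tsv", "marks_tsv", "pwm_file", "haplotypes_tsv",
              "gwas_tsv", "out_dir")) {
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(run_config, raw)
}

#' Filter GWAS SNPs by association p-value
#'
#' Keeps rows with `pval < threshold` (strict inequality) and deduplicates
#' by rsID keeping the smallest p-value.
#'
#' @param snp_table data.table with at least `rsid` and `pval`.
#' @param threshold Strict inclusion threshold (default 1e-6).
#' @return Filtered, deduplicated data.table.
#' @export
filter_gwas_snps <- function(snp_table, threshold = 1e-6) {
  dt <- data.table::as.data.table(snp_table)
  if (!"pval" %in% names(dt)) stop("GWAS table needs a 'pval' column")
  kept <- dt[pval < threshold]
  kept <- kept[order(pval)]
  unique(kept, by = "rsid")
}

.stage_fail <- function(stage, msg) {
  stop(structure(class = c("spateqtl_stage_error", "error", "condition"),
                 list(message = sprintf("[stage:%s] %s", stage, msg),
                      call = NULL, stage = stage)))
}

#' Run the full spatial eQTL pipeline
#'
#' Executes digestion, variant assignment and functional annotation,
#' contact indexing, spatial pair calling, the eQTL join with BH FDR
#' control and cis/trans classification, optional regulatory annotation
#' (histone marks, motif deltas, LD), and interaction summarisation. All
#' stage outputs are written as TSV/JSON under `config$out_dir` together
#' with a provenance manifest (config, input checksums, stage row counts).
#' The pipeline is a pure function of (config, inputs): a rerun reproduces
#' byte-identical outputs.
#'
#' @param config A `run_config`.
#' @return The output directory path, invisibly; stage results are also
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  log_info <- function(...) message(sprintf(...))

  genome <- tryCatch(read_genome(config$genome_fasta),
                     error = function(e) .stage_fail("read_genome", conditionMessage(e)))
  gm <- tryCatch(read_gene_models(config$genes_tsv),
                 error = function(e) .stage_fail("read_genes", conditionMessage(e)))
  variants <- tryCatch(read_variants(config$variants_tsv),
                       error = function(e) .stage_fail("read_variants", conditionMessage(e)))
  counts$variants_in <- nrow(variants)

  if (!is.null(config$gwas_tsv)) {
    gwas <- data.table::fread(config$gwas_tsv, sep = "\t")
    keep <- filter_gwas_snps(gwas, config$gwas_p_threshold)
    variants <- variants[rsid %in% keep$rsid]
    counts$variants_gwas_filtered <- nrow(variants)
    log_info("GWAS filter: %d -> %d SNPs (p < %g)", counts$variants_in,
             nrow(variants), config$gwas_p_threshold)
  }

  fragments <- tryCatch(digest_genome(genome, config$enzyme),
                        error = function(e) .stage_fail("digest", conditionMessage(e)))
  counts$fragments <- nrow(fragments)
  write_fragments_bed(fragments, file.path(config$out_dir, "fragments.bed"))

  variants <- assign_variants_to_fragments(variants, fragments)
  variants <- annotate_variants(variants, gm, config$upstream_window)
  counts$variants_assigned <- sum(!is.na(variants$fragment_index))
  write_tsv(variants, file.path(config$out_dir, "variants_annotated.tsv"))

  contacts <- tryCatch(read_contacts(config$contacts_tsv),
                       error = function(e) .stage_fail("read_contacts", conditionMessage(e)))
  counts$contacts <- nrow(contacts)
  index <- build_contact_index(contacts, fragments)

  pairs <- spatial_snp_gene_pairs(
    variants, index, fragments, gm,
    min_libraries = config$min_libraries,
    include_self_fragment_pairs = config$include_self_fragment_pairs)
  counts$spatial_pairs <- nrow(pairs)
  write_tsv(pairs[, .(rsid, gene_id, n_libraries, n_contacts)],
            file.path(config$out_dir, "spatial_pairs.tsv"))
  log_info("%d variants -> %d spatial SNP-gene pairs", nrow(variants),
           nrow(pairs))

  eqtl_table <- tryCatch(read_eqtl_table(config$eqtl_tsv),
                         error = function(e) .stage_fail("read_eqtl", conditionMessage(e)))
  res <- significant_spatial_eqtls(pairs, eqtl_table, variants, gm,
                                   alpha = config$fdr_alpha,
                                   window = config$cis_window,
                                   strict = config$strict_fdr)
  counts$eqtl_records <- nrow(res$all)
  counts$significant <- nrow(res$significant)
  write_tsv(res$all, file.path(config$out_dir, "eqtl_adjusted.tsv"))
  write_tsv(res$significant, file.path(config$out_dir, "eqtl_significant.tsv"))
  log_info("%d eQTL records -> %d significant (FDR %s %g)",
           counts$eqtl_records, counts$significant,
           if (config$strict_fdr) "<" else "<=", config$fdr_alpha)

  results <- list(fragments = fragments, variants = variants, pairs = pairs,
                  eqtl = res)

  sig_variants <- variants[rsid %in% res$significant$rsid]
  if (!is.null(config$marks_tsv) && nrow(sig_variants)) {
    marks <- read_marks(config$marks_tsv)
    hist <- histone_overlap(sig_variants, marks, config$mark_grouping)
    hm <- data.table::copy(hist)
    hm[, marks := vapply(marks, paste, "", collapse = ";")]
    write_tsv(hm, file.path(config$out_dir, "histone_overlap.tsv"))
    results$histone <- hist
    counts$histone_rows <- nrow(hist)
  }
  if (!is.null(config$pwm_file) && nrow(sig_variants)) {
    pwms <- read_pwms(config$pwm_file)
    ctx <- extract_variant_contexts(genome, sig_variants)
    hits <- motif_delta(ctx, pwms)
    write_tsv(hits, file.path(config$out_dir, "motif_delta.tsv"))
    results$motifs <- hits
    counts$motif_rows <- nrow(hits)
  }
  if (!is.null(config$haplotypes_tsv) && nrow(sig_variants) >= 2L) {
    hap <- read_haplotypes(config$haplotypes_tsv)
    ids <- intersect(sig_variants$rsid, colnames(hap))
    if (length(ids) >= 2L) {
      ld <- ld_matrix(hap, ids)
      write_tsv(ld, file.path(config$out_dir, "ld.tsv"))
      results$ld <- ld
      counts$ld_pairs <- nrow(ld)
    }
  }

  if (nrow(res$significant)) {
    recs <- res$significant[, .(tissue, gene = gene_id, rsid,
                                effect_size = slope)]
    summ <- summarise_interactions(recs)
    results$summary <- summ
    write_interaction_matrix(summ, file.path(config$out_dir,
                                             "interaction_matrix.tsv"))
    jsonlite::write_json(list(
      n_records = summ$n_records, n_pairs = summ$n_pairs,
      n_tissues = summ$n_tissues, n_snps = summ$n_snps,
      n_genes = summ$n_genes,
      n_cis = sum(res$significant$regulation_class == "cis"),
      n_trans = sum(res$significant$regulation_class == "trans")),
      file.path(config$out_dir, "summary.json"), auto_unbox = TRUE)
  }

  input_paths <- Filter(Negate(is.null),
                        config[c("genome_fasta", "genes_tsv", "variants_tsv",
                                 "contacts_tsv", "eqtl_tsv", "marks_tsv",
                                 "pwm_file", "haplotypes_tsv", "gwas_tsv")])
  provenance <- list(
    config = config[setdiff(names(config), "mark_grouping")],
    mark_grouping = config$mark_grouping,
    input_md5 = as.list(tools::md5sum(unlist(input_paths))),
    stage_counts = counts)
  jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null")
  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}
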