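# End-to-end orchestration over an input bundle (the layout emitted by
# generate_fixture(), which is also the documented input contract for
# real data), with per-stage TSV outputs so a run is idempotent and
# resumable: a stage whose outputs already exist is skipped unless
# `force = TRUE`.

.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

.pipeline_defaults <- list(
  seed = 1L, r2_min = 0.8, catalog_r2 = 0.1, feature_alpha = 0.05,
  null_quantile = 0.95, motif_p = 1e-4, mqtl_fdr = 0.1, cis_fdr = 0.05,
  min_qtl_datasets = 2L, min_interaction_datasets = 2L,
  min_motif_databases = 2L, pp4 = 0.8, promoter_half_width = 1000L,
  ppi = 0.9, locus_flank = 1e6)

#' Load a pipeline configuration
#'
#' Reads a YAML configuration (or accepts a list), fills in defaults for
#' every threshold, and resolves `data_dir` relative to the configuration
#' file. The thresholds and their defaults: LD expansion `r2_min` 0.8,
#' catalog exclusion `catalog_r2` 0.1, feature selection `feature_alpha`
#' 0.05 (Bonferroni over all features), `null_quantile` 0.95, `motif_p`
#' 1e-4, `mqtl_fdr` 0.1, `cis_fdr` 0.05, `min_qtl_datasets` and
#' `min_interaction_datasets` 2, `min_motif_databases` 2, `pp4` 0.8,
#' `promoter_half_width` 1000 bp, `ppi` 0.9, `locus_flank` 1 Mb.
#'
#' @param config YAML file path or a named list
#' @return validated configuration list
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    if (is.null(config$data_dir) || config$data_dir == ".")
      config$data_dir <- dir
    else if (!grepl("^/", config$data_dir))
      config$data_dir <- file.path(dir, config$data_dir)
  }
  for (k in names(.pipeline_defaults))
    config[[k]] <- config[[k]] %||% .pipeline_defaults[[k]]
  stopifnot(config$r2_min > 0, config$r2_min <= 1,
            config$null_quantile > 0, config$null_quantile < 1,
            config$promoter_half_width >= 500,
            config$promoter_half_width <= 10000)
  config
}

.cfg_mhc <- function(config) {
  if (is.null(config$mhc)) gintervals("chr6", 25e6, 35e6, "MHC")
  else gintervals(config$mhc$chrom, config$mhc$start, config$mhc$end, "MHC")
}

#' Run the full prioritization pipeline
#'
#' Executes curate, score, allelic, genes, tfnet, drugs and report in
#' order, reading the input bundle under `config$data_dir` and writing
#' per-stage TSV outputs into `out_dir`. Stages whose outputs already
#' exist are skipped (resume contract); `force = TRUE` recomputes
#' everything. Missing required inputs fail fast naming the stage and
#' file.
#'
#' @param config configuration (path or list, see [load_config()])
#' @param out_dir output directory
#' @param force recompute stages whose outputs already exist
#' @param stages subset of stage names to run (default all, in order)
#' @return invisibly, the [summarize_results()] report
#' @export
run_pipeline <- function(config, out_dir, force = FALSE,
                         stages = c("curate", "score", "allelic", "genes",
                                    "tfnet", "drugs", "report")) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dd <- function(f) {
    p <- file.path(cfg$data_dir, f)
    if (!file.exists(p)) stop("missing required input for stage: ", f)
    p
  }
  oo <- function(f) file.path(out_dir, f)
  wt <- function(x, f) utils::write.table(x, oo(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  run_stage <- function(name, outputs, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    if (!force && all(file.exists(vapply(outputs, oo, character(1))))) {
      message("[", name, "] outputs present; skipped (use force = TRUE to redo)")
      return(invisible(NULL))
    }
    message("[", name, "] running")
    fun()
  }

  run_stage("curate", c("positives.tsv", "snp_classes.tsv", "loci.bed"), function() {
    tags <- .read_tsv(dd("tags.tsv"))
    snps <- .read_tsv(dd("snps.tsv"))
    ld <- .read_tsv(dd("ld.tsv"))
    positives <- expand_tags(tags, ld, snps, r2_min = cfg$r2_min)
    locus_set <- define_loci(tags, flank = cfg$locus_flank, mhc = .cfg_mhc(cfg))
    catalog_ld <- if (file.exists(file.path(cfg$data_dir, "catalog_ld.tsv")))
      .read_tsv(dd("catalog_ld.tsv")) else NULL
    catalog <- if (file.exists(file.path(cfg$data_dir, "catalog_snps.txt")))
      readLines(dd("catalog_snps.txt")) else character(0)
    classes <- classify_snps(snps, positives, locus_set, catalog_ld, catalog,
                             r2_exclude = cfg$catalog_r2)
    wt(positives, "positives.tsv")
    wt(classes, "snp_classes.tsv")
    write_bed(locus_set$loci, oo("loci.bed"))
    message("[curate] positives: ", nrow(positives),
            "; background: ", sum(classes$snp_class == "background"),
            "; negative: ", sum(classes$snp_class == "negative"))
  })

  run_stage("score", c("enrichment.tsv", "scores.tsv", "support.tsv"), function() {
    classes <- .read_tsv(oo("snp_classes.tsv"))
    manifest <- .read_tsv(dd("feature_manifest.tsv"))
    peaks <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
      b <- read_bed(dd(manifest$bed_path[i]))
      b$label <- manifest$feature_id[i]
      b
    }))
    pos <- classes[classes$snp_class == "positive", , drop = FALSE]
    bg <- classes[classes$snp_class == "background", , drop = FALSE]
    neg <- classes[classes$snp_class == "negative", , drop = FALSE]
    ann_pos <- annotate_features(pos, peaks, manifest$feature_id)
    ann_bg <- annotate_features(bg, peaks, manifest$feature_id)
    enr <- enrich_features(ann_pos, ann_bg, manifest, alpha = cfg$feature_alpha)
    pos_scores <- score_snp_set(pos, peaks, enr)
    neg_scores <- score_snp_set(neg, peaks, enr)
    support <- epigenetic_support(pos_scores, neg_scores,
                                  quantile = cfg$null_quantile)
    wt(enr, "enrichment.tsv")
    wt(data.frame(snp_id = pos$snp_id, pos_scores), "scores.tsv")
    wt(support, "support.tsv")
    wt(data.frame(category = names(attr(support, "thresholds")),
                  threshold = as.numeric(attr(support, "thresholds"))),
       "null_thresholds.tsv")
    message("[score] selected features: ", sum(enr$selected),
            "; supported SNPs: ", sum(support$n_categories >= 1))
  })

  run_stage("allelic", c("motif_calls.tsv", "mqtl_significant.tsv",
                         "functional.tsv"), function() {
    support <- .read_tsv(oo("support.tsv"))
    positives <- .read_tsv(oo("positives.tsv"))
    snps <- .read_tsv(dd("snps.tsv"))
    pwms <- c(read_meme(dd("motifs_dbx.meme"), database = "dbx"),
              read_jaspar(dd("motifs_dby.pfm"), database = "dby"))
    expr <- .read_tsv(dd("expressed_tfs.tsv"))
    expressed <- toupper(expr$tf_name[expr$rpkm > 1])
    fl <- Biostrings::readDNAStringSet(dd("flanks.fa"))
    ps <- snps[match(positives$snp_id, snps$snp_id), , drop = FALSE]
    calls <- allelic_motif_scan(ps, fl, pwms, expressed_tfs = expressed,
                                p_threshold = cfg$motif_p)
    mqtl <- filter_molecular_qtl(.read_tsv(dd("molecular_qtl.tsv")),
                                 fdr_max = cfg$mqtl_fdr)
    functional <- prioritize_functional_snps(support, calls, mqtl)
    wt(calls, "motif_calls.tsv")
    wt(mqtl, "mqtl_significant.tsv")
    wt(functional, "functional.tsv")
    message("[allelic] retained motif calls: ", sum(calls$retained),
            "; significant molecular QTLs: ", nrow(mqtl),
            "; functional SNPs: ", sum(functional$functional))
  })

  run_stage("genes", c("cis_pairs.tsv", "coloc.tsv", "predicted_pairs.tsv",
                       "predicted_genes.tsv"), function() {
    functional <- .read_tsv(oo("functional.tsv"))
    snps <- .read_tsv(dd("snps.tsv"))
    genes <- .read_tsv(dd("genes.tsv"))
    promoters <- promoter_windows(genes, half_width = cfg$promoter_half_width)
    cis <- filter_cis_qtl(.read_tsv(dd("cis_qtl.tsv")), genes,
                          fdr_max = cfg$cis_fdr,
                          min_datasets = cfg$min_qtl_datasets)
    contacts <- .read_tsv(dd("contacts.bedpe"))
    inter <- interaction_support(cis$pairs, snps, promoters, contacts)
    cg <- .read_tsv(dd("coloc_gwas.tsv"))
    cq <- .read_tsv(dd("coloc_qtl.tsv"))
    coloc <- do.call(rbind, lapply(unique(cg$gene_id), function(g) {
      res <- coloc_abf(cg[cg$gene_id == g, ], cq[cq$gene_id == g, ])
      data.frame(gene_id = g, t(res$pp), pp4 = unname(res$pp["PP4"]),
                 nsnps = res$nsnps, stringsAsFactors = FALSE)
    })) %||% data.frame(gene_id = character(0), pp4 = numeric(0))
    pred <- predict_target_genes(functional, cis$pairs, inter, coloc,
                                 snps, promoters,
                                 min_qtl_datasets = cfg$min_qtl_datasets,
                                 min_interaction_datasets =
                                   cfg$min_interaction_datasets,
                                 pp4_min = cfg$pp4)
    wt(cis$pairs, "cis_pairs.tsv")
    wt(inter, "interactions.tsv")
    wt(coloc, "coloc.tsv")
    wt(pred$pairs, "predicted_pairs.tsv")
    wt(pred$genes, "predicted_genes.tsv")
    message("[genes] predicted pairs: ", sum(pred$pairs$predicted),
            "; predicted genes: ", nrow(pred$genes))
  })

  run_stage("tfnet", c("tf_enrichment.tsv", "tf_edges.tsv"), function() {
    pairs <- .read_tsv(oo("predicted_pairs.tsv"))
    positives <- .read_tsv(oo("positives.tsv"))
    calls <- .read_tsv(oo("motif_calls.tsv"))
    calls <- calls[calls$retained, , drop = FALSE]
    with_targets <- unique(pairs$snp_id[pairs$predicted])
    tfe <- enrich_tfs(with_targets, positives$snp_id, calls)
    map <- .read_tsv(dd("tf_gene_map.tsv"))
    edges <- assign_tf_targets(tfe$tf_name[tfe$enriched], calls,
                               pairs[pairs$predicted, , drop = FALSE], map)
    stm <- shared_target_matrix(edges)
    wt(tfe, "tf_enrichment.tsv")
    wt(edges, "tf_edges.tsv")
    write_sif(edges, oo("tf_edges.sif"))
    writeLines(stm$cover, oo("tf_cover.txt"))
    message("[tfnet] enriched TFs: ", sum(tfe$enriched),
            "; edges: ", nrow(edges))
  })

  run_stage("drugs", c("gene_tiers.tsv", "ora.tsv", "drug_records.tsv",
                       "drug_predictions.tsv"), function() {
    genes <- .read_tsv(dd("genes.tsv"))
    pred_genes <- .read_tsv(oo("predicted_genes.tsv"))
    pairs <- .read_tsv(oo("predicted_pairs.tsv"))
    positives <- .read_tsv(oo("positives.tsv"))
    fn_long <- .read_tsv(dd("gene_function.tsv"))
    tables <- split(fn_long$gene_id, fn_long$flag)
    tiers <- annotate_gene_function(pred_genes$gene_id, tables)
    pw_long <- .read_tsv(dd("pathways.tsv"))
    ora <- ora_test(pred_genes$gene_id, split(pw_long$gene_id, pw_long$pathway),
                    universe = genes$gene_id)
    drugs <- .read_tsv(dd("drugs.tsv"))
    dg_long <- .read_tsv(dd("druggability.tsv"))
    records <- build_drug_annotations(
      drugs, split(dg_long$gene_id, dg_long$resource),
      .read_tsv(dd("indication_classes.tsv")))
    # predicted genes inherit the diseases of their predicting SNPs
    pp <- pairs[pairs$predicted, , drop = FALSE]
    dis <- .split_diseases(positives$diseases[match(pp$snp_id,
                                                    positives$snp_id)])
    gene_diseases <- unique(do.call(rbind, lapply(seq_len(nrow(pp)), function(i)
      if (length(dis[[i]]) == 0L) NULL else
        data.frame(gene_id = pp$gene_id[i], disease = dis[[i]],
                   stringsAsFactors = FALSE)))) %||%
      data.frame(gene_id = character(0), disease = character(0))
    preds <- predict_new_drug_targets(gene_diseases, records, drugs,
                                      .read_tsv(dd("ppi.tsv")),
                                      ppi_min = cfg$ppi)
    wt(tiers, "gene_tiers.tsv")
    wt(ora, "ora.tsv")
    wt(records, "drug_records.tsv")
    wt(gene_diseases, "gene_diseases.tsv")
    wt(preds, "drug_predictions.tsv")
    message("[drugs] candidate drug targets: ", nrow(preds))
  })

  summary <- NULL
  run_stage("report", "summary.json", function() {
    pairs <- .read_tsv(oo("predicted_pairs.tsv"))
    genes_pred <- .read_tsv(oo("predicted_genes.tsv"))
    gene_models <- .read_tsv(dd("genes.tsv"))
    snps <- .read_tsv(dd("snps.tsv"))
    edges <- .read_tsv(oo("tf_edges.tsv"))
    drugs <- .read_tsv(oo("drug_predictions.tsv"))
    summary <<- summarize_results(pairs[pairs$predicted, , drop = FALSE],
                                  genes_pred, snps, gene_models,
                                  tf_edges = edges, drug_predictions = drugs)
    jsonlite::write_json(unclass(summary), oo("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wt(data.frame(metric = names(unlist(summary)),
                  value = unname(unlist(summary))), "summary.tsv")
  })
  invisible(summary)
}

#' Summarize prediction results
#'
#' Counts and percentages over the predicted SNP-gene pairs and genes:
#' local/distal pair and gene tallies (distal-gene percentage at 1
#' decimal, distal-pair percentage at 2 decimals, half-up rounding),
#' SNP-gene distances measured to the nearest TSS of the target gene
#' (mean in kb, and the share of distal pairs beyond 50 kb), TF target
#' coverage (predicted genes reachable by at least one enriched TF), and
#' the number of drug-target predictions. An empty gene table yields
#' `NA` percentages.
#'
#' @param pairs predicted SNP-gene pairs (`snp_id`, `gene_id`,
#'   `pair_class`)
#' @param genes predicted gene table (`gene_id`, `gene_class`)
#' @param snps SNP coordinates
#' @param gene_models gene model table (`gene_id`, `tss`)
#' @param tf_edges optional TF-gene edge table
#' @param drug_predictions optional drug-prediction table
#' @return object of class `funsnp_summary` (a named list)
#' @export
summarize_results <- function(pairs, genes, snps, gene_models,
                              tf_edges = NULL, drug_predictions = NULL) {
  n_local_p <- sum(pairs$pair_class == "local")
  n_distal_p <- sum(pairs$pair_class == "distal")
  n_local_g <- sum(genes$gene_class == "local")
  n_distal_g <- sum(genes$gene_class == "distal")
  dist_bp <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tss <- gene_models$tss[gene_models$gene_id == pairs$gene_id[i]]
    pos <- snps$pos[match(pairs$snp_id[i], snps$snp_id)]
    if (length(tss) > 0L && !is.na(pos)) dist_bp[i] <- min(abs(pos - tss))
  }
  distal_d <- dist_bp[pairs$pair_class == "distal"]
  out <- list(
    n_pairs = nrow(pairs),
    n_local_pairs = n_local_p,
    n_distal_pairs = n_distal_p,
    distal_pair_percent = percent_of(n_distal_p, nrow(pairs), 2),
    n_genes = nrow(genes),
    n_local_genes = n_local_g,
    n_distal_genes = n_distal_g,
    distal_gene_percent = percent_of(n_distal_g, n_local_g + n_distal_g, 1),
    n_exclusively_distal_genes = sum(genes$exclusively_distal %||% logical(0)),
    mean_pair_distance_kb =
      if (all(is.na(dist_bp))) NA_real_
      else round_half_up(mean(dist_bp, na.rm = TRUE) / 1000, 2),
    distal_pairs_gt50kb_percent =
      percent_of(sum(distal_d > 5e4, na.rm = TRUE),
                 sum(!is.na(distal_d)), 2),
    tf_covered_genes = NA_integer_,
    tf_coverage_percent = NA_real_,
    n_drug_predictions =
      if (is.null(drug_predictions)) NA_integer_ else nrow(drug_predictions))
  if (!is.null(tf_edges)) {
    covered <- intersect(genes$gene_id, unique(tf_edges$gene_id))
    out$tf_covered_genes <- length(covered)
    out$tf_coverage_percent <- percent_of(length(covered), nrow(genes), 2)
  }
  structure(out, class = "funsnp_summary")
}

#' @export
print.funsnp_summary <- function(x, ...) {
  cat("Prediction summary\n")
  cat(sprintf("  SNP-gene pairs: %d (local %d, distal %d; %.2f%% distal)\n",
              x$n_pairs, x$n_local_pairs, x$n_distal_pairs,
              x$distal_pair_percent))
  cat(sprintf("  target genes:   %d (local %d, distal %d; %.1f%% distal)\n",
              x$n_genes, x$n_local_genes, x$n_distal_genes,
              x$distal_gene_percent))
  cat(sprintf("  mean SNP-gene distance: %.2f kb; distal pairs > 50 kb: %.2f%%\n",
              x$mean_pair_distance_kb, x$distal_pairs_gt50kb_percent))
  if (!is.na(x$tf_coverage_percent))
    cat(sprintf("  TF-covered genes: %d (%.2f%%)\n", x$tf_covered_genes,
                x$tf_coverage_percent))
  if (!is.na(x$n_drug_predictions))
    cat(sprintf("  drug-target predictions: %d\n", x$n_drug_predictions))
  invisible(x)
}
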