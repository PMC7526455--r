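# Deterministic synthetic-data generator. Emits every input family the
# pipeline consumes (SNP tables, LD, peak BEDs, motif libraries, FASTA
# flanks, molecular/cis QTL tables, BEDPE contacts, summary statistics,
# function/drug/PPI tables) plus a machine-readable planted-truth
# manifest, so each stage and the end-to-end run are testable offline.
#
# One pseudo-random stream per output family, derived from the master
# seed by labelled sub-seeding: adding an output family never perturbs
# the draws of another.

.sub_seed <- function(master, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v) * 131) %% 1000003L
  as.integer((as.integer(master) %% 1000003L) * 1009L + h) %% 2147483L + 1L
}

.stream <- function(master, label) set.seed(.sub_seed(master, label))

#' Fixture configuration
#'
#' Defaults define the reference synthetic study: a 2 x 10 Mb genome, 20
#' tag SNPs over 3 diseases with 4 strong proxies each, 4000 background
#' and 4000 negative SNPs, 16 enriched epigenetic features (4 per
#' category, planted fold enrichment `fc_target`) among 24 nulls, 30
#' planted functional SNPs, 3 local and 6 distal planted target genes,
#' shared-causal colocalization loci (n = 5000, 60 SNPs, effect 0.6 s.d.
#' per allele), 2 enriched TFs and 2 planted drug-target triples with
#' one-rule-short decoys throughout.
#'
#' @param seed master seed; a fixed seed yields byte-identical output
#' @param ... overrides of any default listed above (see the source for
#'   the full field list)
#' @return a `funsnp_fixture_config` list
#' @export
fixture_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
    mhc = gintervals("chr2", 8e6, 9e6, "MHC"),
    diseases = c("autoimm_1", "autoimm_2", "autoimm_3"),
    n_tags = 20L,
    proxies_per_tag = 4L,
    decoy_proxies_per_tag = 2L,
    n_background = 4000L,
    n_negative = 4000L,
    n_catalog_excluded = 20L,
    enriched_per_category = 4L,
    null_per_category = 6L,
    bg_rate = 0.1,
    fc_target = 3,
    peak_halfwidth = 100L,
    n_functional = 30L,
    n_epi_only = 10L,
    n_local_genes = 3L,
    n_distal_genes = 6L,
    snps_per_distal_gene = 2L,
    n_extra_genes = 100L,
    flank_width = 41L,
    motif_length = 8L,
    coloc_n = 5000L,
    coloc_snps = 60L,
    coloc_effect = 0.6,
    promoter_half_width = 1000L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$pos_rate <- cfg$bg_rate * cfg$fc_target
  structure(cfg, class = "funsnp_fixture_config")
}

# Random SNP ids / DNA -------------------------------------------------------

.rand_bases <- function(n) sample(DNA_BASES, n, replace = TRUE)

.rand_seq <- function(len) paste(.rand_bases(len), collapse = "")

# A near-consensus PWM: probability `strength` on the consensus base.
.consensus_pwm <- function(tf, db, consensus, strength = 0.97) {
  b <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - strength) / 3, nrow = length(b), ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  mat[cbind(seq_along(b), match(b, DNA_BASES))] <- strength
  pwm(tf, db, mat, pseudocount = 0)
}

#' Simulate a colocalization scenario
#'
#' GWAS and QTL summary statistics for one locus with block-structured
#' LD (blocks of 20 SNPs, within-block correlation `0.95^|i-j|`).
#' z-scores are multivariate normal with covariance R and mean `R lambda`
#' where `lambda` places the causal non-centrality
#' `effect * sqrt(n) * sqrt(2 f (1-f))` (standardized trait, per-allele
#' effect in trait-s.d. units, allele frequency `f = 0.3`):
#' `kind = "shared"` uses one causal SNP for both traits,
#' `"distinct"` two causal SNPs in different LD blocks, and `"null"` none
#' (standard-normal z marginals).
#'
#' @param kind `"shared"`, `"distinct"` or `"null"`
#' @param n GWAS/QTL sample size
#' @param effect causal per-allele effect in trait-s.d. units
#' @param snps number of SNPs in the locus (>= 10)
#' @param seed RNG seed for this locus
#' @return list with `gwas` and `qtl` summary `data.frame`s (`snp_id`,
#'   `beta`, `se`, `p`, `n`, `freq`, `type`) and the causal indices
#' @export
generate_coloc_scenario <- function(kind = c("shared", "distinct", "null"),
                                    n = 5000L, effect = 0.6, snps = 200L,
                                    seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(snps >= 10L)
  set.seed(as.integer(seed))
  block <- 20L
  R <- matrix(0, snps, snps)
  for (s in seq(1L, snps, by = block)) {
    e <- min(s + block - 1L, snps)
    idx <- s:e
    R[idx, idx] <- 0.95^abs(outer(idx, idx, "-"))
  }
  ch <- tryCatch(chol(R), error = function(e) {
    message("LD matrix numerically singular; diagonal jitter applied")
    chol(R + diag(1e-6, snps))
  })
  f <- 0.3
  nc <- effect * sqrt(n) * sqrt(2 * f * (1 - f))
  causal_g <- causal_q <- integer(0)
  if (kind == "shared") {
    causal_g <- causal_q <- sample(snps, 1L)
  } else if (kind == "distinct") {
    blocks <- sample(seq_len(ceiling(snps / block)), 2L)
    causal_g <- (blocks[1] - 1L) * block + sample(min(block, snps - (blocks[1] - 1L) * block), 1L)
    causal_q <- (blocks[2] - 1L) * block + sample(min(block, snps - (blocks[2] - 1L) * block), 1L)
  }
  draw <- function(causal) {
    lambda <- numeric(snps)
    lambda[causal] <- nc
    mu <- as.numeric(R %*% lambda)
    mu + as.numeric(t(ch) %*% rnorm(snps))
  }
  zg <- draw(causal_g); zq <- draw(causal_q)
  se <- 1 / (sqrt(n) * sqrt(2 * f * (1 - f)))
  mk <- function(z) data.frame(
    snp_id = paste0("locsnp", seq_len(snps)), beta = z * se, se = se,
    p = 2 * stats::pnorm(-abs(z)), n = n, freq = f, type = "quant",
    stringsAsFactors = FALSE)
  list(gwas = mk(zg), qtl = mk(zq),
       causal_gwas = causal_g, causal_qtl = causal_q)
}

#' Generate the synthetic input bundle with planted truth
#'
#' Writes every file family the pipeline reads into `dir`, together with
#' `truth.json` (the planted-truth manifest) and `config.yaml` (a ready
#' pipeline configuration pointing at the emitted files). Planted signals
#' are constructed so that each is realizable from the files alone:
#' enriched features annotate positives at `fc_target` times the
#' background rate and cover every planted functional SNP; planted
#' functional SNPs carry destroyed-by-alt motif matches in two motif
#' databases and/or significant local molecular QTLs; planted target
#' genes carry two cis-QTL datasets, two contact datasets (distal only)
#' and a shared-causal colocalization locus; decoys miss exactly one
#' evidence leg.
#'
#' @param config a [fixture_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, the truth manifest as a list
#' @export
generate_fixture <- function(config = fixture_config(), dir) {
  cfg <- config
  n_pair_snps <- cfg$n_local_genes +
    cfg$n_distal_genes * cfg$snps_per_distal_gene
  n_pos <- cfg$n_tags * (1L + cfg$proxies_per_tag)
  if (cfg$n_functional > cfg$n_tags * cfg$proxies_per_tag)
    stop("infeasible config: more planted functional SNPs than proxies")
  if (cfg$n_functional > 0 && n_pair_snps > cfg$n_functional)
    stop("infeasible config: more pair SNPs than planted functional SNPs")
  if (cfg$n_local_genes + cfg$n_distal_genes > cfg$n_tags)
    stop("infeasible config: need one tag per planted gene")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)

  mhc <- cfg$mhc
  truth <- list(seed = cfg$seed)

  # --- tag SNPs and LD proxies ---------------------------------------------
  .stream(cfg$seed, "tags")
  n_gene_tags <- cfg$n_local_genes + cfg$n_distal_genes
  tag_chrom <- rep(c("chr1", "chr2"), length.out = cfg$n_tags)
  tag_pos <- integer(cfg$n_tags)
  for (i in seq_len(cfg$n_tags)) {
    lim <- if (tag_chrom[i] == "chr2") c(1.5e6, 6.5e6) else c(1.5e6, 8.5e6)
    tag_pos[i] <- floor(runif(1, lim[1], lim[2]))
  }
  # one tag straddling the MHC boundary exercises locus truncation
  tag_chrom[cfg$n_tags] <- "chr2"; tag_pos[cfg$n_tags] <- 7.6e6
  tag_ids <- sprintf("rs_tag%02d", seq_len(cfg$n_tags))
  tag_disease <- sample(cfg$diseases, cfg$n_tags, replace = TRUE)
  tag_disease[seq_len(min(n_gene_tags, cfg$n_tags))] <- cfg$diseases[1]
  tags <- data.frame(snp_id = tag_ids, chrom = tag_chrom, pos = tag_pos,
                     diseases = tag_disease, coding_flag = FALSE,
                     stringsAsFactors = FALSE)

  .stream(cfg$seed, "proxies")
  prox <- list(); ld <- list()
  for (i in seq_len(cfg$n_tags)) {
    off_lim <- if (i == cfg$n_tags) c(-1e5, -1e3) else c(-1e5, 1e5)
    k <- cfg$proxies_per_tag + cfg$decoy_proxies_per_tag
    offs <- unique(round(runif(k * 2, off_lim[1], off_lim[2])))
    offs <- offs[offs != 0][seq_len(k)]
    r2 <- c(runif(cfg$proxies_per_tag, 0.85, 0.99),
            runif(cfg$decoy_proxies_per_tag, 0.3, 0.7))
    ids <- sprintf("rs_%02dp%02d", i, seq_len(k))
    prox[[i]] <- data.frame(snp_id = ids, chrom = tag_chrom[i],
                            pos = tag_pos[i] + offs,
                            tag = tag_ids[i], r2 = r2,
                            strong = seq_len(k) <= cfg$proxies_per_tag,
                            stringsAsFactors = FALSE)
    ld[[i]] <- data.frame(snp_a = tag_ids[i], snp_b = ids, r2 = r2,
                          stringsAsFactors = FALSE)
  }
  prox <- do.call(rbind, prox)
  ld <- do.call(rbind, ld)
  positives_truth <- c(tag_ids, prox$snp_id[prox$strong])

  # --- planted functional SNPs, genes and SNP-gene pairs -------------------
  .stream(cfg$seed, "genes")
  strong_prox <- prox[prox$strong, , drop = FALSE]
  # proxies grouped by tag; tags 1..n_local seed local genes, the next
  # n_distal tags seed distal genes
  func_ids <- character(0)
  pair_rows <- list()
  gene_rows <- list()
  gi <- 0L
  if (cfg$n_functional > 0 && n_gene_tags > 0) {
    for (g in seq_len(cfg$n_local_genes)) {
      gi <- gi + 1L
      s <- strong_prox[strong_prox$tag == tag_ids[g], ][1, ]
      gene_id <- sprintf("G_LOC%02d", g)
      gene_rows[[gi]] <- data.frame(gene_id = gene_id, chrom = s$chrom,
                                    strand = "+", tss = s$pos - 200L,
                                    stringsAsFactors = FALSE)
      pair_rows[[gi]] <- data.frame(snp_id = s$snp_id, gene_id = gene_id,
                                    pair_class = "local",
                                    stringsAsFactors = FALSE)
      func_ids <- c(func_ids, s$snp_id)
    }
    for (g in seq_len(cfg$n_distal_genes)) {
      gi <- gi + 1L
      t <- tag_ids[cfg$n_local_genes + g]
      s <- strong_prox[strong_prox$tag == t, ][seq_len(cfg$snps_per_distal_gene), ]
      gene_id <- if (g == 1L) "G_TFB" else sprintf("G_DIST%02d", g)
      gene_rows[[gi]] <- data.frame(gene_id = gene_id, chrom = s$chrom[1],
                                    strand = "+", tss = max(s$pos) + 80000L,
                                    stringsAsFactors = FALSE)
      pair_rows[[gi]] <- data.frame(snp_id = s$snp_id, gene_id = gene_id,
                                    pair_class = "distal",
                                    stringsAsFactors = FALSE)
      func_ids <- c(func_ids, s$snp_id)
    }
  }
  pairs_truth <- do.call(rbind, pair_rows) %||%
    data.frame(snp_id = character(0), gene_id = character(0),
               pair_class = character(0))
  # the decoy-gene tag supplies one functional SNP (for evidence-leg decoy
  # genes) and one inert SNP (for the non-functional-SNP decoy pair)
  decoy_snps <- character(0)
  if (nrow(pairs_truth) > 0L && cfg$n_tags > n_gene_tags) {
    decoy_snps <- strong_prox$snp_id[
      strong_prox$tag == tag_ids[n_gene_tags + 1L]][1:2]
    func_ids <- c(func_ids, decoy_snps[1])
  }
  # remaining planted functional SNPs: strong proxies of later tags
  pool <- setdiff(strong_prox$snp_id, c(func_ids, decoy_snps))
  extra_n <- max(0L, cfg$n_functional - length(func_ids))
  func_ids <- c(func_ids, pool[seq_len(min(extra_n, length(pool)))])
  # epigenetic-support-only decoys (no allelic evidence -> never functional)
  pool <- setdiff(strong_prox$snp_id, c(func_ids, decoy_snps))
  epi_only <- pool[seq_len(min(cfg$n_epi_only, length(pool)))]

  extra_genes <- data.frame(
    gene_id = sprintf("G_X%03d", seq_len(cfg$n_extra_genes)),
    chrom = sample(names(cfg$chrom_lengths), cfg$n_extra_genes, replace = TRUE),
    strand = sample(c("+", "-"), cfg$n_extra_genes, replace = TRUE),
    tss = floor(runif(cfg$n_extra_genes, 1e5, 9.9e6)),
    stringsAsFactors = FALSE)
  # keep random genes' promoters clear of planted functional SNPs so the
  # planted local/distal pair classes are exactly as designed
  fpos <- prox$pos[match(func_ids, prox$snp_id)]
  fchrom <- prox$chrom[match(func_ids, prox$snp_id)]
  bad <- vapply(seq_len(nrow(extra_genes)), function(i)
    any(fchrom == extra_genes$chrom[i] &
          abs(fpos - extra_genes$tss[i]) <= cfg$promoter_half_width + 10),
    logical(1))
  extra_genes$tss[bad] <- extra_genes$tss[bad] + 5000L
  genes <- rbind(do.call(rbind, gene_rows) %||% extra_genes[0, ], extra_genes)
  genes$symbol <- genes$gene_id

  # --- loci, background and negative SNPs ----------------------------------
  locus_set <- define_loci(tags, flank = 1e6, mhc = mhc)
  loci <- locus_set$loci

  .stream(cfg$seed, "background")
  w <- loci$end - loci$start
  seg <- sample(nrow(loci), cfg$n_background, replace = TRUE, prob = w)
  bg <- data.frame(
    snp_id = sprintf("rs_bg%05d", seq_len(cfg$n_background)),
    chrom = loci$chrom[seg],
    pos = floor(loci$start[seg] + runif(cfg$n_background) * w[seg]) + 1L,
    stringsAsFactors = FALSE)

  .stream(cfg$seed, "negatives")
  neg <- data.frame(snp_id = character(0), chrom = character(0),
                    pos = integer(0), stringsAsFactors = FALSE)
  while (nrow(neg) < cfg$n_negative) {
    m <- 2L * (cfg$n_negative - nrow(neg))
    cand <- data.frame(
      chrom = sample(names(cfg$chrom_lengths), m, replace = TRUE),
      pos = floor(runif(m, 1, 10e6)), stringsAsFactors = FALSE)
    ok <- !overlap_annotate(cand, loci) &
      !suppressWarnings(overlap_annotate(cand, mhc))  # one-chromosome batches are fine
    cand <- cand[ok, , drop = FALSE]
    cand$snp_id <- sprintf("rs_ng%05d", nrow(neg) + seq_len(nrow(cand)))
    neg <- rbind(neg, cand[, c("snp_id", "chrom", "pos")])
  }
  neg <- neg[seq_len(cfg$n_negative), , drop = FALSE]

  # SNPs outside loci in LD with catalog SNPs: must end up excluded
  .stream(cfg$seed, "catalog")
  cat_snps <- sprintf("rs_cat%03d", seq_len(50L))
  exc <- data.frame(snp_id = character(0), chrom = character(0),
                    pos = integer(0), stringsAsFactors = FALSE)
  while (nrow(exc) < cfg$n_catalog_excluded) {
    m <- 4L * (cfg$n_catalog_excluded - nrow(exc))
    cand <- data.frame(
      chrom = sample(names(cfg$chrom_lengths), m, replace = TRUE),
      pos = floor(runif(m, 1, 10e6)), stringsAsFactors = FALSE)
    ok <- !overlap_annotate(cand, loci) &
      !suppressWarnings(overlap_annotate(cand, mhc))  # one-chromosome batches are fine
    cand <- cand[ok, , drop = FALSE]
    cand$snp_id <- sprintf("rs_ex%03d", nrow(exc) + seq_len(nrow(cand)))
    exc <- rbind(exc, cand[, c("snp_id", "chrom", "pos")])
  }
  exc <- exc[seq_len(cfg$n_catalog_excluded), , drop = FALSE]
  catalog_ld <- data.frame(
    snp_a = sample(cat_snps, nrow(exc), replace = TRUE),
    snp_b = exc$snp_id, r2 = runif(nrow(exc), 0.15, 0.6),
    stringsAsFactors = FALSE)

  snps <- rbind(
    data.frame(snp_id = tags$snp_id, chrom = tags$chrom, pos = tags$pos,
               stringsAsFactors = FALSE),
    prox[, c("snp_id", "chrom", "pos")], bg, neg, exc)
  .stream(cfg$seed, "alleles")
  snps$ref <- .rand_bases(nrow(snps))
  snps$alt <- vapply(snps$ref, function(r)
    sample(setdiff(DNA_BASES, r), 1L), character(1))
  snps$coding_flag <- FALSE

  # --- epigenetic features --------------------------------------------------
  .stream(cfg$seed, "features")
  manifest <- list(); truth_features <- character(0)
  pos_df <- snps[snps$snp_id %in% positives_truth, , drop = FALSE]
  planted_df <- snps[snps$snp_id %in% c(func_ids, epi_only), , drop = FALSE]
  fid <- 0L
  for (cat in EPI_CATEGORIES) {
    for (k in seq_len(cfg$enriched_per_category + cfg$null_per_category)) {
      fid <- fid + 1L
      enriched <- k <= cfg$enriched_per_category
      feature_id <- sprintf("%s_%s_%02d", if (enriched) "enh" else "nul",
                            cat, k)
      rate_pos <- if (enriched) cfg$pos_rate else cfg$bg_rate
      sel_pos <- pos_df[runif(nrow(pos_df)) < rate_pos, , drop = FALSE]
      sel_bg <- bg[runif(nrow(bg)) < cfg$bg_rate, , drop = FALSE]
      sel_neg <- neg[runif(nrow(neg)) < cfg$bg_rate, , drop = FALSE]
      centers <- rbind(sel_pos[, c("chrom", "pos")], sel_bg[, c("chrom", "pos")],
                       sel_neg[, c("chrom", "pos")])
      if (enriched)  # every planted SNP is covered by every enriched feature
        centers <- rbind(centers, planted_df[, c("chrom", "pos")])
      peaks <- .reduce_intervals(gintervals(
        centers$chrom, pmax(0, centers$pos - 1 - cfg$peak_halfwidth),
        centers$pos + cfg$peak_halfwidth))
      bed <- file.path("peaks", paste0(feature_id, ".bed"))
      write_bed(peaks, file.path(dir, bed))
      manifest[[fid]] <- data.frame(
        feature_id = feature_id, category = cat,
        cell_type = sprintf("cell%02d", (k %% 5L) + 1L), bed_path = bed,
        stringsAsFactors = FALSE)
      if (enriched) truth_features <- c(truth_features, feature_id)
    }
  }
  manifest <- do.call(rbind, manifest)

  # --- motifs and flanks ----------------------------------------------------
  .stream(cfg$seed, "motifs")
  consensus <- list(TFA = "ACGTGACT", TFB = "TGCAATGC", TFC = "GATCCGAT")
  pwms_meme <- lapply(names(consensus), function(tf)
    .consensus_pwm(tf, "dbx", consensus[[tf]]))
  pwms_jaspar <- lapply(c("TFA", "TFB"), function(tf)
    .consensus_pwm(tf, "dby", consensus[[tf]]))  # TFC in one database only
  write_meme(pwms_meme, file.path(dir, "motifs_dbx.meme"))
  .write_jaspar_counts(pwms_jaspar, file.path(dir, "motifs_dby.pfm"))

  .stream(cfg$seed, "flanks")
  pos_all <- snps[snps$snp_id %in% positives_truth, , drop = FALSE]
  center <- (cfg$flank_width + 1L) %/% 2L
  # TFB on local-pair SNPs plus two distal-pair SNPs, TFA on the other
  # planted functional SNPs (both end up enriched among SNPs with
  # predicted targets); TFC (single-database, never retained) on a few
  # epi-only decoys
  local_snps <- pairs_truth$snp_id[pairs_truth$pair_class == "local"]
  tfb_snps <- c(local_snps,  # the last distal gene's SNPs, so TFA keeps G_TFB
                utils::tail(pairs_truth$snp_id[pairs_truth$pair_class == "distal"], 2L))
  tf_for <- stats::setNames(rep(NA_character_, nrow(pos_all)), pos_all$snp_id)
  tf_for[intersect(func_ids, pos_all$snp_id)] <- "TFA"
  tf_for[intersect(tfb_snps, pos_all$snp_id)] <- "TFB"
  tf_for[head(intersect(epi_only, pos_all$snp_id), 3L)] <- "TFC"
  flanks <- character(nrow(pos_all))
  motif_off <- 4L  # SNP sits at motif position 4
  for (i in seq_len(nrow(pos_all))) {
    fl <- .rand_bases(cfg$flank_width)
    tf <- tf_for[[pos_all$snp_id[i]]]
    if (!is.na(tf)) {
      cons <- strsplit(consensus[[tf]], "")[[1]]
      span <- (center - motif_off + 1L):(center - motif_off + cfg$motif_length)
      fl[span] <- cons
      pos_all$ref[i] <- cons[motif_off]
      pos_all$alt[i] <- sample(setdiff(DNA_BASES, cons[motif_off]), 1L)
    }
    fl[center] <- pos_all$ref[i]
    flanks[i] <- paste(fl, collapse = "")
  }
  snps$ref[match(pos_all$snp_id, snps$snp_id)] <- pos_all$ref
  snps$alt[match(pos_all$snp_id, snps$snp_id)] <- pos_all$alt
  writeLines(paste0(">", pos_all$snp_id, "\n", flanks),
             file.path(dir, "flanks.fa"))
  expressed <- data.frame(tf_name = c("TFA", "TFB", "TFC", "TFD"),
                          rpkm = c(5.2, 3.1, 2.4, 0.2),
                          stringsAsFactors = FALSE)

  # --- molecular QTLs -------------------------------------------------------
  .stream(cfg$seed, "mqtl")
  assays <- c("bQTL", "hQTL", "caQTL", "dsQTL")
  mq_ids <- func_ids[seq_len(min(length(func_ids), n_pair_snps + 5L))]
  mq <- list()
  for (i in seq_along(mq_ids)) {
    s <- snps[snps$snp_id == mq_ids[i], ]
    mq[[i]] <- data.frame(
      snp_id = s$snp_id, chrom = s$chrom, pos = s$pos,
      peak_chrom = s$chrom, peak_start = s$pos - 1L - 150L,
      peak_end = s$pos + 150L, assay = assays[(i %% 4L) + 1L],
      cell_type = "LCL", dataset_id = "mqtl_ds1",
      p = 1e-6, fdr = 0.01, stringsAsFactors = FALSE)
  }
  # decoys: distal peak despite tiny fdr; local peak with weak fdr
  dq <- strong_prox$snp_id[!(strong_prox$snp_id %in% func_ids)][1:5]
  dq <- dq[!is.na(dq)]
  for (id in dq) {
    s <- snps[snps$snp_id == id, ]
    mq[[length(mq) + 1L]] <- data.frame(
      snp_id = s$snp_id, chrom = s$chrom, pos = s$pos,
      peak_chrom = s$chrom, peak_start = s$pos + 10000L,
      peak_end = s$pos + 10300L, assay = "caQTL", cell_type = "LCL",
      dataset_id = "mqtl_ds1", p = 1e-8, fdr = 0.001,
      stringsAsFactors = FALSE)
    mq[[length(mq) + 1L]] <- data.frame(
      snp_id = s$snp_id, chrom = s$chrom, pos = s$pos,
      peak_chrom = s$chrom, peak_start = s$pos - 1L - 100L,
      peak_end = s$pos + 100L, assay = "hQTL", cell_type = "LCL",
      dataset_id = "mqtl_ds2", p = 0.4, fdr = 0.5, stringsAsFactors = FALSE)
  }
  mqtl <- do.call(rbind, mq) %||%
    data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
               peak_chrom = character(0), peak_start = integer(0),
               peak_end = integer(0), assay = character(0),
               cell_type = character(0), dataset_id = character(0),
               p = numeric(0), fdr = numeric(0))

  # --- cis-QTL, contacts, colocalization ------------------------------------
  .stream(cfg$seed, "cisqtl")
  mk_cis <- function(snp_id, gene_id, ds, fdr)
    data.frame(snp_id = snp_id, gene_id = gene_id, dataset_id = ds,
               cell_type = "CD4T", qtl_type = "eQTL", beta = 0.4, se = 0.05,
               p = fdr / 10, fdr = fdr, stringsAsFactors = FALSE)
  cis <- list()
  for (i in seq_len(nrow(pairs_truth)))
    for (ds in c("eqtl_ds1", "eqtl_ds2"))
      cis[[length(cis) + 1L]] <- mk_cis(pairs_truth$snp_id[i],
                                        pairs_truth$gene_id[i], ds, 0.001)
  # decoy genes, each one evidence leg short of prediction
  decoy <- list()
  if (length(decoy_snps) == 2L) {
    dsnp <- decoy_snps
    dpos <- strong_prox$pos[match(dsnp, strong_prox$snp_id)]
    dchrom <- strong_prox$chrom[match(dsnp[1], strong_prox$snp_id)]
    decoy_genes <- data.frame(
      gene_id = c("G_DECOY_QTL1", "G_DECOY_NO3D", "G_DECOY_NOCOLOC",
                  "G_DECOY_NOFUNC"),
      chrom = dchrom, strand = "+",
      tss = max(dpos) + c(90000L, 120000L, 150000L, 180000L),
      symbol = NA, stringsAsFactors = FALSE)
    decoy_genes$symbol <- decoy_genes$gene_id
    genes <- rbind(genes, decoy_genes[, colnames(genes)])
    cis[[length(cis) + 1L]] <- mk_cis(dsnp[1], "G_DECOY_QTL1", "eqtl_ds1", 0.001)
    for (ds in c("eqtl_ds1", "eqtl_ds2")) {
      cis[[length(cis) + 1L]] <- mk_cis(dsnp[1], "G_DECOY_NO3D", ds, 0.001)
      cis[[length(cis) + 1L]] <- mk_cis(dsnp[1], "G_DECOY_NOCOLOC", ds, 0.001)
      cis[[length(cis) + 1L]] <- mk_cis(dsnp[2], "G_DECOY_NOFUNC", ds, 0.001)
    }
    decoy <- list(snp = dsnp, genes = decoy_genes$gene_id)
  }
  cis <- do.call(rbind, cis) %||%
    data.frame(snp_id = character(0), gene_id = character(0),
               dataset_id = character(0), cell_type = character(0),
               qtl_type = character(0), beta = numeric(0), se = numeric(0),
               p = numeric(0), fdr = numeric(0))

  .stream(cfg$seed, "contacts")
  ct <- list()
  add_contact <- function(snp_id, gene_id, datasets) {
    sp <- snps[snps$snp_id == snp_id, ]
    gp <- genes[genes$gene_id == gene_id, ][1, ]
    for (ds in datasets)
      ct[[length(ct) + 1L]] <<- data.frame(
        chrom1 = sp$chrom, start1 = sp$pos - 1L - 5000L, end1 = sp$pos + 5000L,
        chrom2 = gp$chrom, start2 = max(0, gp$tss - 1L - 5000L),
        end2 = gp$tss + 5000L, dataset_id = ds, stringsAsFactors = FALSE)
  }
  dist_pairs <- pairs_truth[pairs_truth$pair_class == "distal", , drop = FALSE]
  for (i in seq_len(nrow(dist_pairs)))
    add_contact(dist_pairs$snp_id[i], dist_pairs$gene_id[i],
                c("hic_ds1", "hic_ds2"))
  if (length(decoy) > 0L) {
    add_contact(decoy$snp[1], "G_DECOY_NO3D", "hic_ds1")  # one dataset only
    add_contact(decoy$snp[1], "G_DECOY_QTL1", c("hic_ds1", "hic_ds2"))
    add_contact(decoy$snp[1], "G_DECOY_NOCOLOC", c("hic_ds1", "hic_ds2"))
    add_contact(decoy$snp[2], "G_DECOY_NOFUNC", c("hic_ds1", "hic_ds2"))
  }
  contacts <- do.call(rbind, ct) %||%
    data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
               chrom2 = character(0), start2 = integer(0), end2 = integer(0),
               dataset_id = character(0))

  # colocalization loci: one summary pair per candidate gene
  coloc_genes <- unique(cis$gene_id)
  gw <- qt <- list()
  for (g in coloc_genes) {
    kind <- if (g == "G_DECOY_NOCOLOC") "null" else "shared"
    sc <- generate_coloc_scenario(kind, n = cfg$coloc_n,
                                  effect = cfg$coloc_effect,
                                  snps = cfg$coloc_snps,
                                  seed = .sub_seed(cfg$seed, paste0("coloc_", g)))
    sc$gwas$gene_id <- g; sc$qtl$gene_id <- g
    sc$gwas$snp_id <- paste0(g, "_", sc$gwas$snp_id)
    sc$qtl$snp_id <- paste0(g, "_", sc$qtl$snp_id)
    gw[[g]] <- sc$gwas; qt[[g]] <- sc$qtl
  }
  coloc_gwas <- do.call(rbind, gw) %||%
    data.frame(snp_id = character(0), beta = numeric(0), se = numeric(0),
               p = numeric(0), n = integer(0), freq = numeric(0),
               type = character(0), gene_id = character(0))
  coloc_qtl <- do.call(rbind, qt) %||% coloc_gwas[0, ]

  # --- TF map, function, drug, PPI tables -----------------------------------
  tf_gene_map <- data.frame(
    tf_name = c("TFA", "TFB", "TFC"),
    gene_id = c("G_X001", "G_TFB", "G_X002"), stringsAsFactors = FALSE)

  planted_gene_ids <- unique(pairs_truth$gene_id)
  .stream(cfg$seed, "function")
  fn_tables <- list(
    pathway_immune = c(planted_gene_ids,
                       sample(extra_genes$gene_id, 5L)),
    impc_immune = head(planted_gene_ids, 2L),
    omim_immune = head(planted_gene_ids, 1L),
    expressed_blood = c(planted_gene_ids,
                        sample(extra_genes$gene_id, 60L)),
    tsea_blood = head(planted_gene_ids, 2L),
    disgenet_immune = head(planted_gene_ids, 3L),
    smr_causal = head(planted_gene_ids, 2L))
  fn_long <- do.call(rbind, lapply(names(fn_tables), function(f) {
    g <- unique(fn_tables[[f]])
    data.frame(gene_id = g, flag = rep(f, length(g)),
               stringsAsFactors = FALSE)
  }))
  pathways <- rbind(
    data.frame(pathway = "immune_pathway_1",
               gene_id = unique(c(planted_gene_ids,
                                  sample(extra_genes$gene_id, 5L))),
               stringsAsFactors = FALSE),
    data.frame(pathway = "other_pathway_1",
               gene_id = sample(extra_genes$gene_id, 20L),
               stringsAsFactors = FALSE))

  # drug-target planting over the planted genes (disease B = diseases[1])
  B <- cfg$diseases[1]
  dist_ids <- unique(dist_pairs$gene_id)
  drug_truth <- list()
  drugs <- list(); drugg <- list(); ppi <- list()
  if (length(dist_ids) >= 3L && cfg$n_local_genes >= 1L) {
    A1 <- dist_ids[2]; C1 <- dist_ids[3]; A2 <- "G_LOC01"
    drugs[[1]] <- data.frame(gene_id = C1, drug_id = "drugX", indication = B,
                             stringsAsFactors = FALSE)
    drugs[[2]] <- data.frame(gene_id = A2, drug_id = "drugY",
                             indication = "other_dis_1", stringsAsFactors = FALSE)
    d4 <- if (length(dist_ids) >= 4L) dist_ids[4] else character(0)
    drugg$dgidb <- c(A1, d4, "G_X003")
    drugg$pharos <- c(A1, d4, "G_X004")
    drugg$finan <- "G_X003"
    ppi[[1]] <- data.frame(gene_a = A1, gene_b = C1, score = 0.95,
                           stringsAsFactors = FALSE)
    ppi[[2]] <- data.frame(gene_a = A2, gene_b = C1, score = 0.93,
                           stringsAsFactors = FALSE)
    # decoys: weak PPI; strong PPI but no druggability; partner unregulated
    if (length(dist_ids) >= 4L) {
      ppi[[3]] <- data.frame(gene_a = dist_ids[4], gene_b = C1, score = 0.85,
                             stringsAsFactors = FALSE)
    }
    ppi[[4]] <- data.frame(gene_a = dist_ids[1], gene_b = C1, score = 0.95,
                           stringsAsFactors = FALSE)  # dist_ids[1] not druggable
    drugs[[3]] <- data.frame(gene_id = "G_X005", drug_id = "drugZ",
                             indication = B, stringsAsFactors = FALSE)
    ppi[[5]] <- data.frame(gene_a = A1, gene_b = "G_X005", score = 0.96,
                           stringsAsFactors = FALSE)  # partner not regulated for B
    drug_truth <- list(
      data.frame(candidate_gene = A1, disease = B, repurposing_flag = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(candidate_gene = A2, disease = B, repurposing_flag = TRUE,
                 stringsAsFactors = FALSE))
  }
  .stream(cfg$seed, "ppi_noise")
  ppi[[length(ppi) + 1L]] <- data.frame(
    gene_a = sample(extra_genes$gene_id, 30L),
    gene_b = sample(extra_genes$gene_id, 30L),
    score = runif(30L, 0.1, 0.89), stringsAsFactors = FALSE)
  ppi <- do.call(rbind, ppi)
  drugs <- do.call(rbind, drugs) %||%
    data.frame(gene_id = character(0), drug_id = character(0),
               indication = character(0))
  druggability <- do.call(rbind, lapply(names(drugg), function(r)
    data.frame(gene_id = drugg[[r]], resource = r, stringsAsFactors = FALSE))) %||%
    data.frame(gene_id = character(0), resource = character(0))
  ind_classes <- data.frame(
    indication = c(cfg$diseases, "other_dis_1", "immune_rel_1"),
    class = c(rep("autoimmune", length(cfg$diseases)), "other",
              "immune_related"), stringsAsFactors = FALSE)

  # --- write the bundle -----------------------------------------------------
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(tags, "tags.tsv")
  wt(snps, "snps.tsv")
  wt(ld, "ld.tsv")
  wt(catalog_ld, "catalog_ld.tsv")
  writeLines(cat_snps, file.path(dir, "catalog_snps.txt"))
  wt(manifest, "feature_manifest.tsv")
  wt(expressed, "expressed_tfs.tsv")
  wt(mqtl, "molecular_qtl.tsv")
  wt(cis, "cis_qtl.tsv")
  wt(contacts, "contacts.bedpe")
  wt(coloc_gwas, "coloc_gwas.tsv")
  wt(coloc_qtl, "coloc_qtl.tsv")
  wt(genes[, c("gene_id", "symbol", "chrom", "strand", "tss")], "genes.tsv")
  wt(tf_gene_map, "tf_gene_map.tsv")
  wt(fn_long, "gene_function.tsv")
  wt(pathways, "pathways.tsv")
  wt(drugs, "drugs.tsv")
  wt(druggability, "druggability.tsv")
  wt(ind_classes, "indication_classes.tsv")
  wt(ppi, "ppi.tsv")

  truth$positive_snps <- sort(positives_truth)
  truth$functional_snps <- sort(func_ids)
  truth$epi_only_snps <- sort(epi_only)
  truth$enriched_features <- sort(truth_features)
  truth$pairs <- pairs_truth
  truth$local_genes <- sort(unique(
    pairs_truth$gene_id[pairs_truth$pair_class == "local"]))
  truth$distal_genes <- sort(unique(
    pairs_truth$gene_id[pairs_truth$pair_class == "distal"]))
  truth$decoy_genes <- if (length(decoy) > 0L) decoy$genes else character(0)
  truth$enriched_tfs <- if (cfg$n_functional > 0) c("TFA", "TFB") else character(0)
  if (nrow(pairs_truth) > 0L) {
    tfb_genes <- unique(pairs_truth$gene_id[pairs_truth$snp_id %in% tfb_snps])
    tfa_genes <- setdiff(unique(pairs_truth$gene_id), tfb_genes)
    truth$tf_direct <- list(TFA = sort(tfa_genes), TFB = sort(tfb_genes))
    # TFA targets G_TFB (the gene encoding TFB), so TFB's direct targets
    # are TFA's one-hop indirect targets
    truth$tf_indirect <- list(
      TFA = if ("G_TFB" %in% tfa_genes) sort(tfb_genes) else character(0))
  }
  truth$drug_predictions <- do.call(rbind, drug_truth) %||%
    data.frame(candidate_gene = character(0), disease = character(0),
               repurposing_flag = logical(0))
  truth$excluded_snps <- sort(exc$snp_id)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pipeline_cfg <- list(
    seed = cfg$seed, data_dir = ".",
    mhc = list(chrom = mhc$chrom, start = mhc$start, end = mhc$end),
    r2_min = 0.8, catalog_r2 = 0.1, feature_alpha = 0.05,
    null_quantile = 0.95, motif_p = 1e-4, mqtl_fdr = 0.1, cis_fdr = 0.05,
    min_qtl_datasets = 2, min_interaction_datasets = 2,
    min_motif_databases = 2, pp4 = 0.8,
    promoter_half_width = cfg$promoter_half_width, ppi = 0.9)
  yaml::write_yaml(pipeline_cfg, file.path(dir, "config.yaml"))

  invisible(truth)
}

# JASPAR-style PFM writer (counts scaled to 100).
.write_jaspar_counts <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_name), con)
    counts <- round(t(p$mat) * 100)
    for (b in seq_len(4))
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(counts[b, ], collapse = " ")), con)
  }
}
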