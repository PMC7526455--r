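# Epigenetic feature enrichment and fold-enrichment-weighted functional
# scoring. One "feature" is one annotation (chromatin state, histone mark,
# DHS, TF ChIP peak set) in one cell type; features belong to one of four
# categories: HMM15, histone, DHS, TFBS.

#' The four epigenetic feature categories
#'
#' Chromatin-state segmentations (HMM15), active histone modifications,
#' DNase I hypersensitive sites, and TF-binding sites. Each yields an
#' independent functional score per SNP.
#' @export
EPI_CATEGORIES <- c("HMM15", "histone", "DHS", "TFBS")

#' Annotate SNPs against a set of epigenetic features
#'
#' @param snps SNP table with `chrom`, `pos` (1-based)
#' @param peaks interval table of all feature peaks, `label` holding the
#'   feature id
#' @param feature_ids feature ids defining column order of the result
#' @return logical incidence matrix, `nrow(snps)` x `length(feature_ids)`
#' @export
annotate_features <- function(snps, peaks, feature_ids) {
  ann <- matrix(FALSE, nrow = nrow(snps), ncol = length(feature_ids),
                dimnames = list(NULL, feature_ids))
  hits <- .overlap_hits(snps, peaks)
  if (nrow(hits) > 0L) {
    fidx <- match(peaks$label[hits$interval], feature_ids)
    ok <- !is.na(fidx)
    ann[cbind(hits$snp[ok], fidx[ok])] <- TRUE
  }
  ann
}

#' Per-feature enrichment of positive over background SNPs
#'
#' For every feature, a 2x2 test of annotated/unannotated counts in the
#' positive versus background SNP sets (chi-square without continuity
#' correction, exact fallback at sparse expected counts), the fold change
#' FC = annotated_pos x total_bg / (annotated_bg x total_pos), and a
#' Bonferroni adjustment whose denominator is the *total* number of
#' features across all four categories (the selection rule is
#' `FC > 1` and `p < alpha / N_features`). A feature with no peaks gets an
#' undefined FC and is never selected.
#'
#' @param annotated_pos,annotated_bg per-feature annotated counts, aligned
#'   with `manifest`; alternatively logical incidence matrices from
#'   [annotate_features()] whose column sums are taken
#' @param n_pos,n_bg total positive / background SNP counts (inferred from
#'   matrix inputs when omitted)
#' @param manifest `data.frame` with `feature_id`, `category`, `cell_type`
#' @param alpha family-wise significance level before Bonferroni division
#' @return `data.frame` with one row per feature: counts, `fc`, `p`,
#'   `p_adj`, `selected`
#' @export
enrich_features <- function(annotated_pos, annotated_bg, manifest,
                            n_pos = NULL, n_bg = NULL, alpha = 0.05) {
  if (is.matrix(annotated_pos)) {
    n_pos <- n_pos %||% nrow(annotated_pos)
    annotated_pos <- colSums(annotated_pos)
  }
  if (is.matrix(annotated_bg)) {
    n_bg <- n_bg %||% nrow(annotated_bg)
    annotated_bg <- colSums(annotated_bg)
  }
  stopifnot(length(annotated_pos) == nrow(manifest),
            length(annotated_bg) == nrow(manifest),
            !is.null(n_pos), !is.null(n_bg))
  nf <- nrow(manifest)
  p <- fc <- numeric(nf)
  for (i in seq_len(nf)) {
    a <- annotated_pos[i]; c_ <- annotated_bg[i]
    t <- association_test_2x2(a, n_pos - a, c_, n_bg - c_, method = "chi2")
    p[i] <- t$p_value
    fc[i] <- if (a == 0 && c_ == 0) NaN
             else as.numeric(fold_change(a, n_pos, c_, n_bg))
  }
  p_adj <- adjust_pvalues(p, "bonferroni")
  selected <- is.finite(fc) & fc > 1 & p < alpha / nf
  zero_peak <- annotated_pos == 0 & annotated_bg == 0
  if (any(zero_peak))
    message(sum(zero_peak), " feature(s) annotate no SNPs; FC undefined, not selected")
  data.frame(feature_id = manifest$feature_id, category = manifest$category,
             cell_type = manifest$cell_type,
             annotated_pos = annotated_pos, n_pos = n_pos,
             annotated_bg = annotated_bg, n_bg = n_bg,
             fc = fc, p = p, p_adj = p_adj, selected = selected,
             stringsAsFactors = FALSE)
}

#' Fold-enrichment-weighted category score
#'
#' The accumulative functional score of one SNP within one epigenetic
#' category: `S = sum_j FC_j * B_j` over the selected features `j` of that
#' category, where `B_j` is the 0/1 annotation indicator and `FC_j` the
#' feature's fold enrichment.
#'
#' @param annotations 0/1 (or logical) vector, or a SNP x feature matrix
#' @param weights fold-enrichment weights of the same features
#' @return numeric score (vector of scores for matrix input)
#' @export
score_category <- function(annotations, weights) {
  if (is.matrix(annotations)) {
    if (ncol(annotations) != length(weights))
      stop("annotation/weight length mismatch")
    return(as.numeric(annotations %*% weights))
  }
  if (length(annotations) != length(weights))
    stop("annotation/weight length mismatch")
  sum(weights * as.numeric(annotations))
}

#' Score a SNP set across the four epigenetic categories
#'
#' Annotates SNPs against the selected features only and accumulates the
#' FC-weighted score per category. SNPs are processed in chunks so that
#' scoring tens of millions of negatives never materialises the full
#' incidence matrix.
#'
#' @param snps SNP table (`chrom`, `pos`)
#' @param peaks peak intervals labelled by feature id
#' @param enrichment result of [enrich_features()]
#' @param chunk_size SNPs per annotation chunk
#' @return numeric matrix `nrow(snps)` x 4 with columns HMM15, histone,
#'   DHS, TFBS
#' @export
score_snp_set <- function(snps, peaks, enrichment, chunk_size = 50000L) {
  sel <- enrichment[enrichment$selected, , drop = FALSE]
  scores <- matrix(0, nrow = nrow(snps), ncol = length(EPI_CATEGORIES),
                   dimnames = list(snps$snp_id, EPI_CATEGORIES))
  if (nrow(sel) == 0L || nrow(snps) == 0L) return(scores)
  sel_peaks <- peaks[peaks$label %in% sel$feature_id, , drop = FALSE]
  starts <- seq(1L, nrow(snps), by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, nrow(snps))
    ann <- annotate_features(snps[idx, , drop = FALSE], sel_peaks, sel$feature_id)
    for (cat in EPI_CATEGORIES) {
      j <- which(sel$category == cat)
      if (length(j) > 0L)
        scores[idx, cat] <- score_category(ann[, j, drop = FALSE], sel$fc[j])
    }
  }
  scores
}

#' Empirical-null support call against negative-SNP scores
#'
#' The null threshold is the nearest-rank 95th percentile of the negative
#' scores (the `ceiling(q * n)`-th order statistic — no interpolation), and
#' a positive SNP is supported iff its score *strictly* exceeds it, i.e.
#' lies above the top-5% ranked negative score. By construction at most a
#' `1 - q` fraction of the negatives themselves exceed the threshold.
#'
#' @param positive_scores scores of the SNPs under evaluation
#' @param negative_scores scores of the negative (null) SNPs; must be
#'   non-empty
#' @param quantile null quantile, default 0.95
#' @return list with `threshold` and logical `support` along
#'   `positive_scores`
#' @export
null_support <- function(positive_scores, negative_scores, quantile = 0.95) {
  if (length(negative_scores) == 0L) stop("negative score set is empty")
  k <- ceiling(quantile * length(negative_scores))
  threshold <- sort(negative_scores, method = "quick")[k]
  list(threshold = threshold, support = positive_scores > threshold)
}

#' Per-SNP supported epigenetic categories
#'
#' Applies [null_support()] independently per category and returns, for
#' each SNP, which of the four categories support it and how many.
#'
#' @param pos_scores score matrix of the SNPs under evaluation
#'   ([score_snp_set()])
#' @param neg_scores score matrix of the negative SNPs
#' @param quantile null quantile, default 0.95
#' @return `data.frame` with `snp_id`, one logical column per category,
#'   `n_categories`, and a pipe-separated `categories` string; the
#'   per-category thresholds are attached as attribute `"thresholds"`
#' @export
epigenetic_support <- function(pos_scores, neg_scores, quantile = 0.95) {
  thr <- numeric(length(EPI_CATEGORIES))
  names(thr) <- EPI_CATEGORIES
  sup <- matrix(FALSE, nrow(pos_scores), length(EPI_CATEGORIES),
                dimnames = list(NULL, EPI_CATEGORIES))
  for (cat in EPI_CATEGORIES) {
    ns <- null_support(pos_scores[, cat], neg_scores[, cat], quantile)
    thr[cat] <- ns$threshold
    sup[, cat] <- ns$support
  }
  out <- data.frame(snp_id = rownames(pos_scores) %||% seq_len(nrow(pos_scores)),
                    sup, stringsAsFactors = FALSE)
  out$n_categories <- rowSums(sup)
  out$categories <- apply(sup, 1L, function(z)
    paste(EPI_CATEGORIES[z], collapse = "|"))
  attr(out, "thresholds") <- thr
  out
}
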