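# Target-gene prediction: cis-QTL validation, 3D chromatin-interaction
# support, Bayesian colocalization (ABF and PICS variants), and the final
# multi-evidence conjunction separating local from distal regulation.

#' Filter cis-QTL associations and count supporting datasets
#'
#' Keeps associations at FDR < `fdr_max` (Benjamini-Hochberg within a
#' dataset when no FDR column is supplied) and tallies, per SNP-gene pair,
#' the number of distinct supporting datasets; a pair is `validated` with
#' support from at least `min_datasets` datasets. Associations to genes
#' absent from the gene model are dropped with a message.
#'
#' @param assocs `data.frame` with `snp_id`, `gene_id`, `dataset_id`,
#'   `cell_type`, `qtl_type` and `p` and/or `fdr`
#' @param genes optional gene model (`gene_id`, `tss`); used to drop
#'   associations to unknown genes
#' @param fdr_max significance cut-off, default 0.05
#' @param min_datasets validation threshold, default 2
#' @return list with `assocs` (significant rows) and `pairs`
#'   (`snp_id`, `gene_id`, `qtl_dataset_count`, `validated`)
#' @export
filter_cis_qtl <- function(assocs, genes = NULL, fdr_max = 0.05,
                           min_datasets = 2L) {
  if (!is.null(genes)) {
    known <- assocs$gene_id %in% genes$gene_id
    if (any(!known))
      message(sum(!known), " association(s) to genes without a TSS; dropped")
    assocs <- assocs[known, , drop = FALSE]
  }
  if (is.null(assocs$fdr)) assocs$fdr <- NA_real_
  for (ds in unique(assocs$dataset_id)) {
    i <- assocs$dataset_id == ds
    if (any(is.na(assocs$fdr[i])))
      assocs$fdr[i] <- adjust_pvalues(assocs$p[i], "bh")
  }
  sig <- assocs[assocs$fdr < fdr_max, , drop = FALSE]
  key <- paste(sig$snp_id, sig$gene_id, sep = "\r")
  cnt <- vapply(split(sig$dataset_id, key),
                function(d) length(unique(d)), integer(1))
  parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  pairs <- data.frame(snp_id = parts[, 1], gene_id = parts[, 2],
                      qtl_dataset_count = as.integer(cnt),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L)
    pairs <- data.frame(snp_id = character(0), gene_id = character(0),
                        qtl_dataset_count = integer(0))
  pairs$validated <- pairs$qtl_dataset_count >= min_datasets
  rownames(sig) <- rownames(pairs) <- NULL
  list(assocs = sig, pairs = pairs)
}

#' Chromatin-interaction support for SNP-gene pairs
#'
#' A contact supports a pair iff the SNP falls inside one anchor and some
#' promoter window of the gene overlaps the *other* anchor (both
#' orientations are checked; both evidence legs inside the same anchor do
#' not count). Support is the number of distinct contact datasets;
#' trans-chromosomal pairs naturally get 0.
#'
#' @param pairs `data.frame` with `snp_id`, `gene_id`
#' @param snps SNP coordinates (`snp_id`, `chrom`, `pos`)
#' @param promoters promoter windows labelled by gene id
#'   ([promoter_windows()])
#' @param contacts `data.frame` in BEDPE-like layout: `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `dataset_id`
#' @return `pairs` with an `interaction_dataset_count` column
#' @export
interaction_support <- function(pairs, snps, promoters, contacts) {
  pairs$interaction_dataset_count <- rep(0L, nrow(pairs))
  if (nrow(pairs) == 0L || nrow(contacts) == 0L) return(pairs)
  a1 <- gintervals(contacts$chrom1, contacts$start1, contacts$end1)
  a2 <- gintervals(contacts$chrom2, contacts$start2, contacts$end2)
  link <- function(snp_anchor, prom_anchor) {
    hs <- .overlap_hits(snps, snp_anchor)                 # snp row, contact row
    hp <- .prom_anchor_hits(promoters, prom_anchor)       # promoter row, contact row
    if (nrow(hs) == 0L || nrow(hp) == 0L) return(NULL)
    m <- merge(data.frame(contact = hs$interval, snp_id = snps$snp_id[hs$snp]),
               data.frame(contact = hp$interval,
                          gene_id = promoters$label[hp$prom]),
               by = "contact")
    m$dataset_id <- contacts$dataset_id[m$contact]
    m
  }
  ev <- rbind(link(a1, a2), link(a2, a1))
  if (is.null(ev) || nrow(ev) == 0L) return(pairs)
  key <- paste(ev$snp_id, ev$gene_id, sep = "\r")
  cnt <- vapply(split(ev$dataset_id, key),
                function(d) length(unique(d)), integer(1))
  hit <- match(paste(pairs$snp_id, pairs$gene_id, sep = "\r"), names(cnt))
  pairs$interaction_dataset_count[!is.na(hit)] <-
    as.integer(cnt[hit[!is.na(hit)]])
  pairs
}

# Interval-vs-interval overlap hits (promoter windows vs contact anchors).
.prom_anchor_hits <- function(proms, anchors) {
  if (nrow(proms) == 0L || nrow(anchors) == 0L)
    return(data.frame(prom = integer(0), interval = integer(0)))
  common <- intersect(unique(proms$chrom), unique(anchors$chrom))
  if (length(common) == 0L)
    return(data.frame(prom = integer(0), interval = integer(0)))
  h <- GenomicRanges::findOverlaps(.intervals_to_granges(proms),
                                   .intervals_to_granges(anchors))
  data.frame(prom = S4Vectors::queryHits(h), interval = S4Vectors::subjectHits(h))
}

# Colocalization ------------------------------------------------------------

# Wakefield approximate Bayes factor (log scale) per SNP.
# z: association z-score; V: variance of the effect estimate; W: prior
# effect variance. lABF = 0.5*(log(V/(V+W)) + z^2 * W/(V+W)).
.labf <- function(z, V, W) {
  r <- W / (V + W)
  0.5 * (log(1 - r) + r * z^2)
}

# Recover z and effect variance from a summary-statistics table.
# Preference order: beta/se; else z from two-sided p (signed by beta when
# present) with V approximated from allele frequency and sample size.
.summary_z_v <- function(d) {
  z <- rep(NA_real_, nrow(d))
  V <- rep(NA_real_, nrow(d))
  # [[ ]] throughout: $ would partially match (e.g. "s" to "snp_id")
  beta <- d[["beta"]]; se <- d[["se"]]
  if (!is.null(beta) && !is.null(se)) {
    i <- !is.na(beta) & !is.na(se) & se > 0
    z[i] <- beta[i] / se[i]
    V[i] <- se[i]^2
  }
  need <- is.na(z)
  if (any(need)) {
    if (is.null(d[["p"]])) stop("summary statistics need beta/se or p")
    zz <- stats::qnorm(pmax(d[["p"]][need] / 2, 1e-300), lower.tail = FALSE)
    if (!is.null(beta))
      zz <- zz * ifelse(is.na(beta[need]) | beta[need] >= 0, 1, -1)
    z[need] <- zz
    f <- d[["freq"]][need]
    n <- d[["n"]][need]
    s <- d[["s"]]
    sc <- if (!is.null(s)) ifelse(is.na(s[need]), 1, s[need] * (1 - s[need])) else 1
    V[need] <- 1 / (2 * n * f * (1 - f) * sc)
  }
  list(z = z, V = V)
}

#' Colocalization by approximate Bayes factors
#'
#' The standard single-causal-variant Bayesian colocalization of a GWAS
#' signal and a QTL signal over a shared SNP region. Per-SNP Wakefield
#' approximate Bayes factors are computed for each trait (prior effect
#' s.d. 0.15 for quantitative traits, 0.2 for case-control), combined
#' with the prior probabilities `p1`, `p2`, `p12` in log space, and
#' normalised into five posterior hypothesis probabilities:
#' PP0 no association; PP1 GWAS only; PP2 QTL only; PP3 both, distinct
#' causal variants; PP4 both, one shared causal variant. PP4 > 0.8 is
#' the conventional colocalization call.
#'
#' @param gwas,qtl summary-statistics `data.frame`s with `snp_id` and
#'   either `beta` + `se` or `p` + `n` + `freq`; optional `type`
#'   (`"quant"`/`"cc"`, default quantitative) and case fraction `s`
#' @param p1,p2,p12 prior probabilities that a SNP is causal for trait 1
#'   only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5)
#' @param sd_prior optional explicit prior effect s.d. per trait,
#'   length 2; overrides the type-based default
#' @return object of class `funsnp_coloc`: `pp` (named PP0..PP4),
#'   `nsnps`, `method = "abf"`, `colocalized`
#' @export
coloc_abf <- function(gwas, qtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      sd_prior = NULL) {
  shared <- intersect(gwas$snp_id, qtl$snp_id)
  if (length(shared) < 2L)
    stop("colocalization needs at least 2 shared SNPs between GWAS and QTL")
  g <- gwas[match(shared, gwas$snp_id), , drop = FALSE]
  q <- qtl[match(shared, qtl$snp_id), , drop = FALSE]
  w_for <- function(d, default_idx) {
    if (!is.null(sd_prior)) return(sd_prior[default_idx]^2)
    type <- if (!is.null(d[["type"]])) d[["type"]][1] else "quant"
    if (identical(type, "cc")) 0.2^2 else 0.15^2
  }
  zg <- .summary_z_v(g); zq <- .summary_z_v(q)
  l1 <- .labf(zg$z, zg$V, w_for(g, 1))
  l2 <- .labf(zq$z, zq$V, w_for(q, 2))
  s1 <- logsumexp(l1); s2 <- logsumexp(l2); s12 <- logsumexp(l1 + l2)
  # log(sum_{i != j} BF1_i BF2_j) = logdiff(s1 + s2, s12)
  cross <- if (s1 + s2 <= s12) -Inf else (s1 + s2) + log1p(-exp(s12 - s1 - s2))
  lh <- c(PP0 = 0,
          PP1 = log(p1) + s1,
          PP2 = log(p2) + s2,
          PP3 = log(p1) + log(p2) + cross,
          PP4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp = pp / sum(pp), nsnps = length(shared), method = "abf",
                 colocalized = unname(pp["PP4"] > 0.8)),
            class = "funsnp_coloc")
}

#' @export
print.funsnp_coloc <- function(x, ...) {
  cat(sprintf("colocalization (%s, %d SNPs): %s\n", x$method, x$nsnps,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  cat(if (x$colocalized) "  -> colocalized (PP4 > 0.8)\n" else
      "  -> not colocalized\n")
  invisible(x)
}

#' PICS fine-mapping probabilities from a lead SNP
#'
#' Given the lead SNP's association strength `S = -log10(p)` and each
#' SNP's LD `r` to the lead, the probability that SNP `i` is causal is
#' proportional to the Normal density of the observed lead association
#' under causality of `i`: mean `r_i^2 * S`, s.d.
#' `sqrt(1 - |r_i|^3.2) * sqrt(S) / 2` (constants from the fine-mapping
#' literature; overridable). Perfect proxies (`|r| = 1`) have a
#' degenerate s.d. of 0 and share the point mass equally. Probabilities
#' are normalised over the locus and the credible set is the smallest
#' set of SNPs reaching cumulative probability `credible`.
#'
#' @param lead_log10p `-log10` p-value of the lead SNP (> 0)
#' @param r signed LD correlation of every locus SNP to the lead, in
#'   `[-1, 1]` (include the lead itself with r = 1)
#' @param snp_ids optional SNP identifiers
#' @param credible credible-set mass, default 0.95
#' @param exponent,sd_scale the LD decay exponent (3.2) and s.d. scale
#'   (1/2) of the dispersion model
#' @return object of class `funsnp_pics`: `data.frame` with `snp_id`,
#'   `r`, `prob`, `in_credible`, sorted by decreasing probability
#' @export
pics_probabilities <- function(lead_log10p, r, snp_ids = NULL,
                               credible = 0.95, exponent = 3.2,
                               sd_scale = 0.5) {
  stopifnot(lead_log10p > 0, all(abs(r) <= 1))
  snp_ids <- snp_ids %||% paste0("snp", seq_along(r))
  if (length(r) == 1L) {
    out <- data.frame(snp_id = snp_ids, r = r, prob = 1, in_credible = TRUE,
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("funsnp_pics", "data.frame")))
  }
  mu <- r^2 * lead_log10p
  sdv <- sqrt(pmax(0, 1 - abs(r)^exponent)) * sqrt(lead_log10p) * sd_scale
  perfect <- abs(r) == 1
  if (any(perfect)) {
    dens <- ifelse(perfect, 1, 0)  # degenerate spike dominates any finite density
  } else {
    dens <- stats::dnorm(lead_log10p, mean = mu, sd = sdv)
    if (sum(dens) == 0) dens <- rep(1, length(r))  # all vanishing: flat fallback
  }
  prob <- dens / sum(dens)
  ord <- order(prob, decreasing = TRUE)
  cum <- cumsum(prob[ord])
  k <- which(cum >= credible)[1]
  in_cred <- logical(length(r))
  in_cred[ord[seq_len(k)]] <- TRUE
  out <- data.frame(snp_id = snp_ids, r = r, prob = prob,
                    in_credible = in_cred, stringsAsFactors = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("funsnp_pics", "data.frame"))
}

#' PICS-based colocalization of two fine-mapped signals
#'
#' Given PICS probability vectors `g` (GWAS) and `q` (QTL) over a shared
#' SNP universe, the shared-causal mass is `sum_i g_i q_i` and the
#' distinct-causal mass `sum_{i != j} g_i q_j`. Both fine-mapped sets
#' presuppose an observed association in their trait, so the
#' no-association hypotheses PP0-PP2 carry no mass; PP3 and PP4 are the
#' prior-weighted (`p1 p2` vs `p12`) normalisation of the distinct and
#' shared masses. Disjoint SNP sets yield PP4 = 0 with a warning.
#'
#' @param gwas_pics,qtl_pics [pics_probabilities()] results
#' @param p1,p2,p12 the same priors as [coloc_abf()]
#' @return object of class `funsnp_coloc` with `method = "pics"`
#' @export
pics_coloc <- function(gwas_pics, qtl_pics, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  all_ids <- union(gwas_pics$snp_id, qtl_pics$snp_id)
  g <- q <- stats::setNames(numeric(length(all_ids)), all_ids)
  g[gwas_pics$snp_id] <- gwas_pics$prob
  q[qtl_pics$snp_id] <- qtl_pics$prob
  shared_mass <- sum(g * q)
  distinct_mass <- sum(g) * sum(q) - shared_mass
  if (length(intersect(gwas_pics$snp_id, qtl_pics$snp_id)) == 0L)
    warning("disjoint SNP sets between the two PICS sets; PP4 = 0")
  h3 <- p1 * p2 * distinct_mass
  h4 <- p12 * shared_mass
  tot <- h3 + h4
  pp <- c(PP0 = 0, PP1 = 0, PP2 = 0,
          PP3 = if (tot > 0) h3 / tot else 1,
          PP4 = if (tot > 0) h4 / tot else 0)
  structure(list(pp = pp, nsnps = length(all_ids), method = "pics",
                 colocalized = unname(pp["PP4"] > 0.8)),
            class = "funsnp_coloc")
}

# Prediction -----------------------------------------------------------------

#' Predict regulatory target genes for functional SNPs
#'
#' A SNP-gene pair is *local* when the SNP sits inside a promoter window
#' of the gene and *distal* otherwise. A pair is predicted iff the SNP is
#' functional, the pair has significant cis-QTL support from at least
#' `min_qtl_datasets` datasets, the gene colocalizes (max PP4 >
#' `pp4_min` over tested GWAS x QTL dataset combinations), and — for
#' distal pairs only — chromatin-interaction support from at least
#' `min_interaction_datasets` datasets. Predicted genes are then
#' classified: a *local gene* is predicted exclusively through local
#' pairs, a *distal gene* has at least one distal pair, and genes with
#' no local pair at all are flagged `exclusively_distal`.
#'
#' @param functional functional-SNP table ([prioritize_functional_snps()])
#' @param qtl_pairs pair table from [filter_cis_qtl()]
#' @param interactions pair table from [interaction_support()] (a pair
#'   missing from it counts as 0 datasets)
#' @param coloc_genes `data.frame` with `gene_id`, `pp4` (one row per
#'   tested dataset combination; the per-gene max is used)
#' @param snps SNP coordinates (`snp_id`, `chrom`, `pos`)
#' @param promoters promoter windows labelled by gene id
#' @param min_qtl_datasets,min_interaction_datasets,pp4_min evidence
#'   thresholds (2, 2, 0.8)
#' @return list with `pairs` (all candidate pairs with evidence columns,
#'   `pair_class`, `predicted`) and `genes` (`gene_id`, `gene_class`,
#'   `exclusively_distal`, pair counts) restricted to predicted genes
#' @export
predict_target_genes <- function(functional, qtl_pairs, interactions,
                                 coloc_genes, snps, promoters,
                                 min_qtl_datasets = 2L,
                                 min_interaction_datasets = 2L,
                                 pp4_min = 0.8) {
  pairs <- qtl_pairs
  func_ids <- functional$snp_id[functional$functional]
  pairs$functional <- pairs$snp_id %in% func_ids

  # local iff the SNP lies in a promoter window of this gene
  pos <- snps$pos[match(pairs$snp_id, snps$snp_id)]
  chrom <- snps$chrom[match(pairs$snp_id, snps$snp_id)]
  pairs$pair_class <- rep("distal", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pw <- promoters[promoters$label == pairs$gene_id[i], , drop = FALSE]
    if (nrow(pw) > 0L && !is.na(pos[i]) &&
        any(pw$chrom == chrom[i] & pos[i] - 1 >= pw$start & pos[i] - 1 < pw$end))
      pairs$pair_class[i] <- "local"
  }

  ikey <- paste(interactions$snp_id, interactions$gene_id, sep = "\r")
  hit <- match(paste(pairs$snp_id, pairs$gene_id, sep = "\r"), ikey)
  pairs$interaction_dataset_count <-
    ifelse(is.na(hit), 0L, interactions$interaction_dataset_count[hit])

  pp4 <- tapply(coloc_genes$pp4, coloc_genes$gene_id, max)
  pairs$coloc_pp4_max <- as.numeric(pp4[pairs$gene_id])
  pairs$coloc_pp4_max[is.na(pairs$coloc_pp4_max)] <- 0

  pairs$predicted <- pairs$functional &
    pairs$qtl_dataset_count >= min_qtl_datasets &
    pairs$coloc_pp4_max > pp4_min &
    (pairs$pair_class == "local" |
       pairs$interaction_dataset_count >= min_interaction_datasets)

  pred <- pairs[pairs$predicted, , drop = FALSE]
  genes <- do.call(rbind, lapply(split(pred, pred$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1],
               n_pairs = nrow(g),
               n_local_pairs = sum(g$pair_class == "local"),
               n_distal_pairs = sum(g$pair_class == "distal"),
               gene_class = if (all(g$pair_class == "local")) "local" else "distal",
               exclusively_distal = all(g$pair_class == "distal"),
               stringsAsFactors = FALSE)))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(0), n_pairs = integer(0),
                        n_local_pairs = integer(0), n_distal_pairs = integer(0),
                        gene_class = character(0), exclusively_distal = logical(0))
  rownames(genes) <- NULL
  list(pairs = pairs, genes = genes)
}
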