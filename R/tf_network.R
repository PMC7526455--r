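# Regulatory TF analysis: enrichment of allele-specific motif TFs among
# functional SNPs, target assignment under three regulatory models
# (local / distal / indirect), and target sharing between TFs.

#' TF enrichment among functional SNPs
#'
#' For every TF with an allele-specific motif call, a Fisher exact test
#' compares its annotation rate among functional SNPs (with predicted
#' target genes) against all positive SNPs, with fold change of the two
#' proportions and Bonferroni correction over the number of TFs tested.
#' A TF is `enriched` iff `FC > 1` and `p < alpha / N_tfs`. TFs
#' annotating zero SNPs in both groups are skipped.
#'
#' @param functional_ids SNP ids of functional SNPs carrying predicted
#'   target genes
#' @param positive_ids SNP ids of the full positive set
#' @param motif_calls motif-call table (`snp_id`, `tf_name`); retained
#'   calls should be supplied
#' @param alpha family-wise level before Bonferroni division, default 0.05
#' @return `data.frame` per TF: counts, `fc`, `p`, `p_adj`, `enriched`
#' @export
enrich_tfs <- function(functional_ids, positive_ids, motif_calls,
                       alpha = 0.05) {
  calls <- motif_calls[motif_calls$snp_id %in% positive_ids, , drop = FALSE]
  tfs <- sort(unique(calls$tf_name))
  n_f <- length(unique(functional_ids))
  n_p <- length(unique(positive_ids))
  rows <- list()
  if (n_f == 0L || n_p == 0L) tfs <- character(0)  # nothing to compare against
  for (tf in tfs) {
    ids <- unique(calls$snp_id[calls$tf_name == tf])
    a <- sum(ids %in% functional_ids)
    c_ <- length(ids)  # annotated among all positives
    if (a == 0L && c_ == 0L) next
    t <- association_test_2x2(a, n_f - a, c_, n_p - c_, method = "fisher")
    rows[[tf]] <- data.frame(tf_name = tf, annotated_functional = a,
                             n_functional = n_f, annotated_positive = c_,
                             n_positive = n_p,
                             fc = as.numeric(fold_change(a, n_f, c_, n_p)),
                             p = t$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tf_name = character(0), annotated_functional = integer(0),
                      n_functional = integer(0), annotated_positive = integer(0),
                      n_positive = integer(0), fc = numeric(0), p = numeric(0),
                      p_adj = numeric(0), enriched = logical(0)))
  out$p_adj <- adjust_pvalues(out$p, "bonferroni")
  out$enriched <- is.finite(out$fc) & out$fc > 1 & out$p < alpha / nrow(out)
  rownames(out) <- NULL
  out
}

#' Assign target genes to enriched TFs under three regulatory models
#'
#' Direct edges: for an enriched TF `T` with an allele-specific motif call
#' on SNP `s` and a predicted pair `(s, g)`, the edge `(T, g)` carries the
#' pair's class — *local* (TF bound in the gene's promoter) or *distal*
#' (TF bound at a distal element looping to the gene). Indirect edges:
#' `(T, g')` where some enriched TF `U`'s encoding gene is a direct
#' target of `T` and `g'` is a direct target of `U` — exactly one
#' mediation hop, which avoids cycles. A gene may carry several models
#' for the same TF.
#'
#' @param enriched_tfs TF names (e.g. `enrich_tfs()` rows with
#'   `enriched = TRUE`)
#' @param motif_calls motif-call table (`snp_id`, `tf_name`, retained
#'   calls)
#' @param predicted_pairs predicted SNP-gene pairs with `pair_class`
#'   ([predict_target_genes()] `$pairs`, predicted rows)
#' @param tf_gene_map `data.frame` mapping `tf_name` to the `gene_id`
#'   encoding it; TFs without a mapping keep their direct edges but
#'   cannot mediate indirect ones (message emitted)
#' @param dedup_indirect drop indirect edges to genes the same TF already
#'   reaches directly (default `FALSE`: both tallies visible)
#' @return edge `data.frame`: `tf_name`, `gene_id`, `model`, `via`
#'   (supporting SNP for direct edges, mediating TF for indirect ones)
#' @export
assign_tf_targets <- function(enriched_tfs, motif_calls, predicted_pairs,
                              tf_gene_map, dedup_indirect = FALSE) {
  calls <- motif_calls[motif_calls$tf_name %in% enriched_tfs, , drop = FALSE]
  pred <- if (is.null(predicted_pairs$predicted)) predicted_pairs
          else predicted_pairs[predicted_pairs$predicted, , drop = FALSE]
  direct <- merge(calls[, c("snp_id", "tf_name")],
                  pred[, c("snp_id", "gene_id", "pair_class")], by = "snp_id")
  direct <- unique(data.frame(tf_name = direct$tf_name,
                              gene_id = direct$gene_id,
                              model = direct$pair_class,
                              via = direct$snp_id, stringsAsFactors = FALSE))
  unmapped <- setdiff(enriched_tfs, tf_gene_map$tf_name)
  if (length(unmapped) > 0L)
    message(length(unmapped), " enriched TF(s) without a gene mapping; ",
            "they cannot seed indirect edges")
  tf_of_gene <- stats::setNames(tf_gene_map$tf_name, tf_gene_map$gene_id)
  indirect <- list()
  for (tf in unique(direct$tf_name)) {
    tgt <- direct$gene_id[direct$tf_name == tf]
    mediators <- unique(stats::na.omit(tf_of_gene[tgt]))   # TF genes T targets
    mediators <- intersect(mediators, enriched_tfs)
    mediators <- setdiff(mediators, tf)
    for (u in mediators) {
      g2 <- unique(direct$gene_id[direct$tf_name == u])
      if (length(g2) > 0L)
        indirect[[paste(tf, u)]] <-
          data.frame(tf_name = tf, gene_id = g2, model = "indirect",
                     via = u, stringsAsFactors = FALSE)
    }
  }
  edges <- rbind(direct, do.call(rbind, indirect))
  if (is.null(edges))
    edges <- data.frame(tf_name = character(0), gene_id = character(0),
                        model = character(0), via = character(0))
  edges <- unique(edges)
  if (dedup_indirect && nrow(edges) > 0L) {
    dkey <- paste(edges$tf_name, edges$gene_id)[edges$model != "indirect"]
    drop <- edges$model == "indirect" &
      paste(edges$tf_name, edges$gene_id) %in% dkey
    edges <- edges[!drop, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Shared-target counts between TFs and a greedy covering TF set
#'
#' Pairwise counts of shared target genes between TFs, plus a covering
#' subset: TFs are greedily picked by largest remaining coverage of the
#' union of all targets (ties broken by TF name) until every target of
#' every TF is covered.
#'
#' @param edges edge table from [assign_tf_targets()]
#' @return list with `shared` (symmetric TF x TF count matrix) and
#'   `cover` (character vector of covering TF names, in pick order)
#' @export
shared_target_matrix <- function(edges) {
  tfs <- sort(unique(edges$tf_name))
  targets <- lapply(stats::setNames(tfs, tfs),
                    function(tf) unique(edges$gene_id[edges$tf_name == tf]))
  shared <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (i in seq_along(tfs)) for (j in seq_along(tfs))
    shared[i, j] <- length(intersect(targets[[i]], targets[[j]]))
  universe <- unique(edges$gene_id)
  remaining <- universe
  cover <- character(0)
  avail <- tfs
  while (length(remaining) > 0L && length(avail) > 0L) {
    gain <- vapply(targets[avail], function(t) length(intersect(t, remaining)),
                   integer(1))
    if (max(gain) == 0L) break
    pick <- avail[order(-gain, avail)][1]   # largest gain, ties by name
    cover <- c(cover, pick)
    remaining <- setdiff(remaining, targets[[pick]])
    avail <- setdiff(avail, pick)
  }
  list(shared = shared, cover = cover)
}

#' Export a TF-gene edge list as SIF
#'
#' Simple interaction format: `tf<TAB>model<TAB>gene`, one edge per line.
#' @param edges edge table from [assign_tf_targets()]
#' @param path output path
#' @export
write_sif <- function(edges, path) {
  utils::write.table(edges[, c("tf_name", "model", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}
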