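# Gene-level immunological function tiers, over-representation testing,
# drug/druggability annotation, and rule-based new drug-target prediction
# over a protein-protein interaction network.

#' Annotate immunological function tiers per gene
#'
#' Flags are taken from user-supplied annotation tables. The tier logic:
#' *high* support requires membership in immune-relevant pathways, IMPC
#' immune-phenotype knockouts, or OMIM immunological Mendelian disorders;
#' *suggestive* support is any of blood expression (RPKM > 1),
#' blood-specific expression (TSEA pSI < 0.01), DisGeNET immune-disease
#' association, or SMR causality (input already filtered to FDR < 0.05
#' with heterogeneity p > 0.05) without high support; genes in no table
#' get tier *none*.
#'
#' @param genes character vector of gene ids
#' @param tables named list of character vectors of gene ids, with any of
#'   the names `pathway_immune`, `impc_immune`, `omim_immune`,
#'   `expressed_blood`, `tsea_blood`, `disgenet_immune`, `smr_causal`
#' @return `data.frame` with one logical column per flag, plus `tier`
#' @export
annotate_gene_function <- function(genes, tables) {
  flags <- c("pathway_immune", "impc_immune", "omim_immune",
             "expressed_blood", "tsea_blood", "disgenet_immune", "smr_causal")
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (f in flags) out[[f]] <- genes %in% (tables[[f]] %||% character(0))
  high <- out$pathway_immune | out$impc_immune | out$omim_immune
  sugg <- out$expressed_blood | out$tsea_blood | out$disgenet_immune |
    out$smr_causal
  out$tier <- ifelse(high, "high", ifelse(sugg, "suggestive", "none"))
  out
}

#' Hypergeometric over-representation test for gene sets
#'
#' One-sided hypergeometric p-value for observing at least the overlap of
#' the gene set with each pathway, drawn from the supplied universe, with
#' Benjamini-Hochberg correction across pathways (ties in the BH sort are
#' broken by pathway id, so the adjusted values are reproducible). Empty
#' pathways are skipped.
#'
#' @param gene_set character vector, must be a subset of `universe`
#' @param pathways named list of character vectors (pathway gene sets)
#' @param universe character vector of all testable genes
#' @return `data.frame` per pathway: `pathway`, `overlap`, `pathway_size`,
#'   `set_size`, `universe_size`, `p`, `fdr`, sorted by pathway id
#' @export
ora_test <- function(gene_set, pathways, universe) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  pathways <- pathways[order(names(pathways))]
  pathways <- Filter(function(p) length(intersect(p, universe)) > 0L, pathways)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    k <- length(intersect(gene_set, pw))
    # P(X >= k), X ~ Hypergeom(|pathway| white, rest black, |set| drawn)
    p <- stats::phyper(k - 1, length(pw), length(universe) - length(pw),
                       length(gene_set), lower.tail = FALSE)
    data.frame(pathway = nm, overlap = k, pathway_size = length(pw),
               set_size = length(gene_set), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(0), overlap = integer(0),
                      pathway_size = integer(0), set_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      fdr = numeric(0)))
  out$fdr <- adjust_pvalues(out$p, "bh")
  rownames(out) <- NULL
  out
}

#' Build per-gene drug and druggability annotations
#'
#' Unions drugs and indication classes per gene, counts druggability
#' resources, and applies the two-resource druggability rule. Indications
#' missing from the class mapping fall into class `"other"` (message
#' emitted).
#'
#' @param drug_table `data.frame` with `gene_id`, `drug_id`, `indication`
#' @param druggability named list: resource name -> character vector of
#'   druggable gene ids
#' @param indication_classes `data.frame` mapping `indication` to `class`
#'   (one of `autoimmune`, `immune_related`, `other`)
#' @return `data.frame` per gene: `gene_id`, `drugs`, `indication_classes`
#'   (pipe-separated), `druggable_resource_count`, `druggable`,
#'   `known_drug_target`
#' @export
build_drug_annotations <- function(drug_table, druggability,
                                   indication_classes) {
  cls <- stats::setNames(indication_classes$class, indication_classes$indication)
  drug_table$class <- as.character(cls[drug_table$indication])
  n_unmapped <- sum(is.na(drug_table$class))
  if (n_unmapped > 0L) {
    message(n_unmapped, " drug indication(s) missing from the class mapping; ",
            "classed 'other'")
    drug_table$class[is.na(drug_table$class)] <- "other"
  }
  genes <- sort(unique(c(drug_table$gene_id, unlist(druggability))))
  per_gene <- lapply(genes, function(g) {
    rows <- drug_table[drug_table$gene_id == g, , drop = FALSE]
    n_res <- sum(vapply(druggability, function(r) g %in% r, logical(1)))
    data.frame(gene_id = g,
               drugs = paste(sort(unique(rows$drug_id)), collapse = "|"),
               indication_classes = paste(sort(unique(rows$class)),
                                          collapse = "|"),
               druggable_resource_count = n_res,
               druggable = n_res >= 2L,
               known_drug_target = nrow(rows) > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}

#' Indication-class sharing counts
#'
#' Venn-style tallies of drug-target genes per indication-class
#' combination (how many genes carry autoimmune plus immune-related
#' indications, and so on).
#'
#' @param drug_records output of [build_drug_annotations()]
#' @return table of counts keyed by the pipe-separated class combination
#' @export
indication_class_sharing <- function(drug_records) {
  x <- drug_records$indication_classes[drug_records$known_drug_target]
  table(x)
}

#' Predict new drug-target genes over the PPI network
#'
#' Candidate gene `A` is predicted as a new drug target for disease `B`
#' when all three rules hold: (a) `A` has a strong PPI
#' (score > `ppi_min`) with some drug-target gene `C` already indicated
#' for autoimmune disease `B`; (b) both `A` and `C` are regulated by
#' upstream functional SNPs predisposing to `B`; and (c) `A` is itself a
#' known drug target or predicted druggable gene. Predictions are
#' deduplicated per `(A, B)`, with partners concatenated; the
#' `repurposing_flag` marks candidates that already have a drug for a
#' different indication.
#'
#' @param gene_diseases `data.frame` with `gene_id`, `disease`: the
#'   diseases whose functional SNPs regulate each predicted target gene
#' @param drug_records [build_drug_annotations()] output
#' @param drug_table the drug-indication table (`gene_id`, `drug_id`,
#'   `indication`) used to resolve disease-level indications
#' @param ppi `data.frame` with `gene_a`, `gene_b`, `score` in `[0, 1]`
#'   (undirected)
#' @param ppi_min strict PPI threshold, default 0.9
#' @return `data.frame`: `candidate_gene`, `disease`, `partner_genes`,
#'   `repurposing_flag`
#' @export
predict_new_drug_targets <- function(gene_diseases, drug_records, drug_table,
                                     ppi, ppi_min = 0.9) {
  strong <- ppi[ppi$score > ppi_min, , drop = FALSE]
  strong <- rbind(strong[, c("gene_a", "gene_b")],
                  stats::setNames(strong[, c("gene_b", "gene_a")],
                                  c("gene_a", "gene_b")))
  eligible <- drug_records$gene_id[drug_records$known_drug_target |
                                     drug_records$druggable]
  out <- list()
  for (i in seq_len(nrow(gene_diseases))) {
    A <- gene_diseases$gene_id[i]
    B <- gene_diseases$disease[i]
    if (!(A %in% eligible)) next                               # rule (c)
    partners <- strong$gene_b[strong$gene_a == A]              # rule (a): strong PPI
    # C must be a drug target indicated for B ...
    cands <- unique(drug_table$gene_id[drug_table$indication == B])
    # ... and regulated by functional SNPs predisposing to B (rule b for C;
    # rule b holds for A by construction of gene_diseases)
    reg_b <- gene_diseases$gene_id[gene_diseases$disease == B]
    C <- setdiff(intersect(intersect(partners, cands), reg_b), A)
    if (length(C) == 0L) next
    has_other <- any(drug_table$gene_id == A & drug_table$indication != B)
    out[[paste(A, B)]] <- data.frame(
      candidate_gene = A, disease = B,
      partner_genes = paste(sort(C), collapse = "|"),
      repurposing_flag = has_other, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(candidate_gene = character(0), disease = character(0),
                      partner_genes = character(0), repurposing_flag = logical(0))
  res <- unique(res)
  rownames(res) <- NULL
  res
}
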