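# Allele-specific regulatory evidence: motif gain/loss calls from PWM
# scanning of the two alleles, molecular-QTL filtering, and the final
# functional-SNP conjunction (epigenetic support AND allelic evidence).

#' Allele-specific motif calls for one SNP
#'
#' For every motif, the windows overlapping the SNP are scored for the
#' reference and the alternate allele. A TF binding call is
#' allele-specific when exactly one allele's best SNP-overlapping hit
#' passes the p-value threshold: `gain` when the alternate allele passes,
#' `loss` when only the reference does. Calls are then aggregated per TF
#' (names uppercased): the supporting databases of a (TF, direction) call
#' are counted, and the call is `retained` only with support from at
#' least 2 databases and a TF expressed in the configured cell panel.
#'
#' @param snp_id SNP identifier carried through to the output
#' @param flank reference-allele flanking sequence containing the SNP
#' @param snp_offset 1-based position of the SNP within `flank`; the
#'   flank must extend at least `L - 1` bases each side for a length-`L`
#'   motif, otherwise that motif is skipped with a message
#' @param ref,alt single-base alleles; `flank` must carry `ref` at
#'   `snp_offset`
#' @param pwms list of [pwm()] objects
#' @param expressed_tfs uppercased names of TFs expressed (RPKM > 1) in at
#'   least one configured immune cell type; `NULL` bypasses the filter
#'   with a warning
#' @param p_threshold motif hit threshold, default 1e-4
#' @param background base frequencies for scoring
#' @param scanners optional list of precomputed [pwm_scanner()]s parallel
#'   to `pwms`
#' @return `data.frame` with columns `snp_id`, `tf_name`, `direction`,
#'   `n_databases`, `databases`, `expressed_tf`, `retained`
#' @export
call_allelic_motifs <- function(snp_id, flank, snp_offset, ref, alt, pwms,
                                expressed_tfs = NULL, p_threshold = 1e-4,
                                background = rep(0.25, 4), scanners = NULL) {
  if (is.null(expressed_tfs))
    warning("no TF expression table supplied; expression filter bypassed")
  if (is.null(scanners)) scanners <- lapply(pwms, pwm_scanner, background)
  flank <- toupper(flank)
  if (substr(flank, snp_offset, snp_offset) != toupper(ref))
    stop("flank sequence does not carry the reference allele at snp_offset")
  calls <- list()
  for (pi in seq_along(pwms)) {
    p <- pwms[[pi]]
    L <- nrow(p$mat)
    lo <- snp_offset - L + 1L
    hi <- snp_offset + L - 1L
    if (lo < 1L || hi > nchar(flank)) {
      message("flank too short for motif ", p$tf_name, " (", p$database,
              "); skipped for ", snp_id)
      next
    }
    sub_ref <- substr(flank, lo, hi)          # every window here overlaps the SNP
    sub_alt <- sub_ref
    substr(sub_alt, L, L) <- toupper(alt)
    hit_ref <- scan_pwm(sub_ref, p, background, p_threshold,
                        scanner = scanners[[pi]])
    hit_alt <- scan_pwm(sub_alt, p, background, p_threshold,
                        scanner = scanners[[pi]])
    ref_pass <- any(hit_ref$pass)
    alt_pass <- any(hit_alt$pass)
    if (xor(ref_pass, alt_pass))
      calls[[length(calls) + 1L]] <-
        data.frame(tf_name = p$tf_name,
                   direction = if (alt_pass) "gain" else "loss",
                   database = p$database, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L)
    return(data.frame(snp_id = character(0), tf_name = character(0),
                      direction = character(0), n_databases = integer(0),
                      databases = character(0), expressed_tf = logical(0),
                      retained = logical(0)))
  calls <- do.call(rbind, calls)
  # consensus requires the same TF and the same direction across databases
  key <- paste(calls$tf_name, calls$direction, sep = "\r")
  agg <- lapply(split(calls, key), function(g)
    data.frame(tf_name = g$tf_name[1], direction = g$direction[1],
               n_databases = length(unique(g$database)),
               databases = paste(sort(unique(g$database)), collapse = "|"),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out$expressed_tf <- if (is.null(expressed_tfs)) TRUE
                      else out$tf_name %in% toupper(expressed_tfs)
  out$retained <- out$n_databases >= 2L & out$expressed_tf
  out <- cbind(snp_id = snp_id, out)
  rownames(out) <- NULL
  out
}

#' Allele-specific motif scan over a SNP set
#'
#' Applies [call_allelic_motifs()] to each SNP, drawing flank sequences
#' from a named vector/`DNAStringSet` (names = SNP ids, SNP carried on
#' the reference allele at the centre position). SNPs without a flank
#' sequence are skipped with a message.
#'
#' @param snps `data.frame` with `snp_id`, `ref`, `alt`
#' @param flanks named character vector or `Biostrings::DNAStringSet` of
#'   reference flanks, SNP at position `(width + 1) / 2`
#' @inheritParams call_allelic_motifs
#' @return row-bound `data.frame` of per-SNP calls
#' @export
allelic_motif_scan <- function(snps, flanks, pwms, expressed_tfs = NULL,
                               p_threshold = 1e-4, background = rep(0.25, 4)) {
  if (is.null(expressed_tfs))
    warning("no TF expression table supplied; expression filter bypassed")
  if (methods::is(flanks, "DNAStringSet"))
    flanks <- stats::setNames(as.character(flanks), names(flanks))
  scanners <- lapply(pwms, pwm_scanner, background)
  out <- vector("list", nrow(snps))
  skipped <- 0L
  for (i in seq_len(nrow(snps))) {
    fl <- flanks[[snps$snp_id[i]]]
    if (is.null(fl) || is.na(fl)) { skipped <- skipped + 1L; next }
    out[[i]] <- suppressWarnings(call_allelic_motifs(
      snps$snp_id[i], fl, (nchar(fl) + 1L) %/% 2L,
      snps$ref[i], snps$alt[i], pwms, expressed_tfs = expressed_tfs,
      p_threshold = p_threshold, background = background,
      scanners = scanners))
  }
  if (skipped > 0L) message(skipped, " SNP(s) without flank sequence; skipped")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(snp_id = character(0), tf_name = character(0),
                      direction = character(0), n_databases = integer(0),
                      databases = character(0), expressed_tf = logical(0),
                      retained = logical(0))
  res
}

#' Filter molecular-QTL evidence to significant local associations
#'
#' Molecular QTLs (bQTL, hQTL, caQTL, dsQTL) count as allelic evidence
#' only when the SNP sits inside the associated molecular peak (a *local*
#' SNP-peak pair) and the association survives FDR < `fdr_max`. When a
#' dataset lacks a precomputed FDR column, Benjamini-Hochberg is applied
#' to its raw p-values within the dataset. Rows without peak coordinates
#' cannot be classified local/distal and are dropped (count reported as
#' attribute `"dropped"`).
#'
#' @param qtl `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `peak_start`, `peak_end` (BED convention), `assay`, `cell_type`,
#'   `dataset_id`, and `p` and/or `fdr`
#' @param fdr_max significance cut-off, default 0.1
#' @return the significant local subset, with `local` and `fdr` columns
#'   filled in
#' @export
filter_molecular_qtl <- function(qtl, fdr_max = 0.1) {
  has_peak <- !(is.na(qtl$peak_start) | is.na(qtl$peak_end))
  dropped <- sum(!has_peak)
  qtl <- qtl[has_peak, , drop = FALSE]
  if (is.null(qtl$fdr)) qtl$fdr <- NA_real_
  for (ds in unique(qtl$dataset_id)) {
    i <- qtl$dataset_id == ds
    if (any(is.na(qtl$fdr[i])))
      qtl$fdr[i] <- adjust_pvalues(qtl$p[i], "bh")
  }
  same_chrom <- if (is.null(qtl$peak_chrom)) TRUE else qtl$peak_chrom == qtl$chrom
  qtl$local <- qtl$pos - 1 >= qtl$peak_start & qtl$pos - 1 < qtl$peak_end &
    same_chrom
  out <- qtl[qtl$local & qtl$fdr < fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Prioritize functional SNPs
#'
#' The final call of the prioritization stage: a positive SNP is
#' *functional* iff it has epigenetic functionality support in at least
#' one category AND at least one piece of allele-specific regulatory
#' evidence (a retained motif call or a significant local molecular QTL).
#'
#' @param epi_support per-SNP support table from [epigenetic_support()]
#' @param motif_calls calls from [allelic_motif_scan()]; only `retained`
#'   rows count
#' @param qtl_evidence significant rows from [filter_molecular_qtl()]
#' @return `data.frame` keyed by `snp_id` with `n_categories`, per-assay
#'   evidence flags (`motif`, `bQTL`, `hQTL`, `caQTL`, `dsQTL`),
#'   `n_allelic`, and the `functional` flag
#' @export
prioritize_functional_snps <- function(epi_support, motif_calls, qtl_evidence) {
  ids <- epi_support$snp_id
  motif_ids <- unique(motif_calls$snp_id[motif_calls$retained])
  out <- data.frame(snp_id = ids,
                    n_categories = epi_support$n_categories,
                    motif = ids %in% motif_ids,
                    stringsAsFactors = FALSE)
  for (assay in c("bQTL", "hQTL", "caQTL", "dsQTL")) {
    a_ids <- unique(qtl_evidence$snp_id[qtl_evidence$assay == assay])
    out[[assay]] <- ids %in% a_ids
  }
  out$n_allelic <- rowSums(out[, c("motif", "bQTL", "hQTL", "caQTL", "dsQTL")])
  out$functional <- out$n_categories >= 1L & out$n_allelic >= 1L
  out
}
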