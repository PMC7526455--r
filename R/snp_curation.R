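# SNP curation: building the positive / background / negative variant
# universe from tag SNPs, LD structure and genome-wide significant loci.
#
# Disease labels travel as a single `diseases` column, pipe-separated;
# helpers below split/join so set semantics (union, no duplicates) hold.

.split_diseases <- function(x) {
  x <- as.character(x)
  if (length(x) == 0L) return(list())
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), "|", fixed = TRUE),
         function(d) sort(unique(d[d != ""])))
}

.join_diseases <- function(x) {
  vapply(x, function(d) paste(d, collapse = "|"), character(1))
}

#' Squared LD correlation from phased haplotypes
#'
#' Standard haplotype-frequency r-squared for two biallelic SNPs:
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`. This equals
#' the squared Pearson correlation of the two 0/1 allele indicator
#' vectors. A monomorphic SNP has no defined LD and returns `NA`.
#'
#' @param hap_a,hap_b 0/1 vectors, one entry per phased haplotype
#' @return r-squared in `[0, 1]`, or `NA` when either SNP is monomorphic
#' @export
compute_r2 <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) stop("haplotype vectors differ in length")
  if (length(hap_a) < 2L) stop("need at least 2 haplotypes")
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1)))
    stop("haplotypes must be coded 0/1 (biallelic, phased)")
  pa <- mean(hap_a); pb <- mean(hap_b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(hap_a == 1 & hap_b == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Normalise an LD table to both orientations so lookups are symmetric.
.symmetrize_ld <- function(ld) {
  rbind(ld[, c("snp_a", "snp_b", "r2")],
        stats::setNames(ld[, c("snp_b", "snp_a", "r2")],
                        c("snp_a", "snp_b", "r2")))
}

#' Expand tag SNPs into the positive set through LD
#'
#' The positive set is the noncoding tag SNPs together with every SNP in
#' strong LD (`r2 > r2_min`) with at least one tag. Disease labels
#' propagate from every linked tag (union). Coding or splicing variants
#' are excluded on both sides. A tag absent from the LD table is retained
#' alone (with a message) rather than dropped.
#'
#' @param tags `data.frame` with `snp_id`, `chrom`, `pos`, `diseases`
#'   (pipe-separated) and `coding_flag`
#' @param ld_pairs `data.frame` with `snp_a`, `snp_b`, `r2` (within the
#'   maximum LD distance; orientation immaterial)
#' @param snps SNP universe `data.frame` with `snp_id`, `chrom`, `pos`,
#'   `coding_flag`, supplying coordinates and coding status for proxies
#' @param r2_min strict LD threshold, default 0.8
#' @return `data.frame` of positive SNPs: `snp_id`, `chrom`, `pos`,
#'   `diseases`, `is_tag`, `snp_class = "positive"`
#' @export
expand_tags <- function(tags, ld_pairs, snps, r2_min = 0.8) {
  tags <- tags[!tags$coding_flag, , drop = FALSE]
  ld <- .symmetrize_ld(ld_pairs)
  ld <- ld[ld$snp_a %in% tags$snp_id & ld$r2 > r2_min, , drop = FALSE]

  missing_ld <- setdiff(tags$snp_id, unique(c(ld_pairs$snp_a, ld_pairs$snp_b)))
  if (length(missing_ld) > 0L)
    message(length(missing_ld), " tag SNP(s) absent from the LD table; retained alone")

  tag_dis <- .split_diseases(tags$diseases)
  names(tag_dis) <- tags$snp_id

  # proxy -> union of diseases over all linked tags
  prox <- split(ld$snp_a, ld$snp_b)
  prox_dis <- lapply(prox, function(ts) sort(unique(unlist(tag_dis[ts]))))
  prox_ids <- setdiff(names(prox), tags$snp_id)

  uni <- snps[match(prox_ids, snps$snp_id), , drop = FALSE]
  keep <- !is.na(uni$snp_id) & !uni$coding_flag
  uni <- uni[keep, , drop = FALSE]

  out <- rbind(
    data.frame(snp_id = tags$snp_id, chrom = tags$chrom, pos = tags$pos,
               diseases = .join_diseases(tag_dis), is_tag = TRUE,
               stringsAsFactors = FALSE),
    data.frame(snp_id = uni$snp_id, chrom = uni$chrom, pos = uni$pos,
               diseases = .join_diseases(prox_dis[uni$snp_id]),
               is_tag = rep(FALSE, nrow(uni)),
               stringsAsFactors = FALSE)
  )
  # tags that are each other's proxies: tag status and label union win
  out <- out[!duplicated(out$snp_id), , drop = FALSE]
  out$snp_class <- "positive"
  rownames(out) <- NULL
  out
}

#' Define genome-wide significant loci around tag SNPs
#'
#' Each tag contributes a window of `flank` bp on either side of its
#' position; overlapping windows are merged, and any overlap with the MHC
#' region is cut out (which can split a locus into two segments or remove
#' it entirely).
#'
#' @param tags `data.frame` with `chrom` and `pos` (1-based)
#' @param flank half-width of the per-tag window, default 1 Mb
#' @param mhc the MHC region as a single-row interval `data.frame`
#'   ([gintervals()]); default chr6:25-35 Mb (hg19-style coordinates,
#'   configurable because no canonical boundary exists)
#' @return list with `loci` (merged, MHC-truncated interval table) and
#'   `mhc`
#' @export
define_loci <- function(tags, flank = 1e6,
                        mhc = gintervals("chr6", 25e6, 35e6, "MHC")) {
  if (nrow(tags) == 0L) stop("no tag SNPs supplied")
  win <- gintervals(tags$chrom, pmax(0, tags$pos - 1 - flank), tags$pos + flank)
  loci <- .subtract_intervals(.reduce_intervals(win), mhc)
  list(loci = loci, mhc = mhc)
}

#' Classify the SNP universe into positive / background / negative
#'
#' Precedence: positive (from [expand_tags()]) > background (noncoding,
#' inside a locus) > negative (noncoding, outside all loci and the MHC,
#' with max `r2 < r2_exclude` to every GWAS-catalog SNP). Anything left
#' over — coding SNPs outside loci, or SNPs excluded only by catalog LD —
#' is classed `"excluded"` and reported.
#'
#' @param snps SNP universe with `snp_id`, `chrom`, `pos`, `coding_flag`
#' @param positives positive set from [expand_tags()]
#' @param locus_set list from [define_loci()]
#' @param catalog_ld LD table (`snp_a`, `snp_b`, `r2`) linking universe
#'   SNPs to catalog SNPs (either orientation)
#' @param catalog_snps character vector of catalog SNP ids
#' @param r2_exclude catalog-LD exclusion threshold, default 0.1
#' @return `snps` with an added `snp_class` column
#' @export
classify_snps <- function(snps, positives, locus_set, catalog_ld = NULL,
                          catalog_snps = character(0), r2_exclude = 0.1) {
  in_locus <- overlap_annotate(snps, locus_set$loci)
  in_mhc <- overlap_annotate(snps, locus_set$mhc)

  max_cat_r2 <- rep(0, nrow(snps))
  if (!is.null(catalog_ld) && length(catalog_snps) > 0L && nrow(catalog_ld) > 0L) {
    ld <- .symmetrize_ld(catalog_ld)
    ld <- ld[ld$snp_a %in% catalog_snps, , drop = FALSE]
    if (nrow(ld) > 0L) {
      agg <- tapply(ld$r2, ld$snp_b, max)
      hit <- match(snps$snp_id, names(agg))
      max_cat_r2[!is.na(hit)] <- agg[hit[!is.na(hit)]]
    }
  }

  cls <- rep("excluded", nrow(snps))
  noncoding <- !snps$coding_flag
  cls[noncoding & in_locus] <- "background"
  cls[noncoding & !in_locus & !in_mhc & max_cat_r2 < r2_exclude] <- "negative"
  cls[snps$snp_id %in% positives$snp_id] <- "positive"

  n_exc <- sum(cls == "excluded")
  if (n_exc > 0L)
    message(n_exc, " SNP(s) fall in no class (coding outside loci, or ",
            "catalog-linked outside loci); classed 'excluded'")
  snps$snp_class <- cls
  snps
}
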