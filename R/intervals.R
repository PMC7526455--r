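#' Construct a genomic-interval table (BED convention)
#'
#' Intervals throughout the package follow the BED convention: 0-based,
#' half-open `[start, end)`. SNP positions are 1-based (VCF convention);
#' the conversion between the two conventions happens in exactly one place,
#' [overlap_annotate()], so off-by-one drift cannot accumulate.
#'
#' @param chrom chromosome names
#' @param start 0-based inclusive starts
#' @param end exclusive ends; must satisfy `0 <= start < end`
#' @param label optional label (e.g. gene id or feature id) recycled along
#'   the intervals
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `label`
#' @export
gintervals <- function(chrom, start, end, label = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0 (0-based BED convention)")
  if (any(end <= start)) stop("interval end must exceed start (half-open convention)")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             label = rep_len(as.character(label), length(chrom)),
             stringsAsFactors = FALSE)
}

# BED [start,end) -> GRanges (1-based closed): start+1 .. end
.intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# 1-based SNP positions -> width-1 GRanges
.snps_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
}

#' Read a BED file (3+ columns) into an interval table
#'
#' Columns beyond the fourth are ignored; a missing fourth column yields
#' `NA` labels. Gzipped files are handled transparently.
#'
#' @param path BED file path
#' @param label override label applied to every interval (default: the BED
#'   name column when present)
#' @return interval `data.frame` as from [gintervals()]
#' @export
read_bed <- function(path, label = NULL) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  lab <- if (!is.null(label)) label else if (ncol(x) >= 4) x[[4]] else NA_character_
  gintervals(x[[1]], x[[2]], x[[3]], lab)
}

#' Write an interval table as BED
#'
#' @param x interval `data.frame` ([gintervals()])
#' @param path output path
#' @export
write_bed <- function(x, path) {
  out <- x[, c("chrom", "start", "end")]
  if (!all(is.na(x$label))) out$name <- x$label
  utils::write.table(format(out, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Annotate SNP positions against a genomic-interval set
#'
#' A SNP at 1-based position `pos` is annotated by an interval iff
#' `pos - 1` lies in `[start, end)` — equivalently the width-1 base it
#' occupies intersects the interval. When the two inputs share no
#' chromosome name the result is all-`FALSE` with a warning (a chromosome
#' naming mismatch is almost always an input error, but not a fatal one).
#'
#' @param snps `data.frame` with columns `chrom` and `pos` (1-based)
#' @param intervals interval `data.frame` ([gintervals()])
#' @return logical vector along the rows of `snps`
#' @export
overlap_annotate <- function(snps, intervals) {
  if (nrow(snps) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, nrow(snps)))
  if (!any(unique(snps$chrom) %in% unique(intervals$chrom))) {
    warning("no shared chromosome names between SNPs and intervals; ",
            "returning empty overlap")
    return(rep(FALSE, nrow(snps)))
  }
  q <- .snps_to_granges(snps$chrom, snps$pos)
  s <- .intervals_to_granges(intervals)
  IRanges::overlapsAny(q, s)
}

# Overlap hits as (snp row, interval row) index pairs; used to build
# SNP x feature incidence matrices without materialising per-feature scans.
.overlap_hits <- function(snps, intervals) {
  if (nrow(snps) == 0L || nrow(intervals) == 0L)
    return(data.frame(snp = integer(0), interval = integer(0)))
  common <- intersect(unique(snps$chrom), unique(intervals$chrom))
  if (length(common) == 0L)
    return(data.frame(snp = integer(0), interval = integer(0)))
  q <- .snps_to_granges(snps$chrom, snps$pos)
  s <- .intervals_to_granges(intervals)
  h <- GenomicRanges::findOverlaps(q, s)
  data.frame(snp = S4Vectors::queryHits(h), interval = S4Vectors::subjectHits(h))
}

#' Promoter windows around transcript TSSs
#'
#' One interval per TSS: the 1-based positions `TSS - half_width` through
#' `TSS + half_width` ("1 kb surrounding TSS" at the default), expressed in
#' BED coordinates and clipped at 0. Gene models are supplied flattened:
#' one row per transcript TSS, so a gene with several alternative
#' promoters contributes several windows carrying the same `gene_id`.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `tss`
#'   (1-based); extra columns ignored
#' @param half_width window half-width in bp, allowed range 500-10000
#' @return interval `data.frame` labelled with `gene_id`
#' @export
promoter_windows <- function(genes, half_width = 1000) {
  stopifnot(half_width >= 500, half_width <= 10000)
  if (nrow(genes) == 0L)
    return(gintervals(character(0), numeric(0), numeric(0) + 1))
  start <- pmax(0, genes$tss - 1 - half_width)
  end <- genes$tss - 1 + half_width + 1
  gintervals(genes$chrom, start, end, genes$gene_id)
}

# Merge overlapping/adjacent-in-overlap intervals (labels dropped).
.reduce_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  g <- GenomicRanges::reduce(.intervals_to_granges(x))
  gintervals(as.character(GenomicRanges::seqnames(g)),
             GenomicRanges::start(g) - 1L, GenomicRanges::end(g))
}

# Subtract intervals in `y` from intervals in `x` (both BED convention).
.subtract_intervals <- function(x, y) {
  y <- y[y$chrom %in% x$chrom, , drop = FALSE]  # setdiff warns on foreign chroms
  if (nrow(x) == 0L || nrow(y) == 0L) return(.reduce_intervals(x))
  g <- GenomicRanges::setdiff(.intervals_to_granges(x), .intervals_to_granges(y))
  if (length(g) == 0L)
    return(gintervals(character(0), numeric(0), numeric(0) + 1)[0, ])
  gintervals(as.character(GenomicRanges::seqnames(g)),
             GenomicRanges::start(g) - 1L, GenomicRanges::end(g))
}
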