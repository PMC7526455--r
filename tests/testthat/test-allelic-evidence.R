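# Allele-specific motif calls, molecular-QTL filtering, and the final
# functional-SNP conjunction.

# A strong consensus motif whose only passing hit is the exact consensus
# word, in 1-3 database copies.
mk_consensus_pwms <- function(cons = "ACGTGACT", dbs = c("db1", "db2")) {
  b <- strsplit(cons, "")[[1]]
  m <- matrix(0.01, length(b), 4)
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- 0.97
  lapply(dbs, function(d) pwm("TFZ", d, m, pseudocount = 0))
}

# Flank with the consensus planted so the SNP (centre) sits at motif
# position `at`, carrying the consensus base as the reference allele.
mk_flank <- function(cons = "ACGTGACT", width = 41, at = 4) {
  set.seed(45)
  fl <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  centre <- (width + 1) %/% 2
  span <- (centre - at + 1):(centre - at + nchar(cons))
  fl[span] <- strsplit(cons, "")[[1]]
  paste(fl, collapse = "")
}

test_that("destroying a planted consensus match yields a retained loss call", {
  fl <- mk_flank()
  calls <- call_allelic_motifs("s1", fl, 21, ref = "T", alt = "G",
                               pwms = mk_consensus_pwms(),
                               expressed_tfs = "TFZ")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$direction, "loss")
  expect_equal(calls$n_databases, 2L)
  expect_true(calls$retained)
})

test_that("a call supported by a single database is not retained", {
  fl <- mk_flank()
  calls <- call_allelic_motifs("s1", fl, 21, "T", "G",
                               pwms = mk_consensus_pwms(dbs = "db1"),
                               expressed_tfs = "TFZ")
  expect_equal(calls$n_databases, 1L)
  expect_false(calls$retained)
})

test_that("an unexpressed TF is not retained and a missing table bypasses with warning", {
  fl <- mk_flank()
  calls <- call_allelic_motifs("s1", fl, 21, "T", "G", mk_consensus_pwms(),
                               expressed_tfs = "OTHERTF")
  expect_false(calls$retained)
  expect_warning(
    calls2 <- call_allelic_motifs("s1", fl, 21, "T", "G", mk_consensus_pwms()),
    "expression filter bypassed")
  expect_true(calls2$retained)
})

test_that("allelic calls are invariant under reverse complement of the locus", {
  fl <- mk_flank()
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(fl, "")[[1]]), collapse = ""))
  calls_f <- call_allelic_motifs("s1", fl, 21, "T", "G", mk_consensus_pwms(),
                                 expressed_tfs = "TFZ")
  calls_r <- call_allelic_motifs("s1", rc, 21, "A", "C", mk_consensus_pwms(),
                                 expressed_tfs = "TFZ")
  expect_equal(calls_f$direction, calls_r$direction)
  expect_equal(calls_f$retained, calls_r$retained)
})

test_that("a SNP that creates a new match is called as a gain", {
  cons <- "ACGTGACT"
  fl0 <- mk_flank(cons)
  # put a non-consensus reference base at the SNP position: ref fails,
  # alt (the consensus base) passes
  fl <- fl0
  substr(fl, 21, 21) <- "G"
  calls <- call_allelic_motifs("s1", fl, 21, "G", "T", mk_consensus_pwms(),
                               expressed_tfs = "TFZ")
  expect_equal(calls$direction, "gain")
})

test_that("molecular QTLs must be local and FDR-significant", {
  qtl <- data.frame(
    snp_id = c("a", "b", "c"), chrom = "chr1", pos = c(500, 500, 500),
    peak_chrom = "chr1",
    peak_start = c(400, 10400, 400), peak_end = c(700, 10700, 700),
    assay = "caQTL", cell_type = "LCL", dataset_id = "d1",
    p = c(1e-6, 1e-8, 0.2), fdr = c(0.05, 0.001, 0.5))
  kept <- filter_molecular_qtl(qtl)
  expect_equal(kept$snp_id, "a")   # b distal despite tiny fdr, c weak fdr
})

test_that("missing FDR columns are recomputed per dataset by Benjamini-Hochberg", {
  set.seed(46)
  p <- runif(40)
  qtl <- data.frame(snp_id = paste0("s", 1:40), chrom = "chr1",
                    pos = 500, peak_chrom = "chr1", peak_start = 400,
                    peak_end = 700, assay = "hQTL", cell_type = "LCL",
                    dataset_id = rep(c("d1", "d2"), each = 20), p = p)
  kept <- filter_molecular_qtl(qtl, fdr_max = 1.1)
  expect_equal(kept$fdr,
               c(p.adjust(p[1:20], "BH"), p.adjust(p[21:40], "BH")),
               tolerance = 1e-9)
})

test_that("rows without peak coordinates are dropped and counted", {
  qtl <- data.frame(snp_id = c("a", "b"), chrom = "chr1", pos = 500,
                    peak_chrom = "chr1", peak_start = c(400, NA),
                    peak_end = c(700, NA), assay = "bQTL",
                    cell_type = "LCL", dataset_id = "d1",
                    p = 1e-6, fdr = 0.01)
  kept <- filter_molecular_qtl(qtl)
  expect_equal(attr(kept, "dropped"), 1L)
  expect_equal(kept$snp_id, "a")
})

test_that("functional status needs both epigenetic support and allelic evidence", {
  support <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                        n_categories = c(1, 4, 0, 2))
  calls <- data.frame(snp_id = c("s1", "s3"), tf_name = "TFZ",
                      retained = c(TRUE, TRUE))
  qtl <- data.frame(snp_id = "s4", assay = "bQTL")
  fun <- prioritize_functional_snps(support, calls, qtl)
  got <- setNames(fun$functional, fun$snp_id)
  expect_true(got[["s1"]])    # support + motif
  expect_false(got[["s2"]])   # 4 categories but no allelic evidence
  expect_false(got[["s3"]])   # motif but no support
  expect_true(got[["s4"]])    # support + bQTL
  expect_equal(fun$bQTL, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("fixture functional SNPs are recovered exactly and decoys stay inert", {
  fun <- read.delim(file.path(fx_out, "functional.tsv"))
  called <- fun$snp_id[fun$functional]
  sens <- mean(fx_truth$functional_snps %in% called)
  expect_gte(sens, 0.9)
  # epigenetic-support-only decoys must never be called functional
  expect_false(any(fx_truth$epi_only_snps %in% called))
  # the functional set is a subset of the epigenetically supported positives
  support <- read.delim(file.path(fx_out, "support.tsv"))
  expect_true(all(called %in% support$snp_id[support$n_categories >= 1]))
})
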