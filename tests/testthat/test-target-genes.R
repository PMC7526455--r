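# cis-QTL validation, chromatin-interaction support, colocalization and
# target-gene prediction.

test_that("cis-QTL pairs need two distinct datasets to validate", {
  assocs <- data.frame(
    snp_id = c("s1", "s1", "s2", "s2"),
    gene_id = c("g1", "g1", "g2", "g2"),
    dataset_id = c("e1", "e2", "e1", "e1"),
    cell_type = "c", qtl_type = c("eQTL", "pQTL", "eQTL", "eQTL"),
    p = 1e-5, fdr = 0.01)
  res <- filter_cis_qtl(assocs)
  p <- res$pairs
  expect_true(p$validated[p$snp_id == "s1"])    # eQTL + pQTL datasets
  expect_false(p$validated[p$snp_id == "s2"])   # same dataset twice
  expect_equal(p$qtl_dataset_count[p$snp_id == "s1"], 2L)
})

test_that("cis-QTL FDR is recomputed by BH per dataset when missing", {
  set.seed(51)
  p <- runif(30)
  assocs <- data.frame(snp_id = paste0("s", 1:30), gene_id = "g1",
                       dataset_id = "e1", cell_type = "c", qtl_type = "eQTL",
                       p = p)
  res <- filter_cis_qtl(assocs, fdr_max = 1.1, min_datasets = 1L)
  expect_equal(res$assocs$fdr, p.adjust(p, "BH"), tolerance = 1e-9)
})

test_that("associations to genes without a TSS are dropped with a message", {
  assocs <- data.frame(snp_id = "s1", gene_id = c("known", "ghost"),
                       dataset_id = "e1", cell_type = "c",
                       qtl_type = "eQTL", p = 1e-5, fdr = 0.01)
  genes <- data.frame(gene_id = "known", tss = 100)
  expect_message(res <- filter_cis_qtl(assocs, genes), "dropped")
  expect_equal(unique(res$assocs$gene_id), "known")
})

test_that("a contact supports a pair only across anchors", {
  snps <- mk_snps(1000, ids = "s1")
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 50000)
  prom <- promoter_windows(genes)
  pairs <- data.frame(snp_id = "s1", gene_id = "g1")
  cross <- data.frame(chrom1 = "chr1", start1 = 500, end1 = 1500,
                      chrom2 = "chr1", start2 = 48000, end2 = 52000,
                      dataset_id = "hic1")
  expect_equal(interaction_support(pairs, snps, prom, cross)$
                 interaction_dataset_count, 1L)
  # SNP and promoter both only inside anchor1: no support
  same <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 60000,
                     chrom2 = "chr2", start2 = 0, end2 = 1000,
                     dataset_id = "hic1")
  expect_equal(interaction_support(pairs, snps, prom, same)$
                 interaction_dataset_count, 0L)
  # swapped orientation counts too, and datasets are deduplicated
  both <- rbind(cross,
                data.frame(chrom1 = "chr1", start1 = 48000, end1 = 52000,
                           chrom2 = "chr1", start2 = 500, end2 = 1500,
                           dataset_id = "hic1"))
  expect_equal(interaction_support(pairs, snps, prom, both)$
                 interaction_dataset_count, 1L)
})

test_that("interaction support equals a brute-force scan on random anchors", {
  set.seed(52)
  snps <- mk_snps(sample(1e6, 30))
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      tss = sample(1e6, 10))
  prom <- promoter_windows(genes)
  st1 <- sample(1e6, 60); st2 <- sample(1e6, 60)
  contacts <- data.frame(chrom1 = "chr1", start1 = st1, end1 = st1 + 20000,
                         chrom2 = "chr1", start2 = st2, end2 = st2 + 20000,
                         dataset_id = sample(c("d1", "d2", "d3"), 60, TRUE))
  pairs <- expand.grid(snp_id = snps$snp_id, gene_id = genes$gene_id,
                       stringsAsFactors = FALSE)
  got <- interaction_support(pairs, snps, prom, contacts)
  inside <- function(pos, s, e) pos - 1 >= s & pos - 1 < e
  for (i in sample(nrow(pairs), 40)) {
    pos <- snps$pos[snps$snp_id == pairs$snp_id[i]]
    pw <- prom[prom$label == pairs$gene_id[i], ]
    sup <- unique(contacts$dataset_id[vapply(seq_len(nrow(contacts)), function(k) {
      s_in1 <- inside(pos, contacts$start1[k], contacts$end1[k])
      s_in2 <- inside(pos, contacts$start2[k], contacts$end2[k])
      p_in1 <- any(pw$start < contacts$end1[k] & pw$end > contacts$start1[k])
      p_in2 <- any(pw$start < contacts$end2[k] & pw$end > contacts$start2[k])
      (s_in1 && p_in2) || (s_in2 && p_in1)
    }, logical(1))])
    expect_equal(got$interaction_dataset_count[i], length(sup))
  }
})

test_that("prediction enforces the local vs distal evidence rules", {
  snps <- mk_snps(c(1000, 200000), ids = c("sl", "sd"))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 1500)
  prom <- promoter_windows(genes)
  functional <- data.frame(snp_id = c("sl", "sd"), functional = TRUE)
  qtl_pairs <- data.frame(snp_id = c("sl", "sd"), gene_id = "g1",
                          qtl_dataset_count = 2L, validated = TRUE)
  coloc <- data.frame(gene_id = "g1", pp4 = 0.9)
  inter1 <- data.frame(snp_id = "sd", gene_id = "g1",
                       interaction_dataset_count = 1L)
  res1 <- predict_target_genes(functional, qtl_pairs, inter1, coloc,
                               snps, prom)
  p1 <- res1$pairs
  expect_true(p1$predicted[p1$snp_id == "sl"])    # local: no interactions needed
  expect_false(p1$predicted[p1$snp_id == "sd"])   # distal with 1 dataset only
  inter2 <- data.frame(snp_id = "sd", gene_id = "g1",
                       interaction_dataset_count = 2L)
  res2 <- predict_target_genes(functional, qtl_pairs, inter2, coloc,
                               snps, prom)
  expect_true(all(res2$pairs$predicted))
  expect_equal(res2$genes$gene_class, "distal")   # one local + one distal pair
  expect_false(res2$genes$exclusively_distal)
})

test_that("dropping any evidence leg can only shrink the prediction set", {
  snps <- mk_snps(c(1000, 200000), ids = c("sl", "sd"))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 1500)
  prom <- promoter_windows(genes)
  functional <- data.frame(snp_id = c("sl", "sd"), functional = TRUE)
  qtl_pairs <- data.frame(snp_id = c("sl", "sd"), gene_id = "g1",
                          qtl_dataset_count = 2L, validated = TRUE)
  inter <- data.frame(snp_id = "sd", gene_id = "g1",
                      interaction_dataset_count = 2L)
  coloc <- data.frame(gene_id = "g1", pp4 = 0.9)
  full <- predict_target_genes(functional, qtl_pairs, inter, coloc, snps, prom)
  base <- full$pairs$snp_id[full$pairs$predicted]
  weaker <- list(
    predict_target_genes(functional[functional$snp_id == "sl", ],
                         qtl_pairs, inter, coloc, snps, prom),
    predict_target_genes(functional, transform(qtl_pairs,
                                               qtl_dataset_count = 1L),
                         inter, coloc, snps, prom),
    predict_target_genes(functional, qtl_pairs, inter[0, ], coloc, snps, prom),
    predict_target_genes(functional, qtl_pairs, inter,
                         transform(coloc, pp4 = 0.5), snps, prom))
  for (w in weaker)
    expect_true(all(w$pairs$snp_id[w$pairs$predicted] %in% base))
})

test_that("fixture target genes are recovered exactly with correct classes", {
  pg <- read.delim(file.path(fx_out, "predicted_genes.tsv"))
  expect_setequal(pg$gene_id,
                  c(fx_truth$local_genes, fx_truth$distal_genes))
  expect_setequal(pg$gene_id[pg$gene_class == "local"], fx_truth$local_genes)
  expect_setequal(pg$gene_id[pg$gene_class == "distal"], fx_truth$distal_genes)
  expect_false(any(fx_truth$decoy_genes %in% pg$gene_id))
  # class labels partition the predicted genes
  expect_true(all(pg$gene_class %in% c("local", "distal")))
  pp <- read.delim(file.path(fx_out, "predicted_pairs.tsv"))
  pred <- pp[pp$predicted, ]
  expect_setequal(paste(pred$snp_id, pred$gene_id),
                  paste(fx_truth$pairs$snp_id, fx_truth$pairs$gene_id))
  # predicted pairs are a subset of the validated cis-QTL pair set
  cis <- read.delim(file.path(fx_out, "cis_pairs.tsv"))
  expect_true(all(paste(pred$snp_id, pred$gene_id) %in%
                    paste(cis$snp_id[cis$validated], cis$gene_id[cis$validated])))
})
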