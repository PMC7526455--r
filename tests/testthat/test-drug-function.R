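# Gene-function tiers, over-representation testing, and drug-target rules.

test_that("function tiers follow the high / suggestive / none hierarchy", {
  ann <- annotate_gene_function(
    c("g_omim", "g_expr", "g_none", "g_both"),
    list(omim_immune = c("g_omim", "g_both"),
         expressed_blood = c("g_expr", "g_both")))
  got <- setNames(ann$tier, ann$gene_id)
  expect_equal(got[["g_omim"]], "high")
  expect_equal(got[["g_expr"]], "suggestive")
  expect_equal(got[["g_none"]], "none")
  expect_equal(got[["g_both"]], "high")   # high beats suggestive
})

test_that("tier partition is mutually exclusive and exhaustive", {
  set.seed(81)
  genes <- paste0("g", 1:50)
  tables <- lapply(1:7, function(i) sample(genes, 10))
  names(tables) <- c("pathway_immune", "impc_immune", "omim_immune",
                     "expressed_blood", "tsea_blood", "disgenet_immune",
                     "smr_causal")
  ann <- annotate_gene_function(genes, tables)
  expect_true(all(ann$tier %in% c("high", "suggestive", "none")))
  high <- ann$pathway_immune | ann$impc_immune | ann$omim_immune
  expect_equal(ann$tier == "high", high)
})

test_that("hypergeometric ORA matches closed-form limits", {
  universe <- paste0("g", 1:30)
  gene_set <- universe[1:8]
  res <- ora_test(gene_set,
                  list(same = gene_set, disjoint = universe[9:20]),
                  universe)
  expect_equal(res$p[res$pathway == "disjoint"], 1)    # Pr(X >= 0) = 1
  expect_lt(res$p[res$pathway == "same"], 1e-6)  # 1/choose(30,8)
  expect_error(ora_test(c(gene_set, "ghost"), list(a = gene_set), universe))
})

test_that("ORA p equals exhaustive enumeration for a small universe", {
  set.seed(82)
  universe <- paste0("g", 1:20)
  for (i in 1:20) {
    gene_set <- sample(universe, sample(3:10, 1))
    pw <- sample(universe, sample(3:12, 1))
    res <- ora_test(gene_set, list(pw = pw), universe)
    # enumerate all possible draws of |gene_set| genes from the universe
    k_obs <- length(intersect(gene_set, pw))
    combos <- combn(length(universe), length(gene_set))
    in_pw <- apply(combos, 2, function(idx)
      sum(universe[idx] %in% pw))
    expect_equal(res$p, mean(in_pw >= k_obs), tolerance = 1e-12)
  }
})

test_that("druggability requires two distinct resources and classes union per gene", {
  drug_table <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    drug_id = c("d1", "d2", "d3"),
    indication = c("ra", "melanoma", "ra"))
  classes <- data.frame(indication = c("ra", "melanoma"),
                        class = c("autoimmune", "other"))
  recs <- build_drug_annotations(
    drug_table,
    list(dgidb = c("gA", "gC"), pharos = "gC", finan = character(0)),
    classes)
  gA <- recs[recs$gene_id == "gA", ]
  expect_equal(gA$indication_classes, "autoimmune|other")
  expect_false(gA$druggable)                 # one resource only
  expect_true(recs$druggable[recs$gene_id == "gC"])
  expect_false(recs$known_drug_target[recs$gene_id == "gC"])
})

test_that("unmapped indications fall back to class 'other' with a message", {
  drug_table <- data.frame(gene_id = "gA", drug_id = "d1",
                           indication = "mystery")
  expect_message(
    recs <- build_drug_annotations(drug_table, list(),
                                   data.frame(indication = "ra",
                                              class = "autoimmune")),
    "missing from the class mapping")
  expect_equal(recs$indication_classes, "other")
})

test_that("drug-target prediction enforces all three rules", {
  gene_dis <- data.frame(gene_id = c("A", "C", "D"), disease = "ra")
  drug_table <- data.frame(gene_id = c("C", "A"),
                           drug_id = c("dC", "dA"),
                           indication = c("ra", "psoriasis"))
  recs <- build_drug_annotations(
    drug_table, list(r1 = c("A", "D"), r2 = c("A", "D")),
    data.frame(indication = c("ra", "psoriasis"),
               class = c("autoimmune", "autoimmune")))
  ppi_hi <- data.frame(gene_a = "A", gene_b = "C", score = 0.95)
  got <- predict_new_drug_targets(gene_dis, recs, drug_table, ppi_hi)
  expect_equal(got$candidate_gene, "A")
  expect_equal(got$partner_genes, "C")
  expect_true(got$repurposing_flag)          # A has a non-ra indication
  # rule (a): weak PPI kills the prediction
  ppi_lo <- transform(ppi_hi, score = 0.85)
  expect_equal(nrow(predict_new_drug_targets(gene_dis, recs, drug_table,
                                             ppi_lo)), 0L)
  # rule (b): partner not regulated for the disease
  gene_dis2 <- data.frame(gene_id = c("A", "D"), disease = "ra")
  expect_equal(nrow(predict_new_drug_targets(gene_dis2, recs, drug_table,
                                             ppi_hi)), 0L)
  # rule (c): candidate neither drug target nor druggable
  recs2 <- build_drug_annotations(
    drug_table[drug_table$gene_id == "C", , drop = FALSE],
    list(r1 = "D"), data.frame(indication = "ra", class = "autoimmune"))
  expect_equal(nrow(predict_new_drug_targets(gene_dis, recs2, drug_table,
                                             ppi_hi)), 0L)
})

test_that("raising the PPI threshold can only shrink the prediction set", {
  set.seed(83)
  genes <- paste0("g", 1:20)
  gene_dis <- data.frame(gene_id = genes, disease = "ra")
  drug_table <- data.frame(gene_id = sample(genes, 8), drug_id = paste0("d", 1:8),
                           indication = "ra")
  recs <- build_drug_annotations(
    drug_table, list(r1 = genes[1:10], r2 = genes[1:10]),
    data.frame(indication = "ra", class = "autoimmune"))
  ppi <- data.frame(gene_a = sample(genes, 40, TRUE),
                    gene_b = sample(genes, 40, TRUE),
                    score = runif(40, 0.8, 1))
  prev <- NULL
  for (thr in c(0.85, 0.9, 0.95)) {
    got <- predict_new_drug_targets(gene_dis, recs, drug_table, ppi,
                                    ppi_min = thr)
    key <- paste(got$candidate_gene, got$disease)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("fixture drug-target triples are recovered exactly with repurposing flags", {
  dp <- read.delim(file.path(fx_out, "drug_predictions.tsv"))
  truth <- fx_truth$drug_predictions
  expect_setequal(paste(dp$candidate_gene, dp$disease),
                  paste(truth$candidate_gene, truth$disease))
  m <- match(paste(truth$candidate_gene, truth$disease),
             paste(dp$candidate_gene, dp$disease))
  expect_equal(dp$repurposing_flag[m], truth$repurposing_flag)
})
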