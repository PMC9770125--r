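fixture_genome <- generate_genome()

test_that("gene annotation separates encompassed from partially hit genes", {
  g <- fixture_genome
  del <- cnv_calls("s1", "8", 2.5e6, 3.6e6, 1, "deletion")
  ann <- annotate_genes(del, g$models, g$curation, g$bands)
  expect_equal(ann$genes_full[[1]], "GATA4")
  expect_equal(ann$known_chd_genes[[1]], "GATA4")
  expect_equal(ann$cytoband, "8p23.1")

  dup <- cnv_calls("s2", "5", 30.8e6, 33.1e6, 3, "duplication")
  ann2 <- annotate_genes(dup, g$models, g$curation, g$bands)
  expect_equal(ann2$genes_full[[1]], "FLT4")
  expect_equal(ann2$genes_partial[[1]], "NSD1")
  expect_setequal(ann2$known_chd_genes[[1]], c("FLT4", "NSD1"))

  desert <- cnv_calls("s3", "1", 1e6, 2e6, 1, "deletion")
  ann3 <- annotate_genes(desert, g$models, g$curation)
  expect_length(ann3$genes_full[[1]], 0L)
  expect_length(ann3$genes_partial[[1]], 0L)
})

test_that("rubric scoring reproduces the hand-summed canonical cases", {
  g <- fixture_genome
  # loss fully containing a haploinsufficient known gene, absent from controls
  del <- cnv_calls("s1", "8", 2.5e6, 3.6e6, 1, "deletion")
  cls <- score_cnvs(annotate_genes(del, g$models, g$curation), g$curation)
  expect_equal(cls$evidence_points, 1.15)
  expect_equal(cls$classification, "Pathogenic")
  expect_setequal(cls$evidence_items[[1]]$rule, c("L1", "F1"))

  # known gene without a dosage flag plus encoded expert review: 0.30 + 0.15
  # + 0.45 lands exactly on the likely-pathogenic cut
  crkl <- cnv_calls("P013", "22", 4.4e6, 4.9e6, 1, "deletion")
  manual <- data.frame(sample_id = "P013", chrom = "22", start = 4.4e6,
                       end = 4.9e6, cnv_type = "deletion", points = 0.45,
                       note = "review", stringsAsFactors = FALSE)
  cls2 <- score_cnvs(annotate_genes(crkl, g$models, g$curation), g$curation,
                     manual = manual)
  expect_equal(cls2$evidence_points, 0.90)
  expect_equal(cls2$classification, "Likely pathogenic")

  # gene-empty rare duplication: -0.60 + 0.15
  empty <- cnv_calls("s3", "1", 1e6, 2e6, 3, "duplication")
  cls3 <- score_cnvs(annotate_genes(empty, g$models, g$curation), g$curation)
  expect_equal(cls3$evidence_points, -0.45)
  expect_equal(cls3$classification, "Uncertain significance")

  # common in controls flips the frequency evidence to -1.0
  ctl <- data.frame(chrom = "1", start = 1e6, end = 2e6,
                    cnv_type = "duplication", carrier_count = 500,
                    cohort_size = 10000, frequency = 0.05,
                    stringsAsFactors = FALSE)
  cls4 <- score_cnvs(annotate_genes(empty, g$models, g$curation), g$curation,
                     controls = ctl)
  expect_equal(cls4$evidence_points, -1.6)
  expect_equal(cls4$classification, "Benign")
})

test_that("evidence ledger conserves points and classification is total and monotone", {
  fx <- make_paper_fixture()
  res <- run_cascade(fx$calls, fx$metadata, fx$profiles, fx$controls)
  cls <- score_cnvs(annotate_genes(res$retained, fx$genome$models,
                                   fx$genome$curation),
                    fx$genome$curation, fx$controls,
                    manual = fx$manual_adjustments)
  for (i in seq_len(nrow(cls))) {
    expect_equal(cls$evidence_points[i], sum(cls$evidence_items[[i]]$points))
  }
  tiers <- c("Pathogenic", "Likely pathogenic", "Uncertain significance",
             "Likely benign", "Benign")
  expect_true(all(cls$classification %in% tiers))
  pts <- seq(-2, 2, by = 0.01)
  rank <- match(classify_points(pts), rev(tiers))
  expect_true(all(diff(rank) >= 0))
})

test_that("rubric scoring agrees with a rule-by-rule oracle on random CNVs", {
  set.seed(77)
  genes <- sprintf("G%02d", 1:20)
  curation <- data.frame(
    symbol = genes,
    known_chd = sample(c(TRUE, FALSE), 20, replace = TRUE),
    haploinsufficient = sample(c(TRUE, FALSE, NA), 20, replace = TRUE),
    triplosensitive = sample(c(TRUE, FALSE, NA), 20, replace = TRUE),
    pli = round(runif(20), 2),
    murine_heart_expression = sample(c(TRUE, FALSE, NA), 20, replace = TRUE),
    mouse_cardiac_or_embryonic_phenotype = sample(c(TRUE, FALSE, NA), 20,
                                                  replace = TRUE),
    stringsAsFactors = FALSE)
  n <- 300
  type <- sample(c("deletion", "duplication"), n, replace = TRUE)
  start <- sample.int(1e6, n)
  ann <- cnv_calls(sample(c("a", "b"), n, TRUE), "1", start,
                   start + sample.int(2e5, n),
                   ifelse(type == "deletion", 1, 3), type)
  ann$genes_full <- lapply(seq_len(n), function(i)
    sample(genes, sample(0:3, 1L)))
  ann$genes_partial <- lapply(seq_len(n), function(i)
    sample(setdiff(genes, ann$genes_full[[i]]), sample(0:2, 1L)))
  ann$known_chd_genes <- lapply(seq_len(n), function(i)
    intersect(c(ann$genes_full[[i]], ann$genes_partial[[i]]),
              curation$symbol[curation$known_chd]))
  cstart <- sample.int(1e6, 40)
  controls <- data.frame(
    chrom = "1", start = cstart, end = cstart + sample.int(2e5, 40),
    cnv_type = sample(c("deletion", "duplication"), 40, TRUE),
    carrier_count = sample(0:300, 40, TRUE), cohort_size = 10000,
    stringsAsFactors = FALSE)
  controls$frequency <- controls$carrier_count / controls$cohort_size
  mi <- sample.int(n, 30)
  manual <- data.frame(sample_id = ann$sample_id[mi], chrom = "1",
                       start = ann$start[mi], end = ann$end[mi],
                       cnv_type = ann$cnv_type[mi],
                       points = round(runif(30, -0.5, 0.6), 2),
                       note = "sim", stringsAsFactors = FALSE)
  cls <- score_cnvs(ann, curation, controls, manual = manual)
  for (i in seq_len(n)) {
    exp_pts <- oracle_score(ann[i, ], ann$genes_full[[i]],
                            ann$genes_partial[[i]], curation, controls,
                            manual)
    expect_equal(cls$evidence_points[i], exp_pts, tolerance = 1e-12)
  }
})

test_that("candidate nomination requires the full evidence conjunction", {
  fx <- make_paper_fixture()
  res <- run_cascade(fx$calls, fx$metadata, fx$profiles, fx$controls)
  ann <- annotate_genes(res$retained, fx$genome$models, fx$genome$curation)
  cand <- nominate_candidates(ann, fx$genome$curation)
  expect_setequal(cand$gene[cand$nominated],
                  c("DGCR8", "KDM2A", "JARID2", "FSTL1", "CYFIP1"))
  # known genes never appear among candidates
  expect_false(any(cand$gene %in%
                     fx$genome$curation$symbol[fx$genome$curation$known_chd]))

  # missing mouse evidence fails the criterion even with high pLI
  cur <- data.frame(symbol = "GX", known_chd = FALSE,
                    haploinsufficient = NA, triplosensitive = NA, pli = 0.95,
                    murine_heart_expression = TRUE,
                    mouse_cardiac_or_embryonic_phenotype = NA,
                    stringsAsFactors = FALSE)
  models <- data.frame(symbol = "GX", chrom = "1", start = 1e6, end = 1.1e6,
                       strand = "+", stringsAsFactors = FALSE)
  call <- cnv_calls("s", "1", 0.9e6, 1.2e6, 1, "deletion")
  cand2 <- nominate_candidates(annotate_genes(call, models, cur), cur)
  expect_false(cand2$nominated)

  # monotonicity: completing the missing evidence can only nominate
  cur$mouse_cardiac_or_embryonic_phenotype <- TRUE
  cand3 <- nominate_candidates(annotate_genes(call, models, cur), cur)
  expect_true(cand3$nominated)
})

test_that("karyotype inference rounds within tolerance and flags aneuploidy", {
  p <- data.frame(sample_id = c("a", "b", "c", "d"),
                  mean_cn_x = c(2.02, 1.0, 1.5, 2.0),
                  mean_cn_y = c(0.98, 1.0, 0.5, 0.0),
                  stringsAsFactors = FALSE)
  k <- infer_karyotype(p)
  expect_equal(k$label, c("47,XXY", "46,XY", "other", "46,XX"))
  expect_equal(k$aneuploid, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(infer_karyotype(data.frame(sample_id = "x", mean_cn_x = -0.1,
                                          mean_cn_y = 0)), "non-negative")
})

test_that("CNVs of interest are the deduplicated union of known-gene and candidate hits", {
  fx <- make_paper_fixture()
  res <- run_cascade(fx$calls, fx$metadata, fx$profiles, fx$controls)
  ann <- annotate_genes(res$retained, fx$genome$models, fx$genome$curation)
  cand <- nominate_candidates(ann, fx$genome$curation)
  sel <- select_cnvs_of_interest(ann, cand)
  expect_equal(nrow(sel), 13L)
  expect_equal(sum(sel$interest_tag %in% c("known_gene", "both")), 8L)
  expect_equal(sum(sel$interest_tag %in% c("candidate", "both")), 5L)
  key <- paste(sel$sample_id, sel$chrom, sel$start, sel$end, sel$cnv_type)
  expect_false(any(duplicated(key)))
  # empty candidate table: only known-gene CNVs remain
  sel2 <- select_cnvs_of_interest(ann, cand[0, ])
  expect_equal(nrow(sel2), 8L)
  expect_true(all(sel2$interest_tag == "known_gene"))
  # the triple-deletion patient contributes three distinct calls, once each
  expect_equal(sum(sel$sample_id == "P012"), 3L)
})
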