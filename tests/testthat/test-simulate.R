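test_that("the toy genome is deterministic and encodes the curation roles", {
  g1 <- generate_genome()
  g2 <- generate_genome()
  expect_identical(g1, g2)
  expect_equal(sum(g1$curation$known_chd), 6L)
  qualifying <- with(g1$curation,
                     !known_chd & !is.na(pli) & pli >= 0.9 &
                       !is.na(murine_heart_expression) &
                       murine_heart_expression &
                       !is.na(mouse_cardiac_or_embryonic_phenotype) &
                       mouse_cardiac_or_embryonic_phenotype)
  expect_setequal(g1$curation$symbol[qualifying],
                  c("DGCR8", "KDM2A", "JARID2", "FSTL1", "CYFIP1"))
  len <- g1$chromosomes$length[match(g1$models$chrom, g1$chromosomes$chrom)]
  expect_true(all(g1$models$end <= len))
  # every chromosome is tiled by the band map end to end
  for (ch in g1$chromosomes$chrom) {
    b <- g1$bands[g1$bands$chrom == ch, ]
    expect_equal(min(b$start), 0)
    expect_equal(max(b$end),
                 g1$chromosomes$length[g1$chromosomes$chrom == ch])
  }

  g0 <- generate_genome(include_genes = FALSE)
  ann <- annotate_genes(cnv_calls("s", "8", 1e6, 2e6, 1, "deletion"),
                        g0$models, g0$curation)
  expect_length(ann$genes_full[[1]], 0L)
})

test_that("simulated cohorts are seed-deterministic with calibrated benign coverage", {
  g <- generate_genome()
  cfg <- simulation_config(seed = 4, n_cases = 30)
  sim1 <- simulate_cohorts(g, cfg)
  sim2 <- simulate_cohorts(g, cfg)
  expect_identical(sim1, sim2)

  autosomes <- g$chromosomes[!g$chromosomes$chrom %in% c("X", "Y"), ]
  frac <- sum(sim1$controls$end - sim1$controls$start) /
    sum(autosomes$length)
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.14)
  expect_true(all(sim1$controls$frequency >= 0.005 - 1e-9))
  expect_true(all(sim1$controls$frequency <= 0.2 + 1e-9))
})

test_that("a user-supplied spike colliding with a same-type benign region errors", {
  g <- generate_genome()
  base <- simulate_cohorts(g, simulation_config(seed = 9, n_cases = 5,
                                                n_spikes = 0L))
  r <- base$controls[1, ]
  clash <- data.frame(chrom = r$chrom, start = r$start, end = r$end,
                      cnv_type = r$cnv_type, carrier = 1L,
                      stringsAsFactors = FALSE)
  expect_error(
    simulate_cohorts(g, simulation_config(seed = 9, n_cases = 5,
                                          spikes = clash)),
    "collides")
})

test_that("simulation truth is consistent with the cascade's behaviour", {
  g <- generate_genome()
  sim <- simulate_cohorts(g, simulation_config(seed = 12, n_cases = 40,
                                               n_spikes = 8,
                                               xxy_case = 3L))
  res <- run_cascade(sim$calls, sim$metadata, sim$profiles, sim$controls)
  key <- function(d) paste(d$sample_id, d$chrom, d$start, d$end)
  retained <- key(res$retained)
  surv <- sim$truth[sim$truth$expect_survive, ]
  expect_true(all(key(surv) %in% retained))
  bg <- sim$calls[sim$calls$origin != "spike", ]
  expect_false(any(key(bg) %in% retained))
  # the configured case received the 47,XXY profile and was excluded
  expect_true(sim$metadata$sample_id[3] %in% res$qc$excluded$sample_id)
})

test_that("an empty case cohort still yields a valid control table", {
  g <- generate_genome()
  sim <- simulate_cohorts(g, simulation_config(seed = 2, n_cases = 0,
                                               n_spikes = 0L))
  expect_equal(nrow(sim$calls), 0L)
  expect_equal(nrow(sim$metadata), 0L)
  expect_gt(nrow(sim$controls), 0L)
})

test_that("the cohort fixture is deterministic and mirrors the study structure", {
  fx1 <- make_paper_fixture()
  fx2 <- make_paper_fixture()
  expect_identical(fx1, fx2)
  expect_equal(nrow(fx1$metadata), 90L)
  k <- infer_karyotype(fx1$profiles)
  expect_equal(sum(k$aneuploid), 1L)
  expect_equal(k$label[k$aneuploid], "47,XXY")
  expect_equal(nrow(fx1$spikes), 13L)
})
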