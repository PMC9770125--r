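mk_control <- function(chrom, start, end, type, freq, n = 10000) {
  data.frame(chrom = chrom, start = start, end = end, cnv_type = type,
             carrier_count = round(freq * n), cohort_size = n,
             frequency = freq, stringsAsFactors = FALSE)
}

test_that("size filter applies the 100 kb lower bound inclusively", {
  calls <- cnv_calls(c("s", "s"), c("1", "1"), c(0, 0), c(99999, 100000),
                     c(1, 1), c("deletion", "deletion"))
  kept <- filter_by_size(calls)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$end, 100000)
  expect_equal(nrow(filter_by_size(calls[0, ])), 0L)
})

test_that("probe-count minimum removes thinly supported calls, NA passes", {
  calls <- cnv_calls(rep("s", 3), rep("1", 3), c(0, 0, 0), rep(2e5, 3),
                     rep(1, 3), rep("deletion", 3),
                     n_probes = c(2L, 50L, NA))
  cfg <- filter_config(min_probes = 10)
  expect_equal(nrow(filter_by_size(calls, cfg)), 2L)
})

test_that("control filter removes common matches and keeps rare or absent ones", {
  call <- cnv_calls("s", "1", 1e6, 2e6, 1, "deletion")
  common <- mk_control("1", 1e6, 2e6, "deletion", 0.05)
  expect_equal(nrow(filter_by_controls(call, common)), 0L)
  absent <- mk_control("1", 1e6, 2e6, "deletion", 0)
  expect_equal(nrow(filter_by_controls(call, absent)), 1L)
  # same region but opposite type does not match when type-matching is on
  dup_ctl <- mk_control("1", 1e6, 2e6, "duplication", 0.05)
  expect_equal(nrow(filter_by_controls(call, dup_ctl)), 1L)
  cfg <- filter_config(require_type_match = FALSE)
  expect_equal(nrow(filter_by_controls(call, dup_ctl, cfg)), 0L)
})

test_that("control filter agrees with an exhaustive pairwise oracle", {
  set.seed(21)
  calls <- random_calls(500, samples = sprintf("s%d", 1:20),
                        chroms = c("1", "2", "3"))
  starts <- sample.int(1e6, 50)
  controls <- mk_control(sample(c("1", "2", "3"), 50, replace = TRUE),
                         starts, starts + sample.int(6e4, 50),
                         sample(c("deletion", "duplication"), 50, TRUE),
                         round(runif(50, 0, 0.01), 5))
  cfg <- filter_config()
  kept <- filter_by_controls(calls, controls, cfg)
  oracle_keep <- vapply(seq_len(nrow(calls)), function(i) {
    for (j in seq_len(nrow(controls))) {
      if (controls$chrom[j] != calls$chrom[i]) next
      if (controls$cnv_type[j] != calls$cnv_type[i]) next
      ro <- oracle_ro_arith(calls[i, ], controls[j, ])
      if (ro >= cfg$reciprocal_overlap_threshold &&
            controls$frequency[j] > cfg$max_control_frequency) return(FALSE)
    }
    TRUE
  }, logical(1L))
  expect_equal(kept, calls[oracle_keep, ], ignore_attr = TRUE)
})

test_that("sample QC excludes failed-QC and aneuploid samples with reasons", {
  fx <- make_paper_fixture()
  qc <- apply_sample_qc(fx$metadata, fx$profiles)
  expect_equal(nrow(qc$pass), 89L)
  expect_equal(qc$excluded$sample_id, "P020")
  expect_equal(qc$excluded$reason, "aneuploidy")

  md <- fx$metadata
  flip <- c("P003", "P044", "P071")
  md$qc_pass[md$sample_id %in% flip] <- FALSE
  qc2 <- apply_sample_qc(md, fx$profiles)
  expect_setequal(qc2$excluded$sample_id, c(flip, "P020"))
  expect_equal(sort(qc2$excluded$reason), sort(c(rep("qc_fail", 3),
                                                 "aneuploidy")))

  expect_error(apply_sample_qc(fx$metadata, fx$profiles[-1, ]), "profile")
})

test_that("cascade stages chain, attribute every removal, and are order-invariant", {
  fx <- make_paper_fixture()
  res <- run_cascade(fx$calls, fx$metadata, fx$profiles, fx$controls)
  s <- res$trace$stages
  expect_equal(s$n_out[-nrow(s)], s$n_in[-1])
  expect_true(all(s$n_out <= s$n_in))
  expect_equal(nrow(res$trace$removals), s$n_in[1] - s$n_out[nrow(s)])
  expect_true(all(res$trace$removals$stage %in%
                    c("sample_qc", "size_probes", "control_rarity")))
  # permuting the input calls leaves the retained set and counts unchanged
  set.seed(5)
  perm <- fx$calls[sample.int(nrow(fx$calls)), ]
  res2 <- run_cascade(perm, fx$metadata, fx$profiles, fx$controls)
  expect_equal(res2$trace$stages, s)
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$start, d$end))
  expect_equal(key(res2$retained), key(res$retained))
})

test_that("a permissive configuration makes the cascade a no-op for passing samples", {
  fx <- make_paper_fixture()
  cfg <- filter_config(min_size_bp = 0)
  res <- run_cascade(fx$calls, fx$metadata, fx$profiles, controls = NULL,
                     config = cfg)
  in_pass <- fx$calls[fx$calls$sample_id %in% res$qc$pass$sample_id, ]
  expect_equal(res$retained, in_pass, ignore_attr = TRUE)
})
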