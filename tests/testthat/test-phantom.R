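test_that("phantom generation is bit-reproducible given its seed", {
  a <- generate_phantom(small_phantom_spec(seed = 33L))
  b <- generate_phantom(small_phantom_spec(seed = 33L))
  expect_identical(a$t1$values, b$t1$values)
  expect_identical(a$study$pre$values, b$study$pre$values)
  expect_identical(a$study$posts[[2]]$values, b$study$posts[[2]]$values)
  expect_identical(a$truth$fgt_mask$values, b$truth$fgt_mask$values)
  c <- generate_phantom(small_phantom_spec(seed = 34L))
  expect_false(identical(a$t1$values, c$t1$values))
})

test_that("the FGT fraction hits its target and masks nest", {
  for (target in c(0.08, 0.15, 0.25)) {
    ph <- generate_phantom(small_phantom_spec(
      fgt_fraction_target = target))
    tr <- ph$truth
    frac <- sum(tr$fgt_mask$values) / sum(tr$breast_mask$values)
    expect_lt(abs(frac - target), 0.01)
    expect_false(any(tr$fgt_mask$values & !tr$breast_mask$values))
    expect_false(any(tr$enhancing_mask$values & !tr$fgt_mask$values))
  }
  expect_error(generate_phantom(small_phantom_spec(
    fgt_fraction_target = 0.95)), "unreachable")
})

test_that("true enhancing volumes are monotone and time-ordered", {
  sp <- small_phantom_spec(uptake = list(means = c(25, 37, 50),
                                         sds = c(12, 14, 16)),
                           enhancing_fraction = 0.4)
  ph <- generate_phantom(sp)
  for (k in 1:3) {
    v <- vapply(seq(0, 100, 10), function(ct) true_bpe_cc(ph$truth, k, ct),
                numeric(1))
    expect_true(all(diff(v) <= 0))
  }
  # delayed > early at the representative cutoff
  expect_gt(true_bpe_cc(ph$truth, 3, 30), true_bpe_cc(ph$truth, 1, 30))
  expect_equal(true_bpe_cc(ph$truth, 1, 1e6), 0)
  expect_error(true_bpe_cc(ph$truth, 9, 30), "unknown")
})

test_that("cohort generation is deterministic and honours its moments", {
  a <- generate_cohort(cohort_spec(seed = 5L))
  b <- generate_cohort(cohort_spec(seed = 5L))
  expect_identical(a$pre_value, b$pre_value)

  # law of large numbers: the no-cancer |FGT| pre mean converges to the
  # reference group mean
  big <- generate_cohort(cohort_spec(n_no_cancer = 2000L,
                                     n_cancer = 2000L, seed = 17L))
  fgt0 <- big$pre_value[big$measure == "FGTabs" & big$outcome == 0]
  expect_lt(abs(mean(fgt0) - 83.2) / 83.2, 0.05)
  expect_lt(abs(sd(fgt0) - 63.8) / 63.8, 0.10)

  # within-subject identities: |BPE| <= |FGT|, BPE% consistent with
  # |BPE| and |Breast|, and |BPE| non-increasing in the cutoff
  co <- a
  fgt <- co[co$measure == "FGTabs", c("subject_id", "pre_value")]
  bpe <- co[co$measure == "BPEabs" & !is.na(co$sub_index) &
              co$sub_index == 1, ]
  m <- merge(bpe, fgt, by = "subject_id", suffixes = c("", "_fgt"))
  expect_true(all(m$pre_value <= m$pre_value_fgt + 1e-9))
  for (s in unique(bpe$subject_id)) {
    v <- bpe$pre_value[bpe$subject_id == s][order(bpe$cutoff[bpe$subject_id == s])]
    expect_true(all(diff(v) <= 1e-9))
  }
})

test_that("a no-change cohort rejects at the nominal rate", {
  ms <- default_cohort_measures_null()
  hits <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    co <- generate_cohort(cohort_spec(n_no_cancer = 20L, n_cancer = 2L,
                                      measures = ms, seed = 1000L + i))
    s <- co[co$measure == "FGTabs" & co$outcome == 0, ]
    p <- paired_t(s$pre_value, s$post_value)$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.01)
  expect_lt(hits / reps, 0.11)
})
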