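# cutoff-profile operations and the cohort-level analysis surface

co <- generate_cohort(cohort_spec(seed = 101L))

test_that("p-value profiles cover the cutoff grid for every subset", {
  p <- pvalue_profile(co, "BPEpct", 1, subset = "no_cancer")
  expect_equal(nrow(p), 11)
  expect_equal(p$cutoff, seq(0, 100, 10))
  expect_true(all(p$n == 44))
  expect_true(all(p$p >= 0 & p$p <= 1, na.rm = TRUE))

  # a uniform multiplicative post decrease is significant at every cutoff
  expect_true(all(p$p < 0.05))

  # no change: p-values are large or degenerate
  null_co <- co
  null_co$post_value <- null_co$pre_value
  pn <- pvalue_profile(cohort_table(null_co), "BPEpct", 1)
  expect_true(all(pn$degenerate | pn$p > 0.99))
})

test_that("AUC profiles cover the grid and separate informative cohorts", {
  a <- auc_profile(co, "BPEpct", 1)
  expect_equal(nrow(a), 11)
  expect_true(all(a$auc >= 0 & a$auc <= 1))
  # the no-cancer group decreases, the cancer group does not: the
  # relative change must be informative at the mid-range cutoffs
  mid <- a$auc[a$cutoff %in% seq(20, 60, 10)]
  expect_true(all(mid > 0.6))
})

test_that("permuted outcomes yield chance-level AUC profiles", {
  # apparent (in-sample) AUC of a fitted univariable model is folded
  # above 0.5, with bias of order 1/sqrt(n1*n0): use a large balanced
  # cohort so the chance level is identifiable
  set.seed(41)
  big <- generate_cohort(cohort_spec(n_no_cancer = 100L, n_cancer = 100L,
                                     seed = 77L))
  subj <- unique(big[, c("subject_id", "outcome")])
  aucs <- replicate(100, {
    perm <- setNames(sample(subj$outcome), subj$subject_id)
    cop <- big
    cop$outcome <- as.integer(perm[cop$subject_id])
    auc_profile(cohort_table(cop), "BPEpct", 1,
                cutoffs = 30)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the cohort analysis reproduces the expected group structure", {
  an <- analyze_cohort(co, combined = c("BPEpct_SUB1", "FGTabs"))
  s <- an$summary
  expect_equal(nrow(s), 6)  # FGTabs, FGTpct, BPEabs/BPEpct x SUB 1/3
  expect_true(all(c("p_g0", "p_g1", "p_anova", "auc", "p_g0_fdr") %in%
                    names(s)))
  # significant decrease in the no-cancer group, none in the cancer group
  expect_true(all(s$p_g0[s$label %in%
                           c("FGTabs", "BPEpct_SUB1", "BPEpct_SUB3")] <
                    0.05))
  expect_true(all(s$p_g1 > 0.05))
  # FDR adjustment never decreases a p-value
  expect_true(all(s$p_g0_fdr >= s$p_g0 - 1e-12))
  # combined model reports one ROC plus DeLong comparisons
  expect_s3_class(an$combined$roc, "roc_result")
  expect_true(is.finite(an$combined$delong_vs_a$p) ||
                an$combined$delong_vs_a$degenerate)
  expect_gt(an$combined$roc$auc, 0.5)
})

test_that("cohort tables validate structure and round-trip through CSV", {
  expect_error(cohort_table(data.frame(subject_id = 1)), "missing column")
  bad <- as.data.frame(co)
  bad$outcome[1] <- 2
  expect_error(cohort_table(bad), "binary")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$pre_value, co$pre_value, tolerance = 1e-12)
})
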