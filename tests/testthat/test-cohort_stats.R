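test_that("relative differences are signed and guard against pre == 0", {
  expect_equal(relative_difference(10, 5), -0.5)
  expect_equal(relative_difference(7, 7), 0)
  expect_warning(rd <- relative_difference(c(0, 4), c(1, 6)), "excluded")
  expect_true(is.na(rd[1]))
  expect_equal(rd[2], 0.5)
})

test_that("paired t matches the closed form and flags degeneracy", {
  pre <- c(10, 20, 30)
  post <- pre + c(1, 2, 3)
  got <- paired_t(pre, post)
  want <- paired_t_oracle(pre, post)
  expect_equal(got$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$p, 0.0741799, tolerance = 1e-6)

  deg <- paired_t(c(1, 2, 3), c(3, 4, 5))  # all differences equal
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("paired t holds its nominal type-I error under the null", {
  set.seed(12)
  reps <- 1000
  hits <- 0
  for (i in seq_len(reps)) {
    pre <- rnorm(20, 10, 2)
    post <- pre + rnorm(20, 0, 1)
    if (paired_t(pre, post)$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.03)
  expect_lt(hits / reps, 0.07)
})

test_that("BH adjustment equals its brute-force definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.3), 0.3)
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- fdr_bh(p)
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12))
    expect_true(all(got <= 1))
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("the ANOVA joint contrast matches a sums-of-squares oracle", {
  set.seed(14)
  # fixed balanced 2 x 2 x 5 dataset
  group <- rep(c(0, 1), each = 10)
  phase <- rep(rep(c("pre", "post"), each = 5), 2)
  values <- rnorm(20, 5, 1) + 0.8 * (group == 1 & phase == "post")
  got <- anova_joint(values, group, phase)
  want <- anova_ss_oracle(values, group, phase)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$F, want$F, tolerance = 1e-10)

  # identical values in all cells: no interaction evidence
  flat <- anova_joint(rep(3, 20), group, phase)
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)

  expect_error(anova_joint(values[1:10], group[1:10], phase[1:10]),
               "non-empty|two levels")
})

test_that("a pure interaction pattern is detected as such", {
  set.seed(15)
  detected <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    group <- rep(c(0, 1), each = 12)
    phase <- rep(rep(c(0, 1), each = 6), 2)
    delta <- 2
    mu <- delta * ifelse((group + phase) %% 2 == 0, 1, -1)
    values <- mu + rnorm(24, 0, 0.8)
    fit <- anova_joint(values, group, phase)
    main <- stats::anova(stats::lm(values ~ factor(group) * factor(phase)))
    if (fit$p < main[1, "Pr(>F)"] && fit$p < main[2, "Pr(>F)"])
      detected <- detected + 1
  }
  expect_gt(detected / reps, 0.9)
})

test_that("the repeated-measures variant runs and agrees directionally", {
  set.seed(16)
  n <- 16
  subject <- rep(seq_len(n), each = 2)
  group <- rep(rep(c(0, 1), each = n / 2), each = 2)
  phase <- rep(c("pre", "post"), n)
  values <- rnorm(2 * n, 10, 1) - 2 * (group == 0 & phase == "post")
  fit <- anova_joint(values, group, phase, repeated = TRUE,
                     subject = subject)
  expect_true(is.finite(fit$p))
  expect_lt(fit$p, 0.05)
})

test_that("IRLS logistic regression matches glm", {
  set.seed(18)
  for (i in 1:5) {
    n <- 60
    X <- cbind(a = rnorm(n), b = rnorm(n))
    eta <- -0.3 + 0.9 * X[, 1] - 0.5 * X[, 2]
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    fit <- logistic_fit(X, y)
    ref <- glm(y ~ X, family = binomial,
               control = glm.control(epsilon = 1e-12))
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$probabilities), unname(fitted(ref)),
                 tolerance = 1e-6)
    expect_true(all(diff(fit$deviance) <= 1e-8))
  }
})

test_that("perfect separation is flagged, not silently returned", {
  x <- matrix(c(1:5, 11:15), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  expect_warning(fit <- logistic_fit(x, y), "separation")
  expect_true(fit$separated)
  expect_equal(roc_auc(fit$probabilities, y)$auc, 1)
  expect_error(logistic_fit(matrix(1:4, ncol = 1), c(0, 0, 0, 0)),
               "classes")
})

test_that("ROC AUC equals exhaustive pair counting, curve is consistent", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(19)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    r <- roc_auc(scores, y)
    expect_equal(r$auc, auc_pair_oracle(scores, y), tolerance = 1e-12)
    # curve: starts (0,0), ends (1,1), monotone, trapezoid equals AUC
    cv <- r$curve
    expect_identical(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
    expect_identical(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_lt(abs(trap - r$auc), 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("DeLong's test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  for (i in 1:10) {
    n <- 40
    y <- rep(c(0, 1), c(25, 15))
    base <- rnorm(n) + y
    a <- base + rnorm(n, 0, 0.5)
    b <- 0.5 * base + rnorm(n, 0, 0.8)
    got <- delong_test(a, b, y)
    ra <- pROC::roc(y, a, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    rb <- pROC::roc(y, b, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    ref <- pROC::roc.test(ra, rb, method = "delong")
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
    expect_equal(got$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  }
  same <- delong_test(1:10, 1:10, rep(c(0, 1), 5))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
})

test_that("LOOCV AUC is deterministic and tracks a strong effect", {
  set.seed(22)
  n <- 50
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n) + 2 * y, ncol = 1)
  cv1 <- loocv_auc(x, y)
  cv2 <- loocv_auc(x, y)
  expect_identical(cv1$auc, cv2$auc)
  apparent <- roc_auc(suppressWarnings(
    logistic_fit(x, y))$probabilities, y)$auc
  expect_lt(abs(cv1$auc - apparent), 0.1)
  expect_error(loocv_auc(x[1:8, , drop = FALSE], y[1:8]), "n >= 10")
})

test_that("LOOCV predicts the prior when a fold loses a class", {
  set.seed(23)
  x <- matrix(rnorm(12), ncol = 1)
  y <- c(1, rep(0, 11))
  expect_warning(cv <- loocv_auc(x, y), "prior")
  expect_true(is.finite(cv$auc))
})
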