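#' Relative difference of a paired measure
#'
#' `(post - pre) / pre`, the signed dimensionless change used as the
#' predictor in the outcome models. Pairs with `pre == 0` are undefined
#' and return `NA` with a warning; callers drop such records from the
#' affected model.
#'
#' @param pre,post numeric vectors of paired measurements.
#' @return Numeric vector of relative differences (`NA` where `pre == 0`).
#' @export
relative_difference <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  out <- rep(NA_real_, length(pre))
  bad <- pre == 0
  if (any(bad))
    warning(sprintf("%d record(s) with pre == 0 excluded from relative differences",
                    sum(bad)))
  out[!bad] <- (post[!bad] - pre[!bad]) / pre[!bad]
  out
}

#' Paired two-sided Student's t test
#'
#' @param pre,post equal-length numeric vectors (n >= 2).
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`, and
#'   `degenerate` (`TRUE` when the paired differences have zero
#'   variance, in which case `t` and `p` are `NA`).
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  n <- length(d)
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = n - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in the p-value
#' ranks.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-way ANOVA joint contrast
#'
#' Jointly contrasts the two independent variables (outcome group and
#' pre/post phase) on a measure by two-way fixed-effects ANOVA with
#' interaction; the reported p-value is the group-by-phase interaction
#' term. With `repeated = TRUE`, phase is treated as a within-subject
#' factor (`subject` must then identify the pairs) and the interaction p
#' comes from the within-subject error stratum.
#'
#' @param values numeric measurements, one per observation.
#' @param group binary factor (outcome group), one per observation.
#' @param phase binary factor (pre/post), one per observation.
#' @param repeated treat phase as repeated within subject.
#' @param subject subject identifiers, required when `repeated = TRUE`.
#' @return List with `p` (interaction), `F`, and the full ANOVA table.
#' @export
anova_joint <- function(values, group, phase, repeated = FALSE,
                        subject = NULL) {
  group <- factor(group)
  phase <- factor(phase)
  if (nlevels(group) != 2 || nlevels(phase) != 2)
    stop("'group' and 'phase' must each have exactly two levels")
  if (any(table(group, phase) == 0))
    stop("every group x phase cell must be non-empty")
  if (stats::var(values) == 0)
    return(list(p = 1, F = 0, table = NULL))
  if (!repeated) {
    fit <- stats::lm(values ~ group * phase)
    tab <- stats::anova(fit)
    i <- rownames(tab) == "group:phase"
    Fv <- tab[i, "F value"]
    p <- tab[i, "Pr(>F)"]
    # all-equal responses: zero SS everywhere, F = 0/0; report no effect
    if (!is.finite(Fv)) { Fv <- 0; p <- 1 }
    return(list(p = p, F = Fv, table = tab))
  }
  if (is.null(subject)) stop("'subject' required when repeated = TRUE")
  subject <- factor(subject)
  dat <- data.frame(values = values, group = group, phase = phase,
                    subject = subject)
  fit <- stats::aov(values ~ group * phase + Error(subject / phase),
                    data = dat)
  s <- summary(fit)
  within <- s[[which(grepl("subject:phase|Within", names(s)))[1]]][[1]]
  i <- trimws(rownames(within)) == "group:phase"
  Fv <- within[i, "F value"]
  p <- within[i, "Pr(>F)"]
  if (!length(p) || !is.finite(Fv)) { Fv <- 0; p <- 1 }
  list(p = p, F = Fv, table = s)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of a binary outcome on one or
#' more features. The fitted probabilities are the ROC decision variable
#' downstream. Perfect separation is detected (diverging linear
#' predictor) and reported via the `separated` flag with the
#' coefficients capped at the point of detection.
#'
#' @param X numeric matrix or data frame of features (one row per
#'   subject), without an intercept column.
#' @param y binary outcomes (0/1 or logical).
#' @param tol relative deviance-change convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @param standardize centre/scale the features before fitting (off by
#'   default; single-feature AUC is invariant to monotone rescaling).
#' @return List with `coefficients` (named, intercept first),
#'   `probabilities`, `deviance` (per-iteration, non-increasing),
#'   `converged`, `separated`.
#' @export
logistic_fit <- function(X, y, tol = 1e-8, max_iter = 100L,
                         standardize = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary (0/1)")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  n <- nrow(X)
  if (n <= ncol(X) + 1)
    stop("need more subjects than features + 1")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (standardize)
    X <- scale(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  b <- rep(0, ncol(Xd))
  dev <- numeric(0)
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% b)
    p <- stats::plogis(eta)
    dev_it <- -2 * sum(y * log(pmax(p, 1e-300)) +
                         (1 - y) * log(pmax(1 - p, 1e-300)))
    dev <- c(dev, dev_it)
    if (it > 1 && abs(dev[it - 1] - dev_it) <
        tol * (abs(dev_it) + 0.1)) { converged <- TRUE; break }
    if (max(abs(eta)) > 30) { separated <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    b <- tryCatch(
      solve(crossprod(Xd, w * Xd), crossprod(Xd, w * z)),
      error = function(e) stop("IRLS failed: singular weighted design"))
    b <- drop(b)
  }
  if (separated)
    warning("perfect separation detected; coefficients capped")
  eta <- drop(Xd %*% b)
  p <- stats::plogis(eta)
  names(b) <- colnames(Xd)
  list(coefficients = b, probabilities = p, deviance = dev,
       converged = converged, separated = separated)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with
#' ties counted 0.5. The curve is built by a threshold sweep over the
#' unique scores, so its trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param scores numeric decision variable (higher = more positive).
#' @param y binary labels.
#' @return An object of class `roc_result`: `auc`, `curve` (data frame
#'   `fpr`, `tpr`, ordered (0,0) to (1,1)), `scores`, `y`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t) sum(y == 1 & scores == t),
                            numeric(1))) / n1)
  fpr <- c(0, cumsum(vapply(thr, function(t) sum(y == 0 & scores == t),
                            numeric(1))) / n0)
  structure(list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr),
                 scores = scores, y = y),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(x$curve$fpr, x$curve$tpr, type = "l", col = col,
         xlab = "False positive rate", ylab = "True positive rate",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$curve$fpr, x$curve$tpr, col = col, ...)
  }
  invisible(x)
}

# placement values: for each positive, the fraction of negatives it
# outranks (ties 0.5), and vice versa
placement_values <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two markers scored on the same subjects using the
#' placement-value covariance estimator; ties are handled with midranks.
#'
#' @param scores_a,scores_b paired decision variables on the same
#'   subjects.
#' @param y binary labels.
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`,
#'   `degenerate` (`TRUE` when the AUC-difference variance is zero; then
#'   `p` is 1 for a zero difference and `NA` otherwise).
#' @export
delong_test <- function(scores_a, scores_b, y) {
  y <- as.numeric(y)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  pa <- placement_values(scores_a, y)
  pb <- placement_values(scores_b, y)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- auc_a - auc_b
  if (var_diff <= 0) {
    return(list(auc_a = auc_a, auc_b = auc_b, z = NA_real_,
                p = if (d == 0) 1 else NA_real_, var_diff = var_diff,
                degenerate = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff,
       degenerate = FALSE)
}

#' Leave-one-out cross-validated AUC
#'
#' Refits the logistic model with each subject held out in turn,
#' predicts the held-out probability, and computes one AUC on the pooled
#' held-out probabilities (fold-wise AUCs are undefined for single
#' held-out subjects). A training fold that loses one outcome class
#' predicts the training prevalence for its held-out subject, with a
#' warning.
#'
#' @param X feature matrix or data frame (no intercept column).
#' @param y binary outcomes.
#' @param seed recorded for provenance; the procedure is deterministic.
#' @return List with `auc` and `scores` (held-out probabilities).
#' @export
loocv_auc <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 10) stop("need n >= 10 for leave-one-out cross-validation")
  if (length(unique(y)) < 2) stop("both classes must be present")
  scores <- numeric(n)
  lost_class <- 0L
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    if (length(unique(yt)) < 2) {
      lost_class <- lost_class + 1L
      scores[i] <- mean(yt)
      next
    }
    fit <- suppressWarnings(logistic_fit(Xt, yt))
    eta <- fit$coefficients[1] +
      drop(X[i, , drop = FALSE] %*% fit$coefficients[-1])
    scores[i] <- stats::plogis(eta)
  }
  if (lost_class > 0)
    warning(sprintf("%d training fold(s) lost an outcome class; predicted the prior rate",
                    lost_class))
  list(auc = roc_auc(scores, y)$auc, scores = scores)
}
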