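#' Cohort table of paired pre/post measures
#'
#' Long-format table with one row per subject, measure, subtraction time
#' point and cutoff. Columns: `subject_id`, `outcome` (0 = no cancer
#' post-intervention, 1 = cancer), `measure` (`FGTabs`, `FGTpct`,
#' `BPEabs`, `BPEpct`), `sub_index` (`NA` for FGT measures), `cutoff`
#' (`NA` for FGT measures), `pre_value`, `post_value`.
#'
#' @param df a data frame with the columns above.
#' @return The validated table, class `cohort_table`.
#' @export
cohort_table <- function(df) {
  need <- c("subject_id", "outcome", "measure", "sub_index", "cutoff",
            "pre_value", "post_value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("cohort table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (!all(df$outcome %in% c(0, 1)))
    stop("'outcome' must be binary 0/1")
  key <- paste(df$subject_id, df$measure, df$sub_index, df$cutoff,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, measure, sub_index, cutoff) rows")
  out_by_subj <- tapply(df$outcome, df$subject_id,
                        function(o) length(unique(o)))
  if (any(out_by_subj > 1))
    stop("a subject appears with two different outcomes")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  subj <- unique(x[, c("subject_id", "outcome")])
  cat(sprintf("cohort_table: %d subjects (%d no-cancer, %d cancer), %d rows\n",
              nrow(subj), sum(subj$outcome == 0), sum(subj$outcome == 1),
              nrow(x)))
  invisible(x)
}

#' Read / write a cohort table as CSV
#' @param path CSV path.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

# per-subject pre/post values of one measure slice, outcome-aligned
cohort_slice <- function(cohort, measure, sub_index = NA, cutoff = NA) {
  sel <- cohort$measure == measure &
    (if (is.na(sub_index)) is.na(cohort$sub_index)
     else !is.na(cohort$sub_index) & cohort$sub_index == sub_index) &
    (if (is.na(cutoff)) is.na(cohort$cutoff)
     else !is.na(cohort$cutoff) & cohort$cutoff == cutoff)
  s <- cohort[sel, , drop = FALSE]
  if (!nrow(s))
    stop(sprintf("no rows for measure %s (sub %s, cutoff %s)",
                 measure, sub_index, cutoff))
  s[order(s$subject_id), c("subject_id", "outcome", "pre_value",
                           "post_value")]
}

subset_outcome <- function(s, subset = c("all", "no_cancer", "cancer")) {
  subset <- match.arg(subset)
  switch(subset,
         all = s,
         no_cancer = s[s$outcome == 0, , drop = FALSE],
         cancer = s[s$outcome == 1, , drop = FALSE])
}

#' Paired-t p-value profile over the cutoff grid
#'
#' For one measure and subtraction time point, runs the paired two-sided
#' t test (pre vs post) at every cutoff of the grid — the Manhattan-plot
#' profile of the pre/post comparison.
#'
#' @param cohort a [cohort_table()].
#' @param measure `"BPEabs"` or `"BPEpct"` (FGT measures have no cutoff
#'   axis).
#' @param sub_index subtraction time point.
#' @param cutoffs cutoff grid (percent).
#' @param subset `"all"`, `"no_cancer"` or `"cancer"`.
#' @return Data frame of class `pvalue_profile`: `measure`, `sub_index`,
#'   `cutoff`, `n`, `t`, `p`, `degenerate`.
#' @export
pvalue_profile <- function(cohort, measure, sub_index,
                           cutoffs = default_cutoffs(),
                           subset = c("all", "no_cancer", "cancer")) {
  subset <- match.arg(subset)
  rows <- lapply(cutoffs, function(ct) {
    s <- subset_outcome(cohort_slice(cohort, measure, sub_index, ct),
                        subset)
    if (nrow(s) < 2) stop("subset leaves fewer than 2 subjects")
    tt <- paired_t(s$pre_value, s$post_value)
    data.frame(measure = measure, sub_index = sub_index, cutoff = ct,
               n = nrow(s), t = tt$t, p = tt$p,
               degenerate = tt$degenerate)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pvalue_profile", "data.frame")
  out
}

#' @export
plot.pvalue_profile <- function(x, alpha = 0.05, ...) {
  plot(x$cutoff, -log10(x$p), pch = 19,
       xlab = "R%_cutoff (%)", ylab = "-log10 p",
       main = sprintf("%s, SUB %d", x$measure[1], x$sub_index[1]), ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}

#' AUC-versus-cutoff profile
#'
#' For one measure and subtraction time point: at every cutoff, the
#' relative difference (post - pre)/pre per subject is fed to a
#' univariable logistic regression of the outcome and the AUC of the
#' fitted probabilities is recorded. Subjects with `pre == 0` at a given
#' cutoff are excluded from that cutoff's model (with a warning from
#' [relative_difference()]).
#'
#' @inheritParams pvalue_profile
#' @return Data frame of class `auc_profile`: `measure`, `sub_index`,
#'   `cutoff`, `n`, `auc`.
#' @export
auc_profile <- function(cohort, measure, sub_index,
                        cutoffs = default_cutoffs()) {
  rows <- lapply(cutoffs, function(ct) {
    s <- cohort_slice(cohort, measure, sub_index, ct)
    rd <- relative_difference(s$pre_value, s$post_value)
    keep <- !is.na(rd)
    y <- s$outcome[keep]
    if (length(unique(y)) < 2) stop("both outcome groups required")
    fit <- suppressWarnings(
      logistic_fit(matrix(rd[keep], ncol = 1, dimnames = list(NULL, "rd")),
                   y))
    data.frame(measure = measure, sub_index = sub_index, cutoff = ct,
               n = sum(keep), auc = roc_auc(fit$probabilities, y)$auc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("auc_profile", "data.frame")
  out
}

#' @export
plot.auc_profile <- function(x, ...) {
  plot(x$cutoff, x$auc, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "R%_cutoff (%)", ylab = "AUC",
       main = sprintf("%s, SUB %d", x$measure[1], x$sub_index[1]), ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey")
  invisible(x)
}

#' Full cohort analysis at a representative cutoff
#'
#' Produces the group-summary analysis surface: per measure, group
#' means and SDs pre/post, the paired t p-value per group with
#' Benjamini-Hochberg correction across the measures of each group, the
#' two-way ANOVA joint-contrast p (group x phase interaction, also
#' FDR-corrected), and the AUC of the univariable logistic model on the
#' relative differences. Optionally fits a combined two-feature model
#' and compares its AUC with the single-feature models by DeLong's test.
#'
#' @param cohort a [cohort_table()].
#' @param sub_indices subtraction time points for the BPE measures.
#' @param ref_cutoff representative cutoff for single-number reporting
#'   (30% by default).
#' @param combined optional character vector of two measure labels (as in
#'   the returned summary's `label`) for the combined logistic model;
#'   `NULL` to skip.
#' @param loocv also compute the leave-one-out cross-validated AUC per
#'   measure.
#' @return List with `summary` (data frame), and when requested
#'   `combined` (list: `fit`, `roc`, `delong_vs_a`, `delong_vs_b`).
#' @export
analyze_cohort <- function(cohort, sub_indices = c(1L, 3L),
                           ref_cutoff = 30,
                           combined = c("BPEpct_SUB1", "FGTabs"),
                           loocv = FALSE) {
  specs <- list(list(measure = "FGTabs", sub_index = NA),
                list(measure = "FGTpct", sub_index = NA))
  for (k in sub_indices) {
    specs <- c(specs, list(list(measure = "BPEabs", sub_index = k),
                           list(measure = "BPEpct", sub_index = k)))
  }
  rows <- list()
  rel_diffs <- list()
  for (sp in specs) {
    ct <- if (is.na(sp$sub_index)) NA else ref_cutoff
    s <- cohort_slice(cohort, sp$measure, sp$sub_index, ct)
    label <- if (is.na(sp$sub_index)) sp$measure
    else sprintf("%s_SUB%d", sp$measure, sp$sub_index)
    g0 <- s[s$outcome == 0, ]
    g1 <- s[s$outcome == 1, ]
    t0 <- paired_t(g0$pre_value, g0$post_value)
    t1 <- paired_t(g1$pre_value, g1$post_value)
    long <- data.frame(
      values = c(s$pre_value, s$post_value),
      group = factor(rep(s$outcome, 2)),
      phase = factor(rep(c("pre", "post"), each = nrow(s)),
                     levels = c("pre", "post")))
    av <- anova_joint(long$values, long$group, long$phase)
    rd <- suppressWarnings(relative_difference(s$pre_value, s$post_value))
    keep <- !is.na(rd)
    fit <- suppressWarnings(
      logistic_fit(matrix(rd[keep], ncol = 1,
                          dimnames = list(NULL, label)),
                   s$outcome[keep]))
    auc <- roc_auc(fit$probabilities, s$outcome[keep])$auc
    cv_auc <- if (loocv)
      suppressWarnings(loocv_auc(matrix(rd[keep], ncol = 1),
                                 s$outcome[keep]))$auc
    else NA_real_
    rel_diffs[[label]] <- data.frame(subject_id = s$subject_id,
                                     outcome = s$outcome, rd = rd)
    rows[[label]] <- data.frame(
      label = label, measure = sp$measure, sub_index = sp$sub_index,
      cutoff = ct,
      pre_mean_g0 = mean(g0$pre_value), pre_sd_g0 = stats::sd(g0$pre_value),
      post_mean_g0 = mean(g0$post_value),
      post_sd_g0 = stats::sd(g0$post_value),
      pre_mean_g1 = mean(g1$pre_value), pre_sd_g1 = stats::sd(g1$pre_value),
      post_mean_g1 = mean(g1$post_value),
      post_sd_g1 = stats::sd(g1$post_value),
      p_g0 = t0$p, p_g1 = t1$p, p_anova = av$p, auc = auc,
      loocv_auc = cv_auc)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  # FDR families: the tests reported together (one family per column)
  summary$p_g0_fdr <- fdr_bh(summary$p_g0)
  summary$p_g1_fdr <- fdr_bh(summary$p_g1)
  summary$p_anova_fdr <- fdr_bh(summary$p_anova)

  out <- list(summary = summary, rel_diffs = rel_diffs,
              ref_cutoff = ref_cutoff)
  if (!is.null(combined)) {
    if (!all(combined %in% names(rel_diffs)))
      stop(sprintf("combined measures must be among: %s",
                   paste(names(rel_diffs), collapse = ", ")))
    a <- rel_diffs[[combined[1]]]
    b <- rel_diffs[[combined[2]]]
    m <- merge(a, b, by = c("subject_id", "outcome"),
               suffixes = c("_a", "_b"))
    keep <- !is.na(m$rd_a) & !is.na(m$rd_b)
    m <- m[keep, ]
    Xc <- cbind(m$rd_a, m$rd_b)
    colnames(Xc) <- combined
    fit_c <- suppressWarnings(logistic_fit(Xc, m$outcome))
    fit_a <- suppressWarnings(
      logistic_fit(Xc[, 1, drop = FALSE], m$outcome))
    fit_b <- suppressWarnings(
      logistic_fit(Xc[, 2, drop = FALSE], m$outcome))
    out$combined <- list(
      measures = combined,
      fit = fit_c,
      roc = roc_auc(fit_c$probabilities, m$outcome),
      roc_a = roc_auc(fit_a$probabilities, m$outcome),
      roc_b = roc_auc(fit_b$probabilities, m$outcome),
      delong_vs_a = delong_test(fit_c$probabilities, fit_a$probabilities,
                                m$outcome),
      delong_vs_b = delong_test(fit_c$probabilities, fit_b$probabilities,
                                m$outcome))
  }
  class(out) <- "cohort_analysis"
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis at R%%_cutoff = %g%%\n", x$ref_cutoff))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-12s p(no-cancer)=%.3g [FDR %.3g]  p(cancer)=%.3g  ANOVA p=%.3g  AUC=%.3f\n",
      s$label[i], s$p_g0[i], s$p_g0_fdr[i], s$p_g1[i], s$p_anova[i],
      s$auc[i]))
  }
  if (!is.null(x$combined))
    cat(sprintf("  Combined %s + %s: AUC = %.3f (DeLong vs each: p = %.3g, %.3g)\n",
                x$combined$measures[1], x$combined$measures[2],
                x$combined$roc$auc, x$combined$delong_vs_a$p,
                x$combined$delong_vs_b$p))
  invisible(x)
}
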