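# Pipeline entry points used by the command-line tool: each run writes
# its resolved configuration and a timestamped log next to its outputs,
# so any run can be reproduced bit-identically from the output directory
# alone.

pipeline_log <- function(out_dir) {
  path <- file.path(out_dir, "run.log")
  function(stage, msg) {
    line <- sprintf("[%s] [%s] %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    cat(line, "\n", sep = "", file = path, append = TRUE)
    message(line)
  }
}

write_config <- function(config, out_dir) {
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Quantify one scan from NIfTI inputs
#'
#' Reads the structural T1 volume and the DCE study, runs
#' [quantify_scan()], and writes `result.json`, `result.csv`, the
#' resolved `config.json` and a run log into `out_dir`. Optionally the
#' breast/FGT/BPE masks are exported as NIfTI.
#'
#' @param t1_path path to the non-fat-suppressed T1 volume.
#' @param pre_path path to the DCE pre-contrast volume.
#' @param post_paths character vector of post-contrast volume paths, in
#'   time order.
#' @param sub_paths optional precomputed subtraction volumes (same length
#'   and order as `post_paths`).
#' @param out_dir output directory (created if needed).
#' @param sub_indices subtraction time points to evaluate.
#' @param cutoffs cutoff grid in percent.
#' @param params per-stage settings, see [quantify_params()].
#' @param seed root seed recorded in the config (the pipeline stages are
#'   deterministic).
#' @param write_masks export breast/FGT masks (T1 grid), the transferred
#'   FGT mask (DCE grid) and the BPE mask at `mask_cutoff`.
#' @param mask_cutoff cutoff for the exported BPE mask.
#' @return The [quantify_scan()] result, invisibly.
#' @export
run_quantify <- function(t1_path, pre_path, post_paths, sub_paths = NULL,
                         out_dir = ".", sub_indices = c(1L, 3L),
                         cutoffs = default_cutoffs(),
                         params = quantify_params(), seed = 1L,
                         write_masks = FALSE, mask_cutoff = 30) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- pipeline_log(out_dir)
  config <- list(command = "quantify", t1 = t1_path, pre = pre_path,
                 posts = post_paths, subs = sub_paths,
                 sub_indices = sub_indices, cutoffs = cutoffs,
                 seed = seed, skip_registration = params$skip_registration,
                 fcm_clusters = params$fgt$n_clusters,
                 fcm_fuzziness = params$fgt$fuzziness,
                 closing_radius = params$breast$closing_radius)
  write_config(config, out_dir)
  set.seed(seed)

  log("io", sprintf("reading T1 %s", t1_path))
  t1 <- read_volume(t1_path)
  log("io", sprintf("reading DCE pre %s + %d post volume(s)", pre_path,
                    length(post_paths)))
  pre <- read_volume(pre_path)
  posts <- lapply(post_paths, read_volume)
  subs <- if (!is.null(sub_paths)) lapply(sub_paths, read_volume)
  study <- dce_study(pre, posts, subs)

  if (max(sub_indices) > length(study$posts))
    stop(sprintf("SUB %d requested but only %d post-contrast volume(s) provided",
                 max(sub_indices), length(study$posts)), call. = FALSE)

  log("quantify", "running segmentation, registration and BPE sweep")
  q <- quantify_scan(t1, study, sub_indices = sub_indices,
                     cutoffs = cutoffs, params = params)
  log("quantify", sprintf(
    "|Breast| %.2f cm^3, |FGT| %.2f cm^3, FGT%% %.2f%%",
    q$breast_cc, q$fgt_cc, q$fgt_pct))
  if (isTRUE(attr(q$transform, "warning")))
    log("register", "warning: registration did not improve over identity")

  report <- list(
    breast_cc = q$breast_cc, fgt_cc = q$fgt_cc, fgt_pct = q$fgt_pct,
    bpe = q$bpe,
    transform = list(rotation = q$transform$rotation,
                     translation = q$transform$translation,
                     center = q$transform$center))
  jsonlite::write_json(report, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(as.data.frame(q), file.path(out_dir, "result.csv"),
                   row.names = FALSE)
  write_transform(q$transform, file.path(out_dir, "transform.txt"))
  if (write_masks) {
    log("io", "writing masks")
    write_volume(q$breast, file.path(out_dir, "breast_mask.nii.gz"))
    write_volume(q$fgt, file.path(out_dir, "fgt_mask.nii.gz"))
    write_volume(q$fgt_dce, file.path(out_dir, "fgt_mask_dce.nii.gz"))
    for (k in sub_indices) {
      emap <- enhancement_ratio(study$pre, derive_subtraction(study, k),
                                q$fgt_dce, eps = params$eps)
      bm <- bpe_mask(emap, q$fgt_dce, mask_cutoff)
      write_volume(bm, file.path(out_dir,
                                 sprintf("bpe_mask_sub%d_cut%g.nii.gz",
                                         k, mask_cutoff)))
    }
  }
  log("done", sprintf("report written to %s", out_dir))
  invisible(q)
}

#' Relative differences between a pre- and a post-intervention scan
#'
#' Computes `(post - pre)/pre` for every measure of two quantified scans
#' of the same subject: |Breast|, |FGT|, FGT%, and |BPE|/BPE% per
#' (subtraction time point, cutoff). Measures with `pre == 0` are
#' reported as `NA` with a warning.
#'
#' @param pre_result,post_result `bpe_quant` objects (from
#'   [quantify_scan()]/[run_quantify()]) or paths to their
#'   `result.json` reports.
#' @param out_dir optional output directory for `compare.csv` plus
#'   config and log.
#' @return Data frame with `measure`, `sub_index`, `cutoff`, `pre`,
#'   `post`, `rel_diff`.
#' @export
run_compare <- function(pre_result, post_result, out_dir = NULL) {
  pre_q <- load_quant(pre_result)
  post_q <- load_quant(post_result)
  rows <- data.frame(
    measure = c("Breastabs", "FGTabs", "FGTpct"),
    sub_index = NA_integer_, cutoff = NA_real_,
    pre = c(pre_q$breast_cc, pre_q$fgt_cc, pre_q$fgt_pct),
    post = c(post_q$breast_cc, post_q$fgt_cc, post_q$fgt_pct))
  b_pre <- pre_q$bpe
  b_post <- post_q$bpe
  m <- merge(b_pre, b_post, by = c("sub_index", "cutoff"),
             suffixes = c("_pre", "_post"))
  rows <- rbind(rows,
                data.frame(measure = "BPEabs", sub_index = m$sub_index,
                           cutoff = m$cutoff, pre = m$bpe_cc_pre,
                           post = m$bpe_cc_post),
                data.frame(measure = "BPEpct", sub_index = m$sub_index,
                           cutoff = m$cutoff, pre = m$bpe_pct_pre,
                           post = m$bpe_pct_post))
  rows$rel_diff <- relative_difference(rows$pre, rows$post)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- pipeline_log(out_dir)
    write_config(list(command = "compare"), out_dir)
    utils::write.csv(rows, file.path(out_dir, "compare.csv"),
                     row.names = FALSE)
    log("done", sprintf("%d relative differences written", nrow(rows)))
  }
  rows
}

load_quant <- function(x) {
  if (inherits(x, "bpe_quant")) return(x)
  if (is.character(x) && length(x) == 1) {
    r <- jsonlite::read_json(x, simplifyVector = TRUE)
    return(list(breast_cc = r$breast_cc, fgt_cc = r$fgt_cc,
                fgt_pct = r$fgt_pct, bpe = as.data.frame(r$bpe)))
  }
  stop("expected a bpe_quant object or a result.json path")
}

#' Cohort statistics from a cohort table
#'
#' Runs the full statistical evaluation on a long-format cohort table:
#' paired-t p-value profiles over the cutoff grid (full cohort and per
#' outcome group), AUC-versus-cutoff profiles for the relative-change
#' predictors, and the group summary at the representative cutoff with
#' FDR-corrected p-values, ANOVA joint contrasts, per-measure AUCs and
#' the combined two-feature model. Writes `pvalue_profiles.csv`,
#' `auc_profiles.csv`, `summary.csv` and `stats.json`.
#'
#' @param cohort a [cohort_table()], or a path to its CSV.
#' @param out_dir optional output directory.
#' @param sub_indices subtraction time points present in the table.
#' @param cutoffs cutoff grid.
#' @param ref_cutoff representative cutoff for the summary.
#' @param combined two measure labels for the combined model, or `NULL`.
#' @param loocv also report leave-one-out cross-validated AUCs.
#' @param seed root seed recorded in the config (the statistics are
#'   deterministic given the table).
#' @return List with `pvalue_profiles`, `auc_profiles`, `analysis`.
#' @export
run_cohort <- function(cohort, out_dir = NULL, sub_indices = c(1L, 3L),
                       cutoffs = default_cutoffs(), ref_cutoff = 30,
                       combined = c("BPEpct_SUB1", "FGTabs"),
                       loocv = FALSE, seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_table"))
  set.seed(seed)

  pprofiles <- list()
  aprofiles <- list()
  for (meas in c("BPEabs", "BPEpct")) {
    for (k in sub_indices) {
      for (subs in c("all", "no_cancer", "cancer")) {
        p <- pvalue_profile(cohort, meas, k, cutoffs, subset = subs)
        p$subset <- subs
        pprofiles[[length(pprofiles) + 1L]] <- p
      }
      aprofiles[[length(aprofiles) + 1L]] <-
        auc_profile(cohort, meas, k, cutoffs)
    }
  }
  pvals <- do.call(rbind, pprofiles)
  aucs <- do.call(rbind, aprofiles)
  analysis <- analyze_cohort(cohort, sub_indices = sub_indices,
                             ref_cutoff = ref_cutoff, combined = combined,
                             loocv = loocv)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- pipeline_log(out_dir)
    write_config(list(command = "cohort", sub_indices = sub_indices,
                      cutoffs = cutoffs, ref_cutoff = ref_cutoff,
                      combined = combined, seed = seed), out_dir)
    utils::write.csv(pvals, file.path(out_dir, "pvalue_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(aucs, file.path(out_dir, "auc_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    stats_json <- list(summary = analysis$summary)
    if (!is.null(analysis$combined))
      stats_json$combined <- list(
        measures = analysis$combined$measures,
        auc = analysis$combined$roc$auc,
        auc_a = analysis$combined$roc_a$auc,
        auc_b = analysis$combined$roc_b$auc,
        delong_p_vs_a = analysis$combined$delong_vs_a$p,
        delong_p_vs_b = analysis$combined$delong_vs_b$p)
    jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    log("done", "cohort statistics written")
  }
  list(pvalue_profiles = pvals, auc_profiles = aucs, analysis = analysis)
}

#' Simulate a phantom or cohort to disk
#'
#' `simulate_phantom_files()` writes the T1, pre-contrast, post-contrast
#' and subtraction volumes plus the truth masks and a truth table CSV;
#' `simulate_cohort_file()` writes a cohort CSV.
#'
#' @param spec a [phantom_spec()] / [cohort_spec()].
#' @param out_dir,path output locations.
#' @return The generated object, invisibly.
#' @export
simulate_phantom_files <- function(spec = phantom_spec(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(spec)
  write_volume(ph$t1, file.path(out_dir, "t1.nii.gz"))
  write_volume(ph$study$pre, file.path(out_dir, "pre.nii.gz"))
  for (k in seq_along(ph$study$posts)) {
    write_volume(ph$study$posts[[k]],
                 file.path(out_dir, sprintf("post%d.nii.gz", k)))
    write_volume(derive_subtraction(ph$study, k),
                 file.path(out_dir, sprintf("sub%d.nii.gz", k)))
  }
  write_volume(ph$truth$breast_mask,
               file.path(out_dir, "truth_breast.nii.gz"))
  write_volume(ph$truth$fgt_mask, file.path(out_dir, "truth_fgt.nii.gz"))
  write_volume(ph$truth$fgt_mask_dce,
               file.path(out_dir, "truth_fgt_dce.nii.gz"))
  write_transform(ph$truth$transform,
                  file.path(out_dir, "truth_transform.txt"))
  truth_rows <- do.call(rbind, lapply(seq_along(ph$truth$true_ratio),
    function(k) {
      data.frame(timepoint = k, cutoff = default_cutoffs(),
                 true_bpe_cc = vapply(default_cutoffs(),
                                      function(ct)
                                        true_bpe_cc(ph$truth, k, ct),
                                      numeric(1)))
    }))
  truth_rows$breast_cc <- mask_volume_cc(ph$truth$breast_mask)
  truth_rows$fgt_cc <- mask_volume_cc(ph$truth$fgt_mask)
  utils::write.csv(truth_rows, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(ph)
}

#' @rdname simulate_phantom_files
#' @export
simulate_cohort_file <- function(spec = cohort_spec(),
                                 path = "cohort.csv") {
  cohort <- generate_cohort(spec)
  write_cohort(cohort, path)
  invisible(cohort)
}
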