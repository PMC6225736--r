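# End-to-end analysis: transform, select k, fit, assign, rank, extract.

#' Run the full robust co-clustering pipeline on a fold-change matrix
#'
#' Applies the logistic count transformation, optionally estimates the
#' number of co-clusters with the gap statistic, fits the hidden
#' variable model by EM, assigns genes and DCCs to co-clusters, ranks
#' the co-clusters by average joint probability, and extracts the
#' biomarker genes with their regulatory DCCs, regulation directions
#' and percent rankings.
#'
#' @param fold Signed gene x DCC fold-change matrix (log2 units) with
#'   row and column names, e.g. from [fold_change_matrix()] or
#'   [read_matrix_csv()].
#' @param k Number of co-clusters, or `"auto"` to select it with
#'   [gap_statistic()].
#' @param tol,max_iter,n_restarts Passed to [phvm_fit()].
#' @param gap_k_max,gap_B Passed to [gap_statistic()] when
#'   `k = "auto"`.
#' @param seed Integer seed for the gap statistic and the EM restarts.
#' @return Object of class `"lphvm_run"`: list with `counts`
#'   (transformed matrix), `gap` (`NULL` unless `k = "auto"`), `fit`
#'   (`"phvm"`), `coclusters` (`"cocluster_result"`), `biomarkers`
#'   (`"biomarker_report"`), `k` and `seed`.
#' @examples
#' ds <- simulate_fold_change(seed = 7)
#' run <- run_lphvm(ds$fold, k = 3, seed = 7, n_restarts = 2)
#' run$coclusters
#' @export
run_lphvm <- function(fold, k = "auto", tol = 1e-5, max_iter = 1000,
                      n_restarts = 5, gap_k_max = 10, gap_B = 100,
                      seed = NULL) {
  fold <- as.matrix(fold)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  counts <- logistic_transform(fold)
  gap <- NULL
  if (identical(k, "auto")) {
    gap <- gap_statistic(counts, k_max = gap_k_max, B = gap_B, seed = seed)
    k <- gap$k_hat
  }
  if (!is.numeric(k) || k < 1) stop("'k' must be \"auto\" or an integer >= 1",
                                    call. = FALSE)
  fit <- phvm_fit(counts, k = k, tol = tol, max_iter = max_iter,
                  seed = seed, n_restarts = n_restarts)
  labels <- assign_coclusters(fit)
  cc <- rank_coclusters(labels, phvm_joint_probability(fit$params))
  report <- extract_biomarkers(cc, fold)
  structure(list(counts = counts, gap = gap, fit = fit, coclusters = cc,
                 biomarkers = report, k = as.integer(k), seed = seed),
            class = "lphvm_run")
}

#' @export
print.lphvm_run <- function(x, ...) {
  cat("LPHVM robust co-clustering run (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$gap)) {
    cat("  k selected by gap statistic: ", x$k, "\n", sep = "")
  } else {
    cat("  k fixed by user: ", x$k, "\n", sep = "")
  }
  print(x$coclusters)
  print(x$biomarkers)
  invisible(x)
}

#' Write the complete result bundle of a pipeline run
#'
#' Writes the transformed count matrix, the fitted model parameters,
#' the co-cluster and biomarker reports, the gap-statistic table when
#' k was selected automatically, and a `run.log` recording seed, k,
#' iterations and final log-likelihood.
#'
#' @param run An `"lphvm_run"` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_lphvm_bundle <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_csv(run$counts, file.path(dir, "counts.csv"))
  write_phvm_fit(run$fit, dir)
  write_cocluster_reports(run$coclusters, run$biomarkers, dir)
  if (!is.null(run$gap)) {
    utils::write.csv(data.frame(k = run$gap$k_grid,
                                gap = run$gap$gap_values,
                                sk = run$gap$sk_values),
                     file.path(dir, "gap.csv"), row.names = FALSE)
  }
  writeLines(c(
    sprintf("seed: %d", run$seed),
    sprintf("k: %d (%s)", run$k,
            if (is.null(run$gap)) "fixed" else "gap statistic"),
    sprintf("em_iterations: %d", run$fit$n_iter),
    sprintf("converged: %s", run$fit$converged),
    sprintf("final_loglik: %.10g", run$fit$loglik)),
    file.path(dir, "run.log"))
  invisible(dir)
}
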