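# Fold-change computation and the logistic count transformation.

#' Per-sample log2 fold change between treatment and control expression
#'
#' Computes the elementwise log2 ratio of treated to matched control
#' expression. Samples are paired by position: column `q` of `treatment`
#' is compared with column `q` of `control`.
#'
#' @param treatment Numeric matrix (genes x samples) of strictly positive
#'   expression values under treatment.
#' @param control Numeric matrix of the same dimension with the matched
#'   control expression values.
#' @return Numeric matrix of log2 fold changes, same dimnames as
#'   `treatment`.
#' @examples
#' fold_change(matrix(8), matrix(2))  # log2(4) = 2
#' @export
fold_change <- function(treatment, control) {
  treatment <- as.matrix(treatment)
  control <- as.matrix(control)
  if (!identical(dim(treatment), dim(control))) {
    stop("'treatment' and 'control' must have identical dimensions ",
         "(matched gene sets and sample counts)", call. = FALSE)
  }
  .check_positive(treatment, "treatment")
  .check_positive(control, "control")
  log2(treatment) - log2(control)
}

.check_positive <- function(x, label) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(x))
    stop(sprintf(
      "non-positive or non-finite expression value in '%s' at row %d, column %d (value: %s)",
      label, ij[1L], ij[2L], format(x[bad[1L]])), call. = FALSE)
  }
  invisible(TRUE)
}

#' Average per-sample fold changes into a gene x DCC matrix
#'
#' Collapses replicate samples of each dose-of-chemical-compound (DCC)
#' condition to their arithmetic mean, giving the averaged fold-change
#' matrix the co-clustering model consumes.
#'
#' @param y Numeric matrix (genes x samples) of per-sample log2 fold
#'   changes, e.g. from [fold_change()].
#' @param sample_dcc Character or factor vector of length `ncol(y)`
#'   assigning each sample column to a DCC label such as
#'   `"acetaminophen_High"`.
#' @return Numeric genes x DCC matrix of mean fold changes; columns are
#'   ordered by first appearance of each DCC in `sample_dcc`.
#' @export
average_fold_change <- function(y, sample_dcc) {
  y <- as.matrix(y)
  if (length(sample_dcc) != ncol(y)) {
    stop("'sample_dcc' must assign a DCC to every sample column",
         call. = FALSE)
  }
  sample_dcc <- as.character(sample_dcc)
  dccs <- unique(sample_dcc)
  out <- vapply(dccs, function(d) {
    cols <- which(sample_dcc == d)
    rowMeans(y[, cols, drop = FALSE])
  }, numeric(nrow(y)))
  out <- matrix(out, nrow = nrow(y),
                dimnames = list(rownames(y), dccs))
  out
}

#' Build an averaged fold-change matrix from paired expression matrices
#'
#' Convenience wrapper chaining [fold_change()] and
#' [average_fold_change()].
#'
#' @inheritParams fold_change
#' @inheritParams average_fold_change
#' @return Genes x DCC matrix of mean log2 fold changes.
#' @export
fold_change_matrix <- function(treatment, control, sample_dcc) {
  average_fold_change(fold_change(treatment, control), sample_dcc)
}

#' Logistic count transformation of a fold-change matrix
#'
#' Maps the absolute fold change of every cell through a scaled logistic
#' function, `100 / (1 + exp(-|F|))`. Values lie in \[50, 100): a fold
#' change of 0 maps to exactly 50 and arbitrarily large up- or
#' down-regulation approaches but never reaches 100. The absolute value
#' merges up- and down-regulated gene subsets driven by the same DCC
#' group into a single co-cluster, and the bounded range caps the
#' influence any outlying cell can exert on the model fit. The
#' transformed values are treated as (real-valued) counts by the aspect
#' model.
#'
#' @param f Numeric matrix (or vector) of finite log2 fold changes,
#'   typically averaged over replicates.
#' @return Object of the same shape with entries in \[50, 100).
#' @examples
#' logistic_transform(c(0, 1, -3))  # 50, 73.106, 95.257
#' @export
logistic_transform <- function(f) {
  if (any(!is.finite(f))) {
    stop("fold-change input contains missing or non-finite values",
         call. = FALSE)
  }
  100 / (1 + exp(-abs(f)))
}
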