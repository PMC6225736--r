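# Block-structured fold-change simulation, outlier contamination, and
# co-clustering error rates -- the robustness benchmarking engine.

#' Simulate a block-structured fold-change dataset
#'
#' Generates a gene x DCC log2 fold-change matrix with three planted
#' co-clusters. The five gene blocks are, in order: up-regulated under
#' DCC group 1 (`+effect`), down-regulated under DCC group 1
#' (`-effect`), up-regulated under DCC group 2, down-regulated under
#' DCC group 2, and unregulated. Gaussian noise `N(0, noise_sd^2)` is
#' added everywhere. After taking absolute values the up- and
#' down-regulated blocks under a DCC group merge, so the true
#' co-cluster labels are: gene blocks 1-2 with DCC group 1, gene
#' blocks 3-4 with DCC group 2, and the unregulated genes with the
#' non-regulatory DCC group 3.
#'
#' The defaults give the 50 x 30 geometry; set
#' `dcc_blocks = c(20, 20, 20)` for the 50 x 60 one.
#'
#' @param gene_blocks Integer vector of 5 gene-block sizes.
#' @param dcc_blocks Integer vector of 3 DCC-group sizes.
#' @param effect_size Mean absolute fold change of regulated blocks
#'   (log2 units); 2 corresponds to a 4-fold expression change.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param seed Optional integer seed.
#' @return Object of class `"sim_dataset"`: `fold` (labeled matrix),
#'   `gene_labels` and `dcc_labels` (true co-cluster indices in 1..3),
#'   `outlier_mask` (logical matrix, all `FALSE` here), and the
#'   generating parameters.
#' @examples
#' ds <- simulate_fold_change(seed = 1)
#' dim(ds$fold)  # 50 x 30
#' @export
simulate_fold_change <- function(gene_blocks = c(10, 10, 10, 10, 10),
                                 dcc_blocks = c(10, 10, 10),
                                 effect_size = 2, noise_sd = 0.3,
                                 seed = NULL) {
  if (length(gene_blocks) != 5 || length(dcc_blocks) != 3 ||
      any(gene_blocks < 1) || any(dcc_blocks < 1)) {
    stop("need 5 positive gene-block sizes and 3 positive DCC-group sizes",
         call. = FALSE)
  }
  if (effect_size <= 0 || noise_sd < 0) {
    stop("'effect_size' must be positive and 'noise_sd' nonnegative",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- sum(gene_blocks)
  m <- sum(dcc_blocks)

  gene_block_id <- rep(seq_len(5), gene_blocks)
  dcc_group <- rep(seq_len(3), dcc_blocks)
  # signed block effects: blocks 1/2 act on DCC group 1, blocks 3/4 on group 2
  block_sign <- c(1, -1, 1, -1, 0)
  block_target <- c(1, 1, 2, 2, 0)
  mu <- matrix(0, n, m)
  for (b in 1:4) {
    rows <- gene_block_id == b
    cols <- dcc_group == block_target[b]
    mu[rows, cols] <- block_sign[b] * effect_size
  }
  fold <- mu + matrix(stats::rnorm(n * m, sd = noise_sd), n, m)

  dose <- c("Low", "Middle", "High")
  dcc_ids <- sprintf("cpd%02d_%s", (seq_len(m) - 1L) %/% 3 + 1L,
                     dose[(seq_len(m) - 1L) %% 3 + 1L])
  dimnames(fold) <- list(sprintf("gene%03d", seq_len(n)), dcc_ids)

  gene_labels <- c(1, 1, 2, 2, 3)[gene_block_id]
  structure(list(fold = fold,
                 gene_labels = as.integer(gene_labels),
                 dcc_labels = as.integer(dcc_group),
                 outlier_mask = matrix(FALSE, n, m, dimnames = dimnames(fold)),
                 gene_blocks = gene_blocks, dcc_blocks = dcc_blocks,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = seed),
            class = "sim_dataset")
}

#' Contaminate a simulated dataset with outlying fold changes
#'
#' Injects outliers under one of two contamination mechanisms:
#' \describe{
#'   \item{THCM}{Tukey-Huber (rowwise/casewise) contamination: each
#'     gene row is independently selected with probability `rate`, and
#'     one uniformly chosen cell of every selected row is replaced.}
#'   \item{ICM}{independent (cellwise) contamination: every cell is
#'     independently replaced with probability `rate`; the chance that
#'     a row contains at least one outlier is then
#'     `1 - (1 - rate)^m` (see [icm_row_probability()]).}
#' }
#' Replacement values have random sign and absolute magnitude uniform
#' in `outlier_range` (log2 units), far outside the signal range so
#' untransformed fits are disrupted. True labels are unchanged.
#'
#' @param ds A `"sim_dataset"`.
#' @param model `"THCM"` or `"ICM"`.
#' @param rate Row-selection probability (THCM) or per-cell probability
#'   (ICM), in `[0, 1]`.
#' @param outlier_range Length-2 numeric, the absolute magnitude range
#'   of injected outliers.
#' @param seed Optional integer seed.
#' @return The dataset with outliers injected and `outlier_mask`
#'   updated.
#' @export
contaminate <- function(ds, model = c("THCM", "ICM"), rate,
                        outlier_range = c(10, 15), seed = NULL) {
  stopifnot(inherits(ds, "sim_dataset"))
  model <- match.arg(model)
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]", call. = FALSE)
  if (length(outlier_range) != 2 || outlier_range[1] > outlier_range[2] ||
      outlier_range[1] <= 0) {
    stop("'outlier_range' must be an increasing positive pair", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds$fold)
  m <- ncol(ds$fold)
  mask <- matrix(FALSE, n, m)
  if (model == "THCM") {
    rows <- which(stats::runif(n) < rate)
    if (length(rows)) {
      cols <- sample.int(m, length(rows), replace = TRUE)
      mask[cbind(rows, cols)] <- TRUE
    }
  } else {
    mask <- matrix(stats::runif(n * m) < rate, n, m)
  }
  n_out <- sum(mask)
  if (n_out) {
    magnitude <- stats::runif(n_out, outlier_range[1], outlier_range[2])
    sign <- sample(c(-1, 1), n_out, replace = TRUE)
    ds$fold[mask] <- sign * magnitude
  }
  dimnames(mask) <- dimnames(ds$fold)
  ds$outlier_mask <- mask | ds$outlier_mask
  ds$contamination <- list(model = model, rate = rate,
                           outlier_range = outlier_range)
  ds
}

#' Row-level contamination probability of the cellwise model
#'
#' Under independent cellwise contamination with per-cell probability
#' `delta`, the probability that a row of `m` cells contains at least
#' one contaminated component is `1 - (1 - delta)^m`.
#'
#' @param delta Per-cell contamination probability.
#' @param m Number of cells per row (DCC columns).
#' @return Numeric probability.
#' @examples
#' icm_row_probability(0.005, 30)  # ~0.14
#' @export
icm_row_probability <- function(delta, m) {
  1 - (1 - delta)^m
}

#' Co-clustering error rate with optimal label matching
#'
#' Matches predicted co-cluster labels to true ones by the label
#' permutation minimizing the number of mismatches over the
#' concatenated gene and DCC items (minimum-cost assignment), then
#' reports the percentage of misclassified items,
#' `100 * mismatches / (n + m)`. Gene-only and DCC-only error rates
#' are computed the same way on their own item sets. When the two
#' labelings use different numbers of labels, matching runs over the
#' larger label set and items of unmatched labels count as misses.
#'
#' @param true_gene,true_dcc Integer vectors of true labels.
#' @param pred_gene,pred_dcc Integer vectors of predicted labels, same
#'   lengths as their true counterparts.
#' @return List with `cocluster`, `gene` and `dcc` error-rate
#'   percentages in `[0, 100]`.
#' @export
cocluster_error_rate <- function(true_gene, true_dcc, pred_gene, pred_dcc) {
  if (length(true_gene) != length(pred_gene) ||
      length(true_dcc) != length(pred_dcc)) {
    stop("label vectors must have matching lengths per side", call. = FALSE)
  }
  list(cocluster = .matched_error(c(true_gene, true_dcc),
                                  c(pred_gene, pred_dcc)),
       gene = .matched_error(true_gene, pred_gene),
       dcc = .matched_error(true_dcc, pred_dcc))
}

# percentage of items misassigned under the best label permutation
.matched_error <- function(true, pred) {
  K <- max(true, pred)
  if (K > 9) stop("optimal label matching supports at most 9 labels",
                  call. = FALSE)
  agree <- table(factor(true, levels = seq_len(K)),
                 factor(pred, levels = seq_len(K)))
  best <- 0
  for (p in .permutations(K)) {
    a <- sum(agree[cbind(p, seq_len(K))])
    if (a > best) best <- a
  }
  100 * (length(true) - best) / length(true)
}

.permutations <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (sub in .permutations(K - 1L)) {
      rest <- seq_len(K)[-i]
      out[[length(out) + 1L]] <- c(i, rest[sub])
    }
  }
  out
}

#' Benchmark co-clustering robustness over a contamination grid
#'
#' For every contamination rate and replicate: simulate a clean
#' dataset, inject outliers, prepare the count matrix (LPHVM: logistic
#' transform of absolute fold changes; PHVM: absolute fold changes
#' only), fit the model with `k` co-clusters, assign labels, and score
#' the error rate against the planted partition. Reports mean error
#' rates per grid point and method.
#'
#' @param gene_blocks,dcc_blocks,effect_size,noise_sd Passed to
#'   [simulate_fold_change()].
#' @param model Contamination mechanism, `"THCM"` or `"ICM"`; ignored
#'   at rate 0.
#' @param rates Numeric vector of contamination rates (may include 0).
#' @param outlier_range Passed to [contaminate()].
#' @param methods Any of `"LPHVM"`, `"PHVM"`.
#' @param k Number of co-clusters fitted.
#' @param n_reps Replicates per grid point.
#' @param seed Integer seed for the whole study.
#' @param ... Further arguments to [phvm_fit()] (`tol`, `max_iter`,
#'   `n_restarts`).
#' @return Data frame with one row per (rate, method): columns
#'   `model`, `rate`, `epsilon` (row-level contamination probability;
#'   for ICM via [icm_row_probability()]), `method`,
#'   `mean_er_cocluster`, `mean_er_gene`, `mean_er_dcc`, `n_reps`,
#'   `seed`.
#' @export
run_robustness_study <- function(gene_blocks = c(10, 10, 10, 10, 10),
                                 dcc_blocks = c(10, 10, 10),
                                 effect_size = 2, noise_sd = 0.3,
                                 model = "ICM", rates = 0,
                                 outlier_range = c(10, 15),
                                 methods = c("LPHVM", "PHVM"),
                                 k = 3, n_reps = 100, seed = NULL, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 2L, 2L * n_reps * length(rates)),
                      nrow = 2L)
  m <- sum(dcc_blocks)

  rows <- list()
  idx <- 0L
  for (ri in seq_along(rates)) {
    rate <- rates[ri]
    er <- array(NA_real_, dim = c(length(methods), n_reps, 3),
                dimnames = list(methods, NULL, c("cocluster", "gene", "dcc")))
    for (rep in seq_len(n_reps)) {
      idx <- idx + 1L
      ds <- simulate_fold_change(gene_blocks, dcc_blocks, effect_size,
                                 noise_sd, seed = rep_seeds[1L, idx])
      if (rate > 0) {
        ds <- contaminate(ds, model = model, rate = rate,
                          outlier_range = outlier_range,
                          seed = rep_seeds[2L, idx])
      }
      for (meth in methods) {
        counts <- if (meth == "LPHVM") logistic_transform(ds$fold)
                  else abs(ds$fold)
        fit <- phvm_fit(counts, k = k, seed = rep_seeds[2L, idx], ...)
        lab <- assign_coclusters(fit)
        e <- cocluster_error_rate(ds$gene_labels, ds$dcc_labels,
                                  lab$gene, lab$dcc)
        er[meth, rep, ] <- c(e$cocluster, e$gene, e$dcc)
      }
    }
    for (meth in methods) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = if (rate > 0) model else "none",
        rate = rate,
        epsilon = if (model == "ICM") icm_row_probability(rate, m) else rate,
        method = meth,
        mean_er_cocluster = mean(er[meth, , "cocluster"]),
        mean_er_gene = mean(er[meth, , "gene"]),
        mean_er_dcc = mean(er[meth, , "dcc"]),
        n_reps = n_reps, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
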