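# Gap-statistic selection of the number of hidden co-clusters.

#' Select the number of co-clusters with the gap statistic
#'
#' Clusters the gene rows of the (transformed) count matrix with k-means
#' for each candidate `k`, compares the log within-cluster dispersion
#' `log(W_k)` against `B` reference datasets drawn uniformly over each
#' column's observed range, and picks the smallest `k` whose gap value
#' is within one standard error of the next one:
#' `Gap(k) >= Gap(k+1) - s_{k+1}`. Because gene and DCC groups pair up
#' one-to-one in a co-clustered matrix, clustering one side (the genes,
#' which offer more observations) determines the shared number of
#' co-clusters.
#'
#' @param x Numeric matrix whose rows are clustered (genes x DCCs),
#'   typically the logistic count matrix.
#' @param k_max Largest number of clusters evaluated.
#' @param B Number of uniform reference datasets.
#' @param seed Optional integer seed controlling both the k-means
#'   restarts and the reference draws.
#' @param nstart Random restarts per k-means run.
#' @return Object of class `"gap_stat"`: list with `k_hat`, `k_grid`,
#'   `gap_values`, `sk_values`, `log_w` (observed `log(W_k)`), `B` and
#'   `seed`.
#' @references Tibshirani, Walther and Hastie (2001), JRSS-B 63(2),
#'   411-423.
#' @export
gap_statistic <- function(x, k_max = 10, B = 100, seed = NULL, nstart = 10) {
  x <- as.matrix(x)
  if (k_max < 1) stop("'k_max' must be at least 1", call. = FALSE)
  if (nrow(x) < k_max) {
    stop("need at least 'k_max' rows to evaluate k up to k_max",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k_grid <- seq_len(k_max)

  log_w <- vapply(k_grid, function(k) .log_wk(x, k, nstart), numeric(1))

  rng_lo <- apply(x, 2, min)
  rng_hi <- apply(x, 2, max)
  log_wstar <- matrix(NA_real_, nrow = B, ncol = k_max)
  for (b in seq_len(B)) {
    ref <- vapply(seq_len(ncol(x)),
                  function(j) stats::runif(nrow(x), rng_lo[j], rng_hi[j]),
                  numeric(nrow(x)))
    ref <- matrix(ref, nrow = nrow(x))
    log_wstar[b, ] <- vapply(k_grid, function(k) .log_wk(ref, k, nstart),
                             numeric(1))
  }

  usable <- is.finite(log_w) & apply(log_wstar, 2, function(col) all(is.finite(col)))
  if (!all(usable)) {
    warning("k value(s) ", paste(k_grid[!usable], collapse = ", "),
            " skipped (fewer distinct rows than clusters)", call. = FALSE)
  }
  gap <- colMeans(log_wstar) - log_w
  sk <- apply(log_wstar, 2, stats::sd) * sqrt(1 + 1 / B)
  gap[!usable] <- NA_real_
  sk[!usable] <- NA_real_

  k_hat <- k_grid[max(which(usable))]
  for (k in k_grid[-length(k_grid)]) {
    if (usable[k] && usable[k + 1L] && gap[k] >= gap[k + 1L] - sk[k + 1L]) {
      k_hat <- k
      break
    }
  }

  structure(list(k_hat = as.integer(k_hat), k_grid = k_grid,
                 gap_values = gap, sk_values = sk, log_w = log_w,
                 B = as.integer(B), seed = seed),
            class = "gap_stat")
}

# log within-cluster sum of squared Euclidean distances to centroids;
# NA when k-means cannot produce k distinct centers.
.log_wk <- function(x, k, nstart) {
  if (k == 1) {
    return(log(sum(sweep(x, 2, colMeans(x))^2)))
  }
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart,
                                   iter.max = 100)),
    error = function(e) NULL)
  if (is.null(km)) NA_real_ else log(km$tot.withinss)
}

#' @export
print.gap_stat <- function(x, ...) {
  cat("Gap statistic (", x$B, " uniform reference datasets)\n", sep = "")
  tab <- data.frame(k = x$k_grid, gap = signif(x$gap_values, 5),
                    se = signif(x$sk_values, 5))
  print(tab, row.names = FALSE)
  cat("Selected number of co-clusters:", x$k_hat, "\n")
  invisible(x)
}
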