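# Probabilistic hidden variable model (aspect model) and its EM estimator.
#
# The model factorizes a gene x DCC count matrix as
#   Pr(G_i, C_j) = sum_r Pr(G_i | H_r) Pr(C_j | H_r) Pr(H_r)
# over k hidden co-clusters H_r. Applied to the logistic transform of
# absolute fold changes this is the robust LPHVM; applied to raw absolute
# fold changes it is the non-robust PHVM baseline.

#' Dirichlet-initialized model parameters
#'
#' Draws every probability vector of the model from a symmetric
#' Dirichlet distribution with concentration 1 (uniform over the
#' simplex) and normalizes exactly.
#'
#' @param k Number of hidden co-clusters (`1 <= k <= min(n, m)`).
#' @param n,m Number of genes and DCCs.
#' @param seed Optional integer seed; a fixed seed gives identical
#'   parameters on every call.
#' @return A list of class `"phvm_params"` with elements `k`, `p_h`
#'   (length-`k` co-cluster probabilities), `p_g_given_h` (`n x k`) and
#'   `p_c_given_h` (`m x k`), each column a probability simplex.
#' @export
phvm_init <- function(k, n, m, seed = NULL) {
  if (k < 1 || n < 1 || m < 1 || k > min(n, m)) {
    stop("need 1 <= k <= min(n, m)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rsimplex <- function(len) {
    g <- stats::rgamma(len, shape = 1, rate = 1)
    g / sum(g)
  }
  params <- list(
    k = as.integer(k),
    p_h = rsimplex(k),
    p_g_given_h = vapply(seq_len(k), function(r) rsimplex(n), numeric(n)),
    p_c_given_h = vapply(seq_len(k), function(r) rsimplex(m), numeric(m))
  )
  params$p_g_given_h <- matrix(params$p_g_given_h, nrow = n, ncol = k)
  params$p_c_given_h <- matrix(params$p_c_given_h, nrow = m, ncol = k)
  class(params) <- "phvm_params"
  params
}

#' Joint gene-DCC probability matrix under the model
#'
#' Evaluates `Pr(G_i, C_j) = sum_r Pr(G_i|H_r) Pr(C_j|H_r) Pr(H_r)`.
#' The result is a genes x DCCs matrix summing to 1 over all cells.
#'
#' @param params A `"phvm_params"` object (see [phvm_init()]).
#' @return Nonnegative `n x m` matrix with total mass 1.
#' @export
phvm_joint_probability <- function(params) {
  joint <- matrix(0, nrow(params$p_g_given_h), nrow(params$p_c_given_h))
  for (r in seq_len(params$k)) {
    joint <- joint + params$p_h[r] *
      tcrossprod(params$p_g_given_h[, r], params$p_c_given_h[, r])
  }
  joint
}

#' E-step: posterior responsibility of each co-cluster per cell
#'
#' Computes `Pr(H_r | G_i, C_j)` by Bayes' rule from the current
#' parameters. Cells where every component contributes zero mass get a
#' uniform posterior `1/k` (degenerate-support rule) with a warning.
#'
#' @param counts Nonnegative count matrix (only its dimension is used
#'   here; kept in the signature for symmetry with [phvm_m_step()]).
#' @param params A `"phvm_params"` object.
#' @return `n x m x k` array of posteriors, summing to 1 over the third
#'   dimension for every cell.
#' @export
phvm_e_step <- function(counts, params) {
  n <- nrow(params$p_g_given_h)
  m <- nrow(params$p_c_given_h)
  k <- params$k
  post <- array(0, dim = c(n, m, k))
  for (r in seq_len(k)) {
    post[, , r] <- params$p_h[r] *
      tcrossprod(params$p_g_given_h[, r], params$p_c_given_h[, r])
  }
  denom <- apply(post, c(1, 2), sum)
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero probability under every ",
            "component; using a uniform posterior there", call. = FALSE)
    denom[zero] <- 1
  }
  post <- post / as.vector(denom)  # recycles denom over the 3rd dim
  if (any(zero)) {
    for (r in seq_len(k)) {
      slab <- post[, , r]
      slab[zero] <- 1 / k
      post[, , r] <- slab
    }
  }
  post
}

#' M-step: re-estimate parameters from counts and responsibilities
#'
#' Standard aspect-model maximization: each probability vector is the
#' responsibility-weighted count total normalized over its own argument,
#' `Pr(H_r) proportional to sum_ij #(G_i,C_j) Pr(H_r|G_i,C_j)` and the two
#' conditionals normalized over genes and DCCs within each component.
#' A component that receives zero total responsibility is reset to
#' uniform conditionals with a warning.
#'
#' @param counts Nonnegative `n x m` count matrix.
#' @param posterior `n x m x k` posterior array from [phvm_e_step()].
#' @return Updated `"phvm_params"`.
#' @export
phvm_m_step <- function(counts, posterior) {
  k <- dim(posterior)[3]
  n <- nrow(counts)
  m <- ncol(counts)
  p_g <- matrix(0, n, k)
  p_c <- matrix(0, m, k)
  s <- numeric(k)
  for (r in seq_len(k)) {
    w <- counts * posterior[, , r]
    s[r] <- sum(w)
    if (s[r] > 0) {
      p_g[, r] <- rowSums(w) / s[r]
      p_c[, r] <- colSums(w) / s[r]
    } else {
      warning("component ", r, " received zero responsibility; ",
              "resetting its conditionals to uniform", call. = FALSE)
      p_g[, r] <- 1 / n
      p_c[, r] <- 1 / m
    }
  }
  total <- sum(s)
  p_h <- if (total > 0) s / total else rep(1 / k, k)
  structure(list(k = as.integer(k), p_h = p_h,
                 p_g_given_h = p_g, p_c_given_h = p_c),
            class = "phvm_params")
}

#' Total log-likelihood of a count matrix under the model
#'
#' `L(G, C) = sum_ij #(G_i, C_j) log Pr(G_i, C_j)`; cells with zero
#' count contribute nothing regardless of their model probability. If a
#' positive count falls on a zero-probability cell the likelihood is
#' `-Inf` and a warning is raised.
#'
#' @inheritParams phvm_m_step
#' @param params A `"phvm_params"` object.
#' @return Scalar log-likelihood.
#' @export
phvm_log_likelihood <- function(counts, params) {
  joint <- phvm_joint_probability(params)
  pos <- counts > 0
  if (any(pos & joint == 0)) {
    warning("positive count on a zero-probability cell; ",
            "log-likelihood is -Inf", call. = FALSE)
    return(-Inf)
  }
  sum(counts[pos] * log(joint[pos]))
}

#' Fit the hidden variable model by EM with random restarts
#'
#' Alternates [phvm_e_step()] and [phvm_m_step()] from a Dirichlet
#' initialization until the increase in total log-likelihood between
#' successive iterations falls below `tol`, or `max_iter` is reached.
#' Because the likelihood surface is multimodal, `n_restarts`
#' independently seeded runs are performed and the fit with the highest
#' final log-likelihood is returned.
#'
#' @param counts Nonnegative finite gene x DCC count matrix, e.g. from
#'   [logistic_transform()] (LPHVM) or `abs()` of the fold-change
#'   matrix (PHVM baseline).
#' @param k Number of hidden co-clusters.
#' @param tol Convergence threshold on the log-likelihood difference of
#'   successive EM iterations.
#' @param max_iter Iteration cap per restart.
#' @param seed Optional integer; restart `s` uses seed `seed + s - 1`,
#'   so a fixed `seed` makes the whole fit reproducible.
#' @param n_restarts Number of seeded EM runs for `init = "random"`;
#'   the best is kept. Set to 1 for a single-initialization fit.
#' @param init Initialization strategy. `"kmeans"` (default) starts a
#'   single EM run from a hard k-means clustering of the gene rows
#'   followed by one M-step; this lands EM in the basin of the
#'   partition-consistent likelihood optimum deterministically.
#'   `"random"` draws `n_restarts` Dirichlet initializations and keeps
#'   the run with the highest final log-likelihood. The random strategy
#'   is kept because it makes no assumption about row geometry, but the
#'   block-structured likelihood has many near-degenerate optima whose
#'   final log-likelihoods differ by less than the convergence
#'   tolerance, so best-of-restarts selection can pick a poor partition
#'   (see the package vignette).
#' @return Object of class `"phvm"`: a list with `params`
#'   (`"phvm_params"`), `loglik` (final value), `loglik_trace`
#'   (per-iteration values, nondecreasing), `n_iter`, `converged`,
#'   `seed` (the winning restart's seed) and `k`.
#' @examples
#' cm <- logistic_transform(matrix(rnorm(60), 10, 6))
#' fit <- phvm_fit(cm, k = 2, seed = 1, n_restarts = 2, max_iter = 200)
#' fit$converged
#' @export
phvm_fit <- function(counts, k, tol = 1e-5, max_iter = 1000,
                     seed = NULL, n_restarts = 5,
                     init = c("kmeans", "random")) {
  counts <- as.matrix(counts)
  init <- match.arg(init)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("'counts' must be a nonnegative finite matrix", call. = FALSE)
  }
  if (k < 1 || k > min(dim(counts))) {
    stop("need 1 <= k <= min(n, m)", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - n_restarts, 1L)

  if (init == "kmeans") {
    start <- .phvm_kmeans_start(counts, k, seed)
    if (!is.null(start)) {
      best <- .phvm_em_once(counts, k, tol, max_iter, seed,
                            init_params = start)
    } else {
      warning("k-means initialization failed (fewer than k distinct ",
              "rows); falling back to random restarts", call. = FALSE)
      init <- "random"
    }
  }
  if (init == "random") {
    best <- NULL
    for (s in seq_len(n_restarts)) {
      run_seed <- seed + s - 1L
      run <- .phvm_em_once(counts, k, tol, max_iter, run_seed)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  }
  if (!best$converged) {
    warning("EM did not converge within ", max_iter,
            " iterations (last increment ",
            format(utils::tail(diff(best$loglik_trace), 1)), ")",
            call. = FALSE)
  }
  best$dimnames <- dimnames(counts)
  class(best) <- "phvm"
  best
}

# Partition-consistent starting parameters: k-means clustering of the
# rows, turned into model parameters by one M-step with softened
# cluster indicators (0.9 own cluster, rest shared) as
# responsibilities. The softening keeps every probability strictly
# positive so EM can still move items that k-means misplaced
# (multiplicative updates never revive an exact zero).
.phvm_kmeans_start <- function(counts, k, seed) {
  set.seed(seed)
  if (k == 1) {
    cl <- rep(1L, nrow(counts))
  } else {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(counts, centers = k, nstart = 10,
                                     iter.max = 100)),
      error = function(e) NULL)
    if (is.null(km)) return(NULL)
    cl <- km$cluster
  }
  post <- array(if (k > 1) 0.1 / (k - 1) else 1,
                dim = c(nrow(counts), ncol(counts), k))
  if (k > 1) for (r in seq_len(k)) post[cl == r, , r] <- 0.9
  suppressWarnings(phvm_m_step(counts, post))
}

# One seeded EM run. Fuses the E- and M-steps so each iteration builds
# the k rank-one slabs once; numerically identical to
# phvm_e_step() followed by phvm_m_step() (tested against them).
.phvm_em_once <- function(counts, k, tol, max_iter, seed,
                          init_params = NULL) {
  n <- nrow(counts)
  m <- ncol(counts)
  params <- if (is.null(init_params)) phvm_init(k, n, m, seed = seed)
            else init_params
  p_h <- params$p_h
  p_g <- params$p_g_given_h
  p_c <- params$p_c_given_h
  pos <- counts > 0
  counts_pos <- counts[pos]

  joint_of <- function() {
    joint <- matrix(0, n, m)
    for (r in seq_len(k)) {
      joint <- joint + p_h[r] * tcrossprod(p_g[, r], p_c[, r])
    }
    joint
  }
  ll_of <- function(joint) {
    jp <- joint[pos]
    if (any(jp == 0)) return(-Inf)
    sum(counts_pos * log(jp))
  }

  joint <- joint_of()
  trace <- numeric(max_iter + 1L)
  trace[1L] <- ll_of(joint)
  converged <- FALSE
  iter <- 0L
  uniform_warned <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    safe_joint <- joint
    zero <- joint == 0
    if (any(zero)) safe_joint[zero] <- 1  # cells get uniform responsibility
    s <- numeric(k)
    new_g <- p_g
    new_c <- p_c
    for (r in seq_len(k)) {
      resp <- p_h[r] * tcrossprod(p_g[, r], p_c[, r]) / safe_joint
      if (any(zero)) resp[zero] <- 1 / k
      w <- counts * resp
      s[r] <- sum(w)
      if (s[r] > 0) {
        new_g[, r] <- rowSums(w) / s[r]
        new_c[, r] <- colSums(w) / s[r]
      } else {
        if (!uniform_warned) {
          warning("component ", r, " received zero responsibility; ",
                  "resetting its conditionals to uniform", call. = FALSE)
          uniform_warned <- TRUE
        }
        new_g[, r] <- 1 / n
        new_c[, r] <- 1 / m
      }
    }
    p_h <- if (sum(s) > 0) s / sum(s) else rep(1 / k, k)
    p_g <- new_g
    p_c <- new_c
    joint <- joint_of()
    ll <- ll_of(joint)
    trace[iter + 1L] <- ll
    if (is.finite(ll) && ll - trace[iter] < tol) {
      converged <- TRUE
      break
    }
  }
  params <- structure(list(k = as.integer(k), p_h = p_h,
                           p_g_given_h = p_g, p_c_given_h = p_c),
                      class = "phvm_params")
  trace <- trace[seq_len(iter + 1L)]
  list(params = params, loglik = trace[length(trace)],
       loglik_trace = trace, n_iter = iter, converged = converged,
       seed = seed, k = as.integer(k))
}

#' @export
print.phvm <- function(x, ...) {
  cat("Hidden variable co-clustering model (aspect model)\n")
  cat(sprintf("  k = %d co-clusters, %d genes x %d DCCs\n",
              x$k, nrow(x$params$p_g_given_h), nrow(x$params$p_c_given_h)))
  cat(sprintf("  log-likelihood %.4f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  Pr(H): %s\n", paste(signif(x$params$p_h, 4), collapse = " ")))
  invisible(x)
}

#' Write fitted model parameters as a plain-text CSV bundle
#'
#' Writes `p_h.csv`, `p_g_given_h.csv`, `p_c_given_h.csv` and
#' `trace.csv` into `dir`.
#'
#' @param fit A `"phvm"` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phvm_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp <- paste0("H", seq_len(fit$k))
  p_g <- fit$params$p_g_given_h
  p_c <- fit$params$p_c_given_h
  dimnames(p_g) <- list(fit$dimnames[[1]], comp)
  dimnames(p_c) <- list(fit$dimnames[[2]], comp)
  utils::write.csv(data.frame(component = comp, p_h = fit$params$p_h),
                   file.path(dir, "p_h.csv"), row.names = FALSE)
  write_matrix_csv(p_g, file.path(dir, "p_g_given_h.csv"), id_column = "gene")
  write_matrix_csv(p_c, file.path(dir, "p_c_given_h.csv"), id_column = "dcc")
  utils::write.csv(data.frame(iteration = seq_along(fit$loglik_trace) - 1L,
                              loglik = fit$loglik_trace),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  invisible(dir)
}
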