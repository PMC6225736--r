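test_that("phvm_init returns normalized simplexes, reproducibly", {
  p <- phvm_init(3, 8, 5, seed = 42)
  expect_equal(sum(p$p_h), 1, tolerance = 1e-12)
  expect_equal(colSums(p$p_g_given_h), rep(1, 3), tolerance = 1e-12)
  expect_equal(colSums(p$p_c_given_h), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p$p_h >= 0) && all(p$p_g_given_h >= 0) &&
                all(p$p_c_given_h >= 0))
  expect_identical(p, phvm_init(3, 8, 5, seed = 42))
  expect_equal(phvm_init(1, 4, 4, seed = 1)$p_h, 1)
  expect_error(phvm_init(5, 4, 6, seed = 1), "k")
  expect_error(phvm_init(0, 4, 6, seed = 1), "k")
})

test_that("joint probability matches structure and brute-force oracle", {
  # uniform one-component model: every cell 1/(n m)
  p1 <- list(k = 1L, p_h = 1, p_g_given_h = matrix(1 / 4, 4),
             p_c_given_h = matrix(1 / 3, 3))
  expect_equal(phvm_joint_probability(p1), matrix(1 / 12, 4, 3))

  # permutation structure: diagonal 1/k
  del <- diag(3)
  p2 <- list(k = 3L, p_h = rep(1 / 3, 3), p_g_given_h = del,
             p_c_given_h = del)
  expect_equal(phvm_joint_probability(p2), diag(3) / 3)

  set.seed(11)
  for (rep in 1:5) {
    p <- phvm_init(2, 3, 4, seed = rep)
    joint <- phvm_joint_probability(p)
    expect_equal(joint, oracle_joint(p$p_h, p$p_g_given_h, p$p_c_given_h),
                 tolerance = 1e-12)
    expect_equal(sum(joint), 1, tolerance = 1e-12)
  }
})

test_that("E-step posteriors normalize and match Bayes-rule oracle", {
  cm <- matrix(runif(12, 50, 100), 3, 4)
  p1 <- phvm_init(1, 3, 4, seed = 5)
  expect_equal(phvm_e_step(cm, p1), array(1, c(3, 4, 1)))

  # two identical components share responsibility equally
  p_sym <- list(k = 2L, p_h = c(0.5, 0.5),
                p_g_given_h = cbind(c(.2, .3, .5), c(.2, .3, .5)),
                p_c_given_h = cbind(rep(.25, 4), rep(.25, 4)))
  expect_equal(phvm_e_step(cm, p_sym), array(0.5, c(3, 4, 2)))

  set.seed(2)
  for (rep in 1:5) {
    p <- phvm_init(2, 3, 4, seed = 100 + rep)
    post <- phvm_e_step(cm, p)
    expect_equal(apply(post, c(1, 2), sum), matrix(1, 3, 4),
                 tolerance = 1e-12)
    expect_equal(post, oracle_e_step(p$p_h, p$p_g_given_h, p$p_c_given_h),
                 tolerance = 1e-12)
  }
})

test_that("M-step renormalizes responsibility-weighted counts", {
  # equal counts + uniform posterior give uniform parameters
  cm <- matrix(7, 3, 4)
  post <- array(0.5, c(3, 4, 2))
  p <- phvm_m_step(cm, post)
  expect_equal(p$p_h, c(0.5, 0.5))
  expect_equal(p$p_g_given_h, matrix(1 / 3, 3, 2))
  expect_equal(p$p_c_given_h, matrix(1 / 4, 4, 2))

  # a single positive cell forces degenerate conditionals at k = 1
  cm1 <- matrix(0, 3, 4); cm1[2, 3] <- 5
  p1 <- phvm_m_step(cm1, array(1, c(3, 4, 1)))
  expect_equal(p1$p_g_given_h[, 1], c(0, 1, 0))
  expect_equal(p1$p_c_given_h[, 1], c(0, 0, 1, 0))

  set.seed(3)
  for (rep in 1:5) {
    cm <- matrix(runif(12, 0, 100), 3, 4)
    post <- phvm_e_step(cm, phvm_init(2, 3, 4, seed = rep))
    got <- phvm_m_step(cm, post)
    want <- oracle_m_step(cm, post)
    expect_equal(got$p_h, want$p_h, tolerance = 1e-12)
    expect_equal(got$p_g_given_h, want$p_g, tolerance = 1e-12)
    expect_equal(got$p_c_given_h, want$p_c, tolerance = 1e-12)
  }
})

test_that("log-likelihood is the count-weighted log joint probability", {
  p1 <- list(k = 1L, p_h = 1, p_g_given_h = matrix(1 / 3, 3),
             p_c_given_h = matrix(1 / 4, 4))
  cm <- matrix(10, 3, 4)  # total 120 on a uniform 1/12 model
  expect_equal(phvm_log_likelihood(cm, p1), 120 * log(1 / 12))
  expect_equal(phvm_log_likelihood(matrix(0, 3, 4), p1), 0)

  # positive count on zero-probability support
  p0 <- list(k = 1L, p_h = 1, p_g_given_h = matrix(c(1, 0, 0), 3),
             p_c_given_h = matrix(1 / 4, 4))
  cm0 <- matrix(1, 3, 4)
  expect_warning(ll <- phvm_log_likelihood(cm0, p0), "zero-probability")
  expect_identical(ll, -Inf)

  set.seed(4)
  p <- phvm_init(2, 3, 4, seed = 9)
  cm <- matrix(runif(12, 0, 5), 3, 4)
  expect_equal(phvm_log_likelihood(cm, p),
               oracle_loglik(cm, p$p_h, p$p_g_given_h, p$p_c_given_h),
               tolerance = 1e-10)
})

test_that("one fused EM iteration equals the naive-loop oracle on 4x4 instances", {
  set.seed(6)
  for (rep in 1:12) {
    k <- sample(1:2, 1)
    cm <- matrix(runif(16, 0, 100), 4, 4)
    init <- phvm_init(k, 4, 4, seed = 1000 + rep)
    # package path: one full EM sweep inside the fitter
    fit <- suppressWarnings(
      phvm_fit(cm, k = k, tol = -1, max_iter = 1, seed = 1000 + rep,
               n_restarts = 1, init = "random"))
    # oracle path: naive E then M from the identical initialization
    post <- oracle_e_step(init$p_h, init$p_g_given_h, init$p_c_given_h)
    want <- oracle_m_step(cm, post)
    expect_equal(fit$params$p_h, want$p_h, tolerance = 1e-10)
    expect_equal(fit$params$p_g_given_h, want$p_g, tolerance = 1e-10)
    expect_equal(fit$params$p_c_given_h, want$p_c, tolerance = 1e-10)
  }
})

test_that("EM log-likelihood trace is monotone and simplexes stay normalized", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(4:8, 1); m <- sample(4:8, 1); k <- sample(1:3, 1)
    cm <- matrix(runif(n * m, 0, 100), n, m)
    fit <- suppressWarnings(
      phvm_fit(cm, k = k, max_iter = 60, seed = rep, n_restarts = 1))
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    p <- fit$params
    expect_equal(sum(p$p_h), 1, tolerance = 1e-12)
    expect_equal(colSums(p$p_g_given_h), rep(1, k), tolerance = 1e-12)
    expect_equal(colSums(p$p_c_given_h), rep(1, k), tolerance = 1e-12)
  }
})

test_that("k = 1 fit converges to the closed-form marginal solution", {
  set.seed(10)
  cm <- matrix(runif(30, 10, 90), 5, 6)
  fit <- phvm_fit(cm, k = 1, seed = 3, n_restarts = 1)
  expect_lte(fit$n_iter, 2)
  expect_true(fit$converged)
  expect_equal(fit$params$p_g_given_h[, 1], rowSums(cm) / sum(cm),
               tolerance = 1e-12)
  expect_equal(fit$params$p_c_given_h[, 1], colSums(cm) / sum(cm),
               tolerance = 1e-12)
  expect_equal(fit$params$p_h, 1)
})

test_that("fit recovers a planted two-block partition and is deterministic", {
  cm <- two_block_counts()
  fit <- phvm_fit(cm, k = 2, seed = 20, n_restarts = 5)
  lab <- assign_coclusters(fit)
  expect_equal(lab$gene[1], lab$gene[2])
  expect_length(unique(lab$gene[1:3]), 1)
  expect_length(unique(lab$gene[4:6]), 1)
  expect_false(lab$gene[1] == lab$gene[4])
  expect_equal(unname(lab$gene), unname(lab$dcc))

  fit2 <- phvm_fit(cm, k = 2, seed = 20, n_restarts = 5)
  expect_identical(fit, fit2)
})

test_that("permuting components leaves the joint probability invariant", {
  p <- phvm_init(3, 6, 5, seed = 77)
  perm <- c(3, 1, 2)
  q <- list(k = 3L, p_h = p$p_h[perm],
            p_g_given_h = p$p_g_given_h[, perm],
            p_c_given_h = p$p_c_given_h[, perm])
  expect_equal(phvm_joint_probability(p), phvm_joint_probability(q),
               tolerance = 1e-14)
})

test_that("fit parameter bundle round-trips through CSV", {
  cm <- two_block_counts()
  dimnames(cm) <- list(paste0("g", 1:6), paste0("c", 1:6))
  fit <- phvm_fit(cm, k = 2, seed = 1, n_restarts = 2)
  dir <- withr::local_tempdir()
  write_phvm_fit(fit, dir)
  pg <- read_matrix_csv(file.path(dir, "p_g_given_h.csv"))
  expect_equal(unname(pg), unname(fit$params$p_g_given_h),
               tolerance = 1e-10)
})
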