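# Independent naive-loop oracles for the aspect model, kept deliberately
# separate from the package's vectorized implementation.

oracle_joint <- function(p_h, p_g, p_c) {
  n <- nrow(p_g); m <- nrow(p_c); k <- length(p_h)
  joint <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) for (r in seq_len(k)) {
    joint[i, j] <- joint[i, j] + p_g[i, r] * p_c[j, r] * p_h[r]
  }
  joint
}

oracle_e_step <- function(p_h, p_g, p_c) {
  n <- nrow(p_g); m <- nrow(p_c); k <- length(p_h)
  post <- array(0, dim = c(n, m, k))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    terms <- vapply(seq_len(k),
                    function(r) p_g[i, r] * p_c[j, r] * p_h[r], 0)
    s <- sum(terms)
    post[i, j, ] <- if (s == 0) rep(1 / k, k) else terms / s
  }
  post
}

oracle_m_step <- function(counts, post) {
  n <- nrow(counts); m <- ncol(counts); k <- dim(post)[3]
  s <- numeric(k)
  p_g <- matrix(0, n, k); p_c <- matrix(0, m, k)
  for (r in seq_len(k)) {
    for (i in seq_len(n)) for (j in seq_len(m)) {
      w <- counts[i, j] * post[i, j, r]
      s[r] <- s[r] + w
      p_g[i, r] <- p_g[i, r] + w
      p_c[j, r] <- p_c[j, r] + w
    }
    p_g[, r] <- p_g[, r] / s[r]
    p_c[, r] <- p_c[, r] / s[r]
  }
  list(p_h = s / sum(s), p_g = p_g, p_c = p_c)
}

oracle_loglik <- function(counts, p_h, p_g, p_c) {
  joint <- oracle_joint(p_h, p_g, p_c)
  total <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    if (counts[i, j] > 0) total <- total + counts[i, j] * log(joint[i, j])
  }
  total
}

# a small planted two-block count matrix whose likelihood optimum is the
# planted partition
two_block_counts <- function() {
  cm <- matrix(50, 6, 6)
  cm[1:3, 1:3] <- 90
  cm[4:6, 4:6] <- 90
  cm
}
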