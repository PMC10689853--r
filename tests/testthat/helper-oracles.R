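# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# stationary distribution of a conformational rate matrix by null space of
# t(Q) via SVD (brute-force linear algebra, independent of the package's
# balance-equation solver)
oracle_stationary <- function(rates) {
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  s <- svd(t(Q))
  v <- s$v[, ncol(s$v)]
  v <- abs(v)
  v / sum(v)
}

# exhaustive Viterbi: maximize the joint log-probability over all K^T paths
oracle_viterbi <- function(y, mu, sigma, trans, init) {
  K <- length(mu)
  T_ <- length(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(paths, 1, function(p) {
    lp <- log(init[p[1]]) + dnorm(y[1], mu[p[1]], sigma[p[1]], log = TRUE)
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(trans[p[t - 1], p[t]]) +
          dnorm(y[t], mu[p[t]], sigma[p[t]], log = TRUE)
      }
    }
    lp
  })
  best <- which.max(logp)
  list(path = as.integer(paths[best, ]), logprob = max(logp))
}

# quick two-state trace tibble: alternating blocks of the given levels
block_trace <- function(levels, block_len = 10, n_blocks = 6, sd = 0,
                        frame = 0.1, seed = 1) {
  set.seed(seed)
  y <- rep(rep(levels, length.out = n_blocks), each = block_len)
  y <- y + rnorm(length(y), 0, sd)
  tibble::tibble(time_s = (seq_along(y) - 1) * frame, intensity = y)
}
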