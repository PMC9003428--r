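# Independent oracles used to cross-check the homotopy solver and the
# evaluation protocol. These deliberately share no code with the package
# internals.

# Cyclic coordinate descent for (1/2N)||y - Xb||^2 + lam * ||b||_1,
# run to convergence tolerance `tol` on the working (already
# standardized) scale.
cd_lasso <- function(X, y, lam, tol = 1e-10, max_iter = 100000) {
  N <- nrow(X); P <- ncol(X)
  b <- numeric(P)
  xtx <- colSums(X^2) / N
  r <- y
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(P)) {
      rho <- sum(X[, j] * r) / N + xtx[j] * b[j]
      bj_new <- sign(rho) * max(abs(rho) - lam, 0) / xtx[j]
      if (bj_new != b[j]) {
        r <- r - X[, j] * (bj_new - b[j])
        delta <- max(delta, abs(bj_new - b[j]))
        b[j] <- bj_new
      }
    }
    if (delta < tol) break
  }
  b
}

lasso_objective <- function(X, y, b, lam) {
  sum((y - X %*% b)^2) / (2 * nrow(X)) + lam * sum(abs(b))
}

# Working-scale (standardized) view of a lasso_problem, mirroring the
# documented standardization contract.
working_scale <- function(prob) {
  X <- prob$X; y <- prob$y
  if (prob$standardize) {
    X <- scale(X)
    y <- y - mean(y)
  }
  list(X = X, y = y)
}

# Textbook paired t statistic and two-tailed p-value.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# A small deterministic recording for I/O and preprocessing tests.
toy_recording <- function(n_ch = 3, n = 40, fs = 2, seed = 1, kind = "hbo") {
  set.seed(seed)
  nirs_recording(matrix(rnorm(n_ch * n), n_ch, n), fs, kind)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
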