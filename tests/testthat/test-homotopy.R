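test_that("lambda_max is the zero-solution threshold", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(lambda_max(lasso_problem(X, rep(0, 40), standardize = FALSE)), 0)

  # one column proportional to y, the rest orthogonalised against y
  y <- rnorm(40)
  Xo <- apply(matrix(rnorm(40 * 5), 40, 5), 2,
              function(v) v - y * sum(v * y) / sum(y^2))
  Xc <- cbind(Xo[, 1:2], y / sqrt(sum(y^2)), Xo[, 3:5])
  prob <- lasso_problem(Xc, y, standardize = FALSE)
  cors <- abs(crossprod(Xc, y)) / 40
  expect_equal(which.max(cors), 3L)
  expect_equal(lambda_max(prob), max(cors))

  # solving just above lambda_max keeps every coefficient at zero
  prob2 <- lasso_problem(matrix(rnorm(30 * 8), 30, 8), rnorm(30))
  path <- solve_path(prob2)
  expect_true(all(solution_at(path, 1.01 * lambda_max(prob2)) == 0))
  expect_true(all(path$coefs[, 1] == 0))
  expect_length(path$active_sets[[1]], 0)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  set.seed(32)
  for (i in 1:5) {
    N <- 40; P <- 6
    Q <- qr.Q(qr(matrix(rnorm(N * P), N, P)))
    X <- Q * sqrt(N)            # X'X / N = I
    y <- rnorm(N)
    path <- solve_path(lasso_problem(X, y, standardize = FALSE))
    ct <- as.numeric(crossprod(X, y)) / N
    soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
    for (k in seq_along(path$breakpoints))
      expect_lt(max(abs(path$coefs[, k] - soft(ct, path$breakpoints[k]))),
                1e-10)
  }
})

test_that("path breakpoints and interpolations satisfy the KKT certificate", {
  set.seed(33)
  for (i in 1:10) {
    prob <- lasso_problem(matrix(rnorm(30 * 8), 30, 8),
                          rnorm(30), standardize = (i %% 2 == 0))
    path <- solve_path(prob)
    expect_true(all(diff(path$breakpoints) < 1e-15))
    for (k in seq_along(path$breakpoints))
      expect_lt(kkt_residual(prob, path$coefs[, k], path$breakpoints[k]),
                1e-8)
    # interpolated solutions at random interior penalties
    lams <- exp(runif(20, log(min(path$breakpoints) * 1.5),
                      log(path$lambda_max * 0.99)))
    for (l in lams)
      expect_lt(kkt_residual(prob, solution_at(path, l), l), 1e-6)
  }
})

test_that("objective values match an independent coordinate-descent oracle", {
  set.seed(34)
  for (i in 1:10) {
    prob <- lasso_problem(matrix(rnorm(30 * 8), 30, 8), rnorm(30))
    path <- solve_path(prob)
    w <- working_scale(prob)
    lams <- exp(seq(log(path$lambda_max * 0.8),
                    log(path$lambda_max * 2e-3), length.out = 5))
    for (l in lams) {
      b_cd <- cd_lasso(w$X, w$y, l)
      obj_cd <- lasso_objective(w$X, w$y, b_cd, l)
      obj_ht <- lasso_objective(w$X, w$y, solution_at(path, l), l)
      expect_lt(abs(obj_ht - obj_cd), 1e-6)
      expect_lte(obj_ht, obj_cd + 1e-9)   # never worse than the oracle
    }
  }
})

test_that("the path end reaches least squares on full-rank problems", {
  set.seed(35)
  for (i in 1:5) {
    X <- matrix(rnorm(50 * 7), 50, 7)
    y <- X %*% rnorm(7) + rnorm(50)
    prob <- lasso_problem(X, y, lambda_min_ratio = 1e-10)
    path <- solve_path(prob)
    w <- working_scale(prob)
    bls <- qr.solve(w$X, w$y)
    expect_lt(max(abs(path$coefs[, ncol(path$coefs)] - bls)), 1e-6)
  }
})

test_that("solution_at handles boundaries and is exact at breakpoints", {
  set.seed(36)
  prob <- lasso_problem(matrix(rnorm(30 * 5), 30, 5), rnorm(30))
  path <- solve_path(prob)
  expect_true(all(solution_at(path, path$breakpoints[1]) == 0))
  for (k in seq_along(path$breakpoints))
    expect_equal(solution_at(path, path$breakpoints[k]), path$coefs[, k])
  expect_warning(b_end <- solution_at(path, min(path$breakpoints) / 10),
                 "below the end")
  expect_equal(b_end, path$coefs[, ncol(path$coefs)])
})

test_that("the solver is deterministic and rejects bad inputs", {
  set.seed(37)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  p1 <- solve_path(lasso_problem(X, y))
  p2 <- solve_path(lasso_problem(X, y))
  expect_identical(p1$breakpoints, p2$breakpoints)
  expect_identical(p1$coefs, p2$coefs)

  expect_error(lasso_problem(matrix(c(1, Inf, 2, 3), 2), c(1, 2)),
               "non-finite")
  Xz <- X; Xz[, 4] <- 2
  expect_error(lasso_problem(Xz, y), "zero-variance")
  expect_error(lasso_problem(X[1, , drop = FALSE], y[1]), "2 observations")
})

test_that("collinear designs stay finite; singular Gram solves fall back to ridge", {
  set.seed(38)
  x1 <- rnorm(30)
  X <- cbind(x1, x1, rnorm(30))        # exactly collinear pair
  y <- 2 * x1 + rnorm(30, sd = 0.1)
  # a duplicate never co-enters the active set, so the path stays clean
  path <- solve_path(lasso_problem(X, y, standardize = FALSE))
  expect_true(all(is.finite(path$coefs)))
  expect_false(all(c(1, 2) %in%
                     path$active_sets[[length(path$active_sets)]]))
  # the direction solve itself warns and recovers on a singular Gram
  G <- matrix(1, 2, 2)
  expect_warning(d <- fnirsbci:::solve_direction(G, c(1, 1)),
                 "ridge-stabilized")
  expect_true(all(is.finite(d)))
})

test_that("unstandardize_coefs reproduces original-scale predictions", {
  set.seed(39)
  X <- matrix(rnorm(40 * 5), 40, 5) %*% diag(c(1, 10, 0.1, 5, 2))
  y <- X %*% c(1, 0.2, -3, 0, 0.5) + rnorm(40, sd = 0.1)
  prob <- lasso_problem(X, y, lambda_min_ratio = 1e-8)
  path <- solve_path(prob)
  lam <- path$lambda_max * 0.05
  u <- unstandardize_coefs(path, lam)
  pred_direct <- as.numeric(X %*% u$beta + u$intercept)
  pred_path <- as.numeric(predict_path(path, X, lam))
  expect_equal(pred_direct, pred_path, tolerance = 1e-10)
})
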