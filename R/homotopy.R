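#' LASSO problem specification
#'
#' The penalised least-squares problem
#' \deqn{\frac{1}{2N}\|y - X\beta\|_2^2 + \lambda \sum_j |\beta_j|}
#' whose solution, as a function of the shrinkage parameter `lambda`, is a
#' piecewise-linear path traced by the homotopy solver [solve_path()].
#'
#' @param X numeric design matrix, observations x predictors.
#' @param y numeric response of length `nrow(X)`.
#' @param standardize logical; centre `y` and z-score the columns of `X`
#'   before solving (default TRUE — the l1 penalty is scale-sensitive).
#'   Coefficients are then reported on the standardised scale; see
#'   [unstandardize_coefs()].
#' @param lambda_min_ratio path termination: the path is traced from
#'   `lambda_max` down to `lambda_min_ratio * lambda_max` (default 1e-4,
#'   i.e. "approximately zero").
#' @return an object of class `lasso_problem`.
#' @export
lasso_problem <- function(X, y, standardize = TRUE, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in X or y")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (ncol(X) < 1L) stop("need at least 1 predictor")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("`lambda_min_ratio` must be in (0, 1)")
  if (standardize) {
    s <- apply(X, 2, stats::sd)
    if (any(s == 0))
      stop("zero-variance column(s) ", paste(which(s == 0), collapse = ", "),
           " cannot be standardized")
  }
  structure(list(X = X, y = y, standardize = isTRUE(standardize),
                 lambda_min_ratio = lambda_min_ratio),
            class = "lasso_problem")
}

# Internal: apply the problem's standardization, returning the working
# matrices plus the transform needed to undo it.
standardize_problem <- function(prob) {
  X <- prob$X
  y <- prob$y
  if (prob$standardize) {
    xc <- colMeans(X)
    xs <- apply(X, 2, stats::sd)
    X <- sweep(sweep(X, 2, xc), 2, xs, "/")
    yc <- mean(y)
    y <- y - yc
  } else {
    xc <- rep(0, ncol(X)); xs <- rep(1, ncol(X)); yc <- 0
  }
  list(X = X, y = y, x_center = xc, x_scale = xs, y_center = yc)
}

#' Entry point of the LASSO path
#'
#' `lambda_max = max_j |X_j' y| / N` (after the problem's configured
#' standardisation): the smallest penalty at which the solution is
#' identically zero. For any `lambda >= lambda_max` no predictor's
#' correlation with the residual can reach the penalty level, so every
#' coefficient stays at zero.
#'
#' @param prob a [lasso_problem()].
#' @return a single non-negative number (0 when `y` is zero after centring).
#' @export
lambda_max <- function(prob) {
  stopifnot(inherits(prob, "lasso_problem"))
  w <- standardize_problem(prob)
  max(abs(crossprod(w$X, w$y)) / nrow(w$X))
}

# Internal: solve G d = s with a ridge fallback when G is numerically
# singular (warns, per the documented contract).
solve_direction <- function(G, s) {
  d <- tryCatch(solve(G, s), error = function(e) NULL)
  if (is.null(d) || any(!is.finite(d))) {
    warning("rank-deficient active Gram matrix; using ridge-stabilized solve")
    d <- solve(G + diag(1e-10, nrow(G)), s)
  }
  d
}

#' Trace the LASSO solution path by homotopy
#'
#' LARS-style homotopy in the penalty parameter: starting at
#' `lambda_max`, where the solution is the zero vector, the solver follows
#' the piecewise-linear solution path downwards. At each breakpoint either
#' an inactive predictor's residual correlation reaches the current
#' penalty level and it enters the active set, or an active coefficient
#' crosses zero and it leaves. Between breakpoints coefficients move
#' linearly in `lambda` along the direction solving the active-set normal
#' equations with the active sign vector. Tracing continues until
#' `lambda <= lambda_min_ratio * lambda_max`; at the end of the path the
#' solution coincides with (penalised-free) least squares on full-rank
#' problems.
#'
#' Every returned breakpoint satisfies the KKT optimality certificate:
#' active predictors have residual correlation `lambda * sign(beta_j)`,
#' inactive ones are bounded by `lambda` in absolute value.
#'
#' Determinism: ties in entry events (within 1e-12) are resolved toward
#' the smaller column index, and a removal occurring at the same `lambda`
#' as an entry is processed first.
#'
#' @param prob a [lasso_problem()].
#' @return an object of class `lasso_path`: fields `breakpoints`
#'   (strictly decreasing lambdas), `coefs` (predictors x breakpoints
#'   matrix), `active_sets` (list of integer supports), `events`
#'   (data frame of add/remove records), `lambda_max`, and the
#'   standardisation transform.
#' @export
solve_path <- function(prob) {
  stopifnot(inherits(prob, "lasso_problem"))
  w <- standardize_problem(prob)
  X <- w$X; y <- w$y
  N <- nrow(X); P <- ncol(X)
  tol <- 1e-12

  c_vec <- as.numeric(crossprod(X, y)) / N
  lam0 <- max(abs(c_vec))
  mk_path <- function(bps, coefs, act, events) {
    structure(list(breakpoints = bps, coefs = coefs, active_sets = act,
                   events = events, lambda_max = lam0,
                   x_center = w$x_center, x_scale = w$x_scale,
                   y_center = w$y_center, standardize = prob$standardize,
                   n_obs = N),
              class = "lasso_path")
  }
  if (lam0 <= tol) {
    return(mk_path(0, matrix(0, P, 1), list(integer(0)),
                   data.frame(lambda = numeric(0), type = character(0),
                              var = integer(0))))
  }
  lam_min <- prob$lambda_min_ratio * lam0
  max_active <- min(N - 1L, P)

  beta <- numeric(P)
  # first entry: the most correlated predictor (smallest index on ties)
  active <- which(abs(c_vec) > lam0 - tol)[1]
  signs <- sign(c_vec[active])
  lam <- lam0

  bps <- lam0
  coefs <- matrix(beta, P, 1)
  act_sets <- list(integer(0))
  ev <- list(list(lambda = lam0, type = "add", var = active))

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L * P + 100L) {
      warning("homotopy iteration cap reached; returning path so far")
      break
    }
    XA <- X[, active, drop = FALSE]
    G <- crossprod(XA) / N
    d <- as.numeric(solve_direction(G, signs))
    u <- XA %*% d
    a_all <- as.numeric(crossprod(X, u)) / N

    gamma_max <- lam - lam_min

    # removal candidates: an active coefficient hits zero
    gdrop <- -beta[active] / d
    gdrop[!is.finite(gdrop) | gdrop <= tol] <- Inf
    g_rem <- min(gdrop)
    var_rem <- if (is.finite(g_rem))
      active[which(gdrop <= g_rem + tol)[1]] else NA_integer_

    # entry candidates: an inactive correlation catches up with lambda
    g_add <- Inf
    var_add <- NA_integer_
    if (length(active) < max_active) {
      inact <- setdiff(seq_len(P), active)
      if (length(inact)) {
        cj <- c_vec[inact]; aj <- a_all[inact]
        g1 <- (lam - cj) / (1 - aj)
        g2 <- (lam + cj) / (1 + aj)
        g1[!is.finite(g1) | g1 <= tol] <- Inf
        g2[!is.finite(g2) | g2 <= tol] <- Inf
        gent <- pmin(g1, g2)
        g_add <- min(gent)
        if (is.finite(g_add))   # smallest column index on ties
          var_add <- inact[which(gent <= g_add + tol)[1]]
      }
    }

    # a removal at (numerically) the same lambda is processed first
    if (g_rem <= g_add + tol) {
      cand_gamma <- g_rem; cand_type <- "remove"; cand_var <- var_rem
    } else {
      cand_gamma <- g_add; cand_type <- "add"; cand_var <- var_add
    }

    if (!is.finite(cand_gamma) || cand_gamma >= gamma_max - tol) {
      beta[active] <- beta[active] + gamma_max * d
      lam <- lam_min
      bps <- c(bps, lam)
      coefs <- cbind(coefs, beta)
      act_sets <- c(act_sets, list(which(abs(beta) > tol)))
      break
    }

    beta[active] <- beta[active] + cand_gamma * d
    lam <- lam - cand_gamma
    c_vec <- as.numeric(crossprod(X, y - X %*% beta)) / N

    if (cand_type == "remove") {
      beta[cand_var] <- 0
      keep <- active != cand_var
      active <- active[keep]
      signs <- signs[keep]
      if (!length(active)) {
        # support emptied: beta stays zero while lambda falls to the next
        # entry level max|c| (or to lambda_min if that is reached first)
        bps <- c(bps, lam)
        coefs <- cbind(coefs, beta)
        act_sets <- c(act_sets, list(integer(0)))
        ev <- c(ev, list(list(lambda = lam, type = "remove", var = cand_var)))
        lam_next <- max(abs(c_vec))
        if (lam_next <= lam_min + tol) {
          bps <- c(bps, lam_min)
          coefs <- cbind(coefs, beta)
          act_sets <- c(act_sets, list(integer(0)))
          break
        }
        lam <- lam_next
        j <- order(-abs(c_vec))[1]
        active <- j
        signs <- sign(c_vec[j])
        bps <- c(bps, lam)
        coefs <- cbind(coefs, beta)
        act_sets <- c(act_sets, list(integer(0)))
        ev <- c(ev, list(list(lambda = lam, type = "add", var = j)))
        next
      }
    } else {
      active <- c(active, cand_var)
      signs <- c(signs, sign(c_vec[cand_var]))
    }
    bps <- c(bps, lam)
    coefs <- cbind(coefs, beta)
    act_sets <- c(act_sets, list(which(abs(beta) > tol)))
    ev <- c(ev, list(list(lambda = lam, type = cand_type, var = cand_var)))

    if (lam <= lam_min + tol) break
  }

  events <- do.call(rbind, lapply(ev, as.data.frame))
  dimnames(coefs) <- list(colnames(prob$X), NULL)
  mk_path(as.numeric(bps), coefs, act_sets, events)
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path> %d breakpoints, lambda %.4g .. %.4g, final support %d/%d\n",
              length(x$breakpoints), x$breakpoints[1],
              x$breakpoints[length(x$breakpoints)],
              length(x$active_sets[[length(x$active_sets)]]), nrow(x$coefs)))
  invisible(x)
}

#' Solution at an arbitrary penalty level
#'
#' Because the path is piecewise-linear in `lambda`, the exact solution at
#' any penalty between two breakpoints is the linear interpolation of the
#' bracketing breakpoint solutions. For `lambda` above the path entry
#' point the solution is the zero vector; below the final breakpoint the
#' last solution is returned with a warning.
#'
#' @param path a [solve_path()] result.
#' @param lam penalty level (>= 0).
#' @return coefficient vector (standardised scale if the problem was
#'   standardised).
#' @export
solution_at <- function(path, lam) {
  stopifnot(inherits(path, "lasso_path"), is.finite(lam), lam >= 0)
  bp <- path$breakpoints
  if (lam >= bp[1]) return(path$coefs[, 1] * 0)
  K <- length(bp)
  if (lam < bp[K]) {
    warning("lambda below the end of the traced path; returning the final solution")
    return(path$coefs[, K])
  }
  k <- findInterval(-lam, -bp)      # segment with bp[k] >= lam >= bp[k+1]
  if (k >= K) return(path$coefs[, K])
  w <- (bp[k] - lam) / (bp[k] - bp[k + 1])
  (1 - w) * path$coefs[, k] + w * path$coefs[, k + 1]
}

# Internal: coefficients at a decreasing grid of lambdas (columnwise).
coefs_at <- function(path, lambdas) {
  vapply(lambdas, function(l) suppressWarnings(solution_at(path, l)),
         numeric(nrow(path$coefs)))
}

#' Predictions from a path solution
#'
#' Applies the path's stored standardisation to new data and evaluates
#' `X beta + intercept` at the requested penalty levels.
#'
#' @param path a [solve_path()] result.
#' @param X new design matrix on the original scale.
#' @param lambdas penalty levels.
#' @return matrix observations x lambdas of predictions.
#' @export
predict_path <- function(path, X, lambdas) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, path$x_center), 2, path$x_scale, "/")
  B <- coefs_at(path, lambdas)
  sweep(Xs %*% B, 2, -path$y_center)   # adds y_center back
}

#' Coefficients on the original data scale
#'
#' Undoes the problem's standardisation: returns slopes `beta_j / s_j` and
#' the implied intercept.
#'
#' @param path a [solve_path()] result.
#' @param lam penalty level.
#' @return list with `beta` (original-scale slopes) and `intercept`.
#' @export
unstandardize_coefs <- function(path, lam) {
  b <- solution_at(path, lam)
  beta <- b / path$x_scale
  list(beta = beta,
       intercept = path$y_center - sum(path$x_center * beta))
}

#' KKT optimality residual of a candidate solution
#'
#' Measures violation of the LASSO optimality conditions at penalty
#' `lam`: for active coefficients the residual correlation must equal
#' `lam * sign(beta_j)`; for inactive ones it must not exceed `lam`.
#' Returns the largest violation (0 for an exact optimum).
#'
#' @param prob a [lasso_problem()].
#' @param beta coefficient vector on the problem's working scale.
#' @param lam penalty level.
#' @param active_tol coefficients with absolute value above this count as
#'   active (default 1e-10).
#' @return maximum KKT violation (non-negative scalar).
#' @export
kkt_residual <- function(prob, beta, lam, active_tol = 1e-10) {
  w <- standardize_problem(prob)
  cvec <- as.numeric(crossprod(w$X, w$y - w$X %*% beta)) / nrow(w$X)
  act <- abs(beta) > active_tol
  v_act <- if (any(act)) max(abs(cvec[act] - lam * sign(beta[act]))) else 0
  v_inact <- if (any(!act)) max(0, abs(cvec[!act]) - lam) else 0
  max(v_act, v_inact)
}
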