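#' Regression design for channel selection
#'
#' Maps a labelled HbO recording to a LASSO problem whose predictors are
#' the channels: rows are the time samples inside the analysis blocks
#' (task blocks and inter-trial rest blocks; lead-in rest and baseline
#' excluded, see [analysis_blocks()]), the response is +1 for task samples
#' and -1 for rest samples, and standardisation is switched on so the
#' penalty treats channels symmetrically.
#'
#' @param rec a preprocessed HbO [nirs_recording()].
#' @param paradigm a [nirs_paradigm()] covering the recording.
#' @param label_shift_s hemodynamic-lag compensation (seconds, >= 0):
#'   sample `k` is labelled by the block containing `t_k - label_shift_s`.
#'   Defaults to 6 s, the canonical response time-to-peak; without it the
#'   evoked response (which peaks ~6 s after block onset and decays well
#'   into the following rest) is nearly orthogonal to the instantaneous
#'   block labels and per-sample regression carries almost no signal. Set
#'   to 0 for strictly instantaneous labelling.
#' @return a [lasso_problem()] with X = samples x channels.
#' @export
build_design <- function(rec, paradigm, label_shift_s = 6) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(paradigm, "nirs_paradigm"))
  n <- ncol(rec$values)
  shift <- as.integer(round(label_shift_s * rec$fs))
  blocks <- analysis_blocks(paradigm)
  idx <- sort(unlist(lapply(blocks, block_sample_idx, paradigm = paradigm,
                            fs = rec$fs, n_samples = n)))
  labs <- paradigm_labels(paradigm, rec$fs, n)[pmax(1L, idx - shift)]
  y <- ifelse(labs == "task", 1, -1)
  if (length(unique(y)) < 2L)
    stop("design covers a single class; need both task and rest samples")
  X <- t(rec$values[, idx, drop = FALSE])
  colnames(X) <- rec$channel_labels
  prob <- lasso_problem(X, y, standardize = TRUE)
  # block membership of each row: the CV in select_channels holds out
  # whole trials, since adjacent samples are strongly autocorrelated
  prob$groups <- rep(seq_along(blocks),
                     vapply(blocks, function(b)
                       length(block_sample_idx(paradigm, b, rec$fs, n)),
                       integer(1)))
  prob$group_labels <- paradigm$blocks$label[blocks]
  prob
}

#' Homotopy-based selection of informative channels
#'
#' Traces the full LASSO path of the channel-regression problem, picks the
#' penalty minimising mean squared prediction error under stratified
#' k-fold cross-validation on a 50-point log-spaced penalty grid spanning
#' the path, and returns the channels with nonzero coefficients at that
#' penalty. If the CV-optimal penalty selects nothing, the result falls
#' back to the largest penalty with at least one nonzero coefficient and
#' is flagged.
#'
#' When the problem carries block-membership information (as built by
#' [build_design()]), cross-validation folds hold out whole trials
#' (stratified over task and rest blocks) rather than individual samples:
#' consecutive samples are strongly autocorrelated, and sample-level folds
#' would let chance alignments of a channel's slow noise with the block
#' structure leak between training and held-out sets, biasing the penalty
#' choice toward dense solutions.
#'
#' @param prob a [lasso_problem()] from [build_design()].
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment (deterministic).
#' @param n_grid penalty-grid resolution (default 50).
#' @return object of class `channel_selection`: `selected` (1-based
#'   channel indices), `lambda_chosen`, `coef_magnitudes`, `cv_curve`
#'   (data frame of lambda and CV mean squared error), and `fallback`
#'   flag.
#' @export
select_channels <- function(prob, folds = 5, seed = 1, n_grid = 50) {
  stopifnot(inherits(prob, "lasso_problem"))
  path <- solve_path(prob)
  lam_max <- path$lambda_max
  if (lam_max <= 0) stop("response carries no signal (lambda_max = 0)")
  lam_min <- prob$lambda_min_ratio * lam_max
  grid <- exp(seq(log(lam_max), log(lam_min), length.out = n_grid))

  if (!is.null(prob$groups)) {
    block_fold <- stratified_folds(prob$group_labels, folds, seed)
    fold_id <- block_fold[prob$groups]
  } else {
    fold_id <- stratified_folds(ifelse(prob$y > 0, "a", "b"), folds, seed)
  }
  sse <- matrix(0, folds, n_grid)
  ntest <- integer(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    sub <- lasso_problem(prob$X[!te, , drop = FALSE], prob$y[!te],
                         standardize = prob$standardize,
                         lambda_min_ratio = prob$lambda_min_ratio)
    p_f <- solve_path(sub)
    pred <- predict_path(p_f, prob$X[te, , drop = FALSE], grid)
    sse[f, ] <- colSums((pred - prob$y[te])^2)
    ntest[f] <- sum(te)
  }
  cv_mse <- colSums(sse) / sum(ntest)
  best <- which.min(cv_mse)           # ties: larger lambda (sparser)
  lam_star <- max(grid[best], min(path$breakpoints))

  coef_star <- solution_at(path, lam_star)
  nz <- which(abs(coef_star) > 1e-8)
  fallback <- FALSE
  if (!length(nz)) {
    # largest lambda on the grid with a nonzero coefficient
    for (l in pmax(grid, min(path$breakpoints))) {
      b <- solution_at(path, l)
      if (any(abs(b) > 1e-8)) {
        lam_star <- l; coef_star <- b; nz <- which(abs(b) > 1e-8)
        break
      }
    }
    fallback <- TRUE
    if (!length(nz)) stop("no penalty level yields a nonzero coefficient")
  }
  structure(list(selected = nz,
                 lambda_chosen = lam_star,
                 coef_magnitudes = abs(coef_star),
                 cv_curve = data.frame(lambda = grid, cv_mse = cv_mse),
                 fallback = fallback,
                 channel_labels = colnames(prob$X)),
            class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat(sprintf("<channel_selection> %d channel(s) at lambda = %.4g%s\n",
              length(x$selected), x$lambda_chosen,
              if (x$fallback) " (fallback)" else ""))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a recording to selected channels
#'
#' @param rec a [nirs_recording()].
#' @param selection a [select_channels()] result or an integer vector of
#'   channel indices.
#' @return recording containing only the selected channels, labels kept.
#' @export
restrict_recording <- function(rec, selection) {
  stopifnot(inherits(rec, "nirs_recording"))
  idx <- if (inherits(selection, "channel_selection")) selection$selected
         else as.integer(selection)
  if (!length(idx)) stop("empty channel selection")
  if (any(idx < 1L | idx > nrow(rec$values)))
    stop("selection indices out of range")
  nirs_recording(rec$values[idx, , drop = FALSE], rec$fs, rec$kind,
                 channel_labels = rec$channel_labels[idx],
                 wavelengths_nm = rec$wavelengths_nm)
}
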