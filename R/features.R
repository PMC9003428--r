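#' Statistical spatial features
#'
#' Per-block, per-channel summary statistics used as classification
#' features: signal mean, signal peak (maximum), sample variance
#' (denominator n - 1), and skewness (third standardised moment,
#' population convention with divisor N).
#'
#' @param x numeric vector of samples.
#' @return a single numeric value.
#' @name statistical-features
NULL

#' @rdname statistical-features
#' @export
stat_mean <- function(x) {
  if (!length(x)) stop("empty sample vector")
  sum(x) / length(x)
}

#' @rdname statistical-features
#' @export
stat_variance <- function(x) {
  if (length(x) < 2L) stop("variance needs at least 2 samples")
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1L)
}

#' @rdname statistical-features
#' @export
stat_skewness <- function(x) {
  if (length(x) < 3L) stop("skewness needs at least 3 samples")
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / n)
  if (s == 0) stop("skewness undefined for zero-variance input")
  sum((x - m)^3) / (n * s^3)
}

#' @rdname statistical-features
#' @export
stat_peak <- function(x) {
  if (!length(x)) stop("empty sample vector")
  max(x)
}

stat_funs <- list(mean = stat_mean, peak = stat_peak,
                  variance = stat_variance, skewness = stat_skewness)

#' Block-wise feature table
#'
#' Builds an observations x features matrix: one observation per analysis
#' block (see [analysis_blocks()]: task blocks and inter-trial rest blocks;
#' lead-in rest and baseline excluded), with the chosen statistics of each
#' channel's samples within the block as features, ordered channel-major
#' (`CH1_mean, CH1_peak, ..., CH2_mean, ...`).
#'
#' @param rec a (typically preprocessed) [nirs_recording()].
#' @param paradigm a [nirs_paradigm()] covering the recording.
#' @param feature_set subset of `c("mean", "peak", "variance", "skewness")`.
#'   The three-feature set mean/peak/variance and the four-feature set
#'   adding skewness are the two standard choices.
#' @return object of class `feature_table`: list with `matrix`
#'   (observations x features), `obs_labels` (block label per row), and
#'   `feature_names` (`"CH<j>_<stat>"`).
#' @export
build_feature_table <- function(rec, paradigm,
                                feature_set = c("mean", "peak", "variance")) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(paradigm, "nirs_paradigm"))
  feature_set <- match.arg(feature_set, names(stat_funs), several.ok = TRUE)
  blocks <- analysis_blocks(paradigm)
  if (!length(blocks)) stop("paradigm has no analysis blocks")
  n <- ncol(rec$values)
  idx_list <- lapply(blocks, block_sample_idx, paradigm = paradigm,
                     fs = rec$fs, n_samples = n)
  short <- lengths(idx_list) < 3L
  if (any(short))
    stop("block(s) ", paste(blocks[short], collapse = ", "),
         " have fewer than 3 samples")
  P <- nrow(rec$values)
  fnames <- as.vector(t(outer(rec$channel_labels, feature_set, paste, sep = "_")))
  mat <- t(vapply(idx_list, function(idx) {
    seg <- rec$values[, idx, drop = FALSE]
    # channel-major: all statistics of CH1, then CH2, ...
    as.vector(vapply(seq_len(P), function(j)
      vapply(feature_set, function(f) stat_funs[[f]](seg[j, ]), numeric(1)),
      numeric(length(feature_set))))
  }, numeric(P * length(feature_set))))
  colnames(mat) <- fnames
  structure(list(matrix = mat,
                 obs_labels = paradigm$blocks$label[blocks],
                 feature_names = fnames,
                 feature_set = feature_set,
                 channels = rec$channel_labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d observations x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$feature_set, collapse = ", ")))
  print(table(x$obs_labels))
  invisible(x)
}
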