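#' Block-design experimental paradigm
#'
#' An ordered sequence of labelled blocks tiling the experiment timeline.
#' Blocks are half-open intervals `[onset, onset + duration)`; they must be
#' sorted, non-overlapping, and cover `[0, total_duration_s]` without gaps.
#'
#' @param blocks data frame with columns `label` (one of `"rest"`, `"task"`,
#'   `"baseline"`), `onset_s` and `duration_s` (seconds, durations > 0).
#'
#' @return an object of class `nirs_paradigm` with fields `blocks` and
#'   `total_duration_s`.
#' @export
nirs_paradigm <- function(blocks) {
  blocks <- as.data.frame(blocks)
  need <- c("label", "onset_s", "duration_s")
  if (!all(need %in% names(blocks)))
    stop("`blocks` needs columns label, onset_s, duration_s")
  blocks$label <- as.character(blocks$label)
  ok <- blocks$label %in% c("rest", "task", "baseline")
  if (!all(ok))
    stop("unknown block label(s): ", paste(unique(blocks$label[!ok]), collapse = ", "))
  if (nrow(blocks) < 1L) stop("paradigm needs at least one block")
  if (any(!is.finite(blocks$onset_s)) || any(!is.finite(blocks$duration_s)))
    stop("block onsets/durations must be finite")
  if (any(blocks$duration_s <= 0)) stop("block durations must be > 0")
  if (is.unsorted(blocks$onset_s, strictly = TRUE))
    stop("blocks must be sorted by onset with no duplicates")
  ends <- blocks$onset_s + blocks$duration_s
  if (abs(blocks$onset_s[1]) > 1e-9)
    stop("first block must start at 0")
  if (nrow(blocks) > 1L &&
      any(abs(blocks$onset_s[-1] - ends[-nrow(blocks)]) > 1e-9))
    stop("blocks must be contiguous (no gaps or overlaps)")
  rownames(blocks) <- NULL
  structure(list(blocks = blocks[need],
                 total_duration_s = ends[nrow(blocks)]),
            class = "nirs_paradigm")
}

#' @export
print.nirs_paradigm <- function(x, ...) {
  tab <- table(x$blocks$label)
  cat(sprintf("<nirs_paradigm> %d blocks over %.1f s (%s)\n",
              nrow(x$blocks), x$total_duration_s,
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Default treadmill-walking block paradigm
#'
#' The acquisition structure the package emulates: an initial quiet rest,
#' then `n_trials` trials of a walking task followed by a standing rest,
#' closed by a final rest used for baseline correction. With the defaults
#' (30 + 10 x (10 + 20) + 30 s) the total duration is 360 s.
#'
#' @param n_trials number of task/rest trials (default 10).
#' @param initial_rest_s lead-in rest duration (s).
#' @param task_s walking-task duration per trial (s).
#' @param rest_s post-task rest duration per trial (s).
#' @param baseline_s closing baseline rest duration (s).
#' @return a [nirs_paradigm()].
#' @export
default_paradigm <- function(n_trials = 10, initial_rest_s = 30,
                             task_s = 10, rest_s = 20, baseline_s = 30) {
  onsets <- initial_rest_s + (seq_len(n_trials) - 1L) * (task_s + rest_s)
  blocks <- rbind(
    data.frame(label = "rest", onset_s = 0, duration_s = initial_rest_s),
    data.frame(label = rep(c("task", "rest"), n_trials),
               onset_s = as.vector(rbind(onsets, onsets + task_s)),
               duration_s = rep(c(task_s, rest_s), n_trials)),
    data.frame(label = "baseline",
               onset_s = initial_rest_s + n_trials * (task_s + rest_s),
               duration_s = baseline_s))
  nirs_paradigm(blocks)
}

#' Per-sample class labels from a paradigm
#'
#' Sample `k` (0-based, time `k / fs`) receives the label of the block whose
#' half-open interval `[onset, onset + duration)` contains it; a sample at
#' exactly a block onset belongs to the new block.
#'
#' @param paradigm a [nirs_paradigm()].
#' @param fs sampling rate in Hz.
#' @param n_samples number of samples to label.
#' @return character vector of length `n_samples`.
#' @export
paradigm_labels <- function(paradigm, fs, n_samples) {
  stopifnot(inherits(paradigm, "nirs_paradigm"), fs > 0, n_samples >= 1)
  t <- (seq_len(n_samples) - 1L) / fs
  if (any(t >= paradigm$total_duration_s + 1e-9))
    stop("sample times extend beyond paradigm coverage (",
         max(t), " s >= ", paradigm$total_duration_s, " s)")
  idx <- findInterval(t + 1e-12, paradigm$blocks$onset_s)
  paradigm$blocks$label[idx]
}

#' Indices of the analysis blocks of a paradigm
#'
#' The observation convention used throughout: classification observations
#' come from the trial portion only — task blocks and the inter-trial rest
#' blocks. The lead-in rest (a rest block starting at t = 0) and any
#' baseline block are excluded, which keeps the two classes balanced
#' (10 task vs 10 rest blocks under the default paradigm).
#'
#' @param paradigm a [nirs_paradigm()].
#' @return integer vector of row indices into `paradigm$blocks`.
#' @export
analysis_blocks <- function(paradigm) {
  b <- paradigm$blocks
  keep <- b$label %in% c("task", "rest")
  keep[b$label == "rest" & abs(b$onset_s) < 1e-9] <- FALSE
  which(keep)
}

# Internal: 0-based sample indices falling in block i (half-open interval).
block_sample_idx <- function(paradigm, i, fs, n_samples) {
  on <- paradigm$blocks$onset_s[i]
  off <- on + paradigm$blocks$duration_s[i]
  k <- seq.int(0L, n_samples - 1L)
  which(k / fs >= on - 1e-12 & k / fs < off - 1e-12)
}
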