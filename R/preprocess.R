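#' Preprocessing filter specification
#'
#' Bundles the tunable parameters of the denoising chain: a zero-phase
#' Butterworth band-pass (0.01-0.5 Hz by default, the conventional fNIRS
#' hemodynamic band), Gaussian temporal smoothing (FWHM in seconds), and a
#' discrete-cosine detrend that removes components with periods longer
#' than `dct_cutoff_s`.
#'
#' @param hp_hz high-pass cutoff in Hz (default 0.01).
#' @param lp_hz low-pass cutoff in Hz (default 0.5); must stay below the
#'   Nyquist rate when applied.
#' @param order Butterworth order (default 4), applied forward-backward.
#' @param zero_phase logical; forward-backward filtering (default TRUE).
#' @param fwhm_s Gaussian smoothing kernel FWHM in seconds (default 4).
#' @param dct_cutoff_s detrend period cutoff in seconds (default 128).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(hp_hz = 0.01, lp_hz = 0.5, order = 4,
                        zero_phase = TRUE, fwhm_s = 4, dct_cutoff_s = 128) {
  if (!(hp_hz > 0 && lp_hz > hp_hz)) stop("need 0 < hp_hz < lp_hz")
  if (order < 1) stop("`order` must be >= 1")
  if (fwhm_s <= 0) stop("`fwhm_s` must be > 0")
  if (dct_cutoff_s <= 0) stop("`dct_cutoff_s` must be > 0")
  structure(list(hp_hz = hp_hz, lp_hz = lp_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase), fwhm_s = fwhm_s,
                 dct_cutoff_s = dct_cutoff_s),
            class = "filter_spec")
}

# Zero-phase IIR filtering with odd-reflect padding and steady-state
# initialisation at each end (so a constant input maps to its steady-state
# response exactly, with no start-up transient).
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  pad <- min(3L * (nf - 1L), n - 1L)
  if (n <= nf * 3L) stop("signal too short for the requested filter (", n, " samples)")
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  h1 <- sum(b) / sum(a)
  run <- function(v)
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1], nf - 1L),
                              init.y = rep(h1 * v[1], nf - 1L)))
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_per_channel <- function(rec, f) {
  out <- t(apply(rec$values, 1, f))
  with_values(rec, out)
}

#' Zero-phase Butterworth band-pass filter
#'
#' High-pass then low-pass Butterworth filtering, each applied
#' forward-backward when `spec$zero_phase` is set, so passband components
#' incur no phase shift. The effective magnitude response is the squared
#' single-pass response.
#'
#' @param rec a [nirs_recording()].
#' @param spec a [filter_spec()].
#' @return filtered recording of the same shape.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$lp_hz >= nyq)
    stop("low-pass cutoff ", spec$lp_hz, " Hz must be below Nyquist (", nyq, " Hz)")
  hp <- signal::butter(spec$order, spec$hp_hz / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$lp_hz / nyq, type = "low")
  one <- function(x) {
    if (spec$zero_phase) {
      x <- filtfilt_reflect(hp$b, hp$a, x)
      filtfilt_reflect(lp$b, lp$a, x)
    } else {
      x <- as.numeric(signal::filter(hp$b, hp$a, x))
      as.numeric(signal::filter(lp$b, lp$a, x))
    }
  }
  apply_per_channel(rec, one)
}

#' Gaussian temporal smoothing
#'
#' Convolution with a unit-sum truncated Gaussian kernel
#' (sigma = FWHM / (2 sqrt(2 ln 2))), reflect-padded at the edges. This is
#' the package's hemodynamic-response smoothing step: it suppresses
#' high-frequency noise while leaving slow task-locked responses intact.
#'
#' @param rec a [nirs_recording()].
#' @param fwhm_s kernel full width at half maximum in seconds.
#' @return smoothed recording.
#' @export
gaussian_smooth <- function(rec, fwhm_s = 4) {
  stopifnot(inherits(rec, "nirs_recording"), fwhm_s > 0)
  if (fwhm_s * rec$fs < 1)
    stop("fwhm_s * fs must be >= 1 (kernel narrower than one sample)")
  sigma <- fwhm_s / (2 * sqrt(2 * log(2))) * rec$fs   # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- ncol(rec$values)
  pad <- min(half, n - 1L)
  one <- function(x) {
    ext <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    full <- stats::convolve(ext, rev(k), type = "open")
    full[(half + pad + 1):(half + pad + n)]
  }
  out <- apply_per_channel(rec, one)
  attr(out, "kernel") <- k
  out
}

#' Discrete-cosine-transform detrending
#'
#' Removes slow drift by projecting out the constant term and the DCT-II
#' basis functions whose period exceeds `cutoff_s`; the retained residual
#' is orthogonal to the removed basis.
#'
#' @param rec a [nirs_recording()].
#' @param cutoff_s period cutoff in seconds (default 128); basis functions
#'   with frequency below `1/cutoff_s` are removed.
#' @return detrended recording.
#' @export
dct_detrend <- function(rec, cutoff_s = 128) {
  stopifnot(inherits(rec, "nirs_recording"), cutoff_s > 0)
  n <- ncol(rec$values)
  dur <- n / rec$fs
  if (cutoff_s >= dur)
    stop("cutoff_s (", cutoff_s, " s) must be shorter than the recording (",
         round(dur, 1), " s)")
  K <- floor(2 * dur / cutoff_s)   # k-th basis has period 2*dur/k
  i <- seq_len(n) - 0.5
  basis <- vapply(seq_len(K), function(k) cos(pi * k * i / n), numeric(n))
  basis <- cbind(1, basis)
  # DCT basis is orthogonal on this grid; project columnwise
  norms <- colSums(basis^2)
  X <- rec$values
  coefs <- (X %*% basis) / rep(norms, each = nrow(X))
  with_values(rec, X - coefs %*% t(basis))
}

#' Baseline correction from a paradigm's baseline block
#'
#' Subtracts each channel's mean over the paradigm's baseline block(s)
#' (the closing rest period) from the entire series.
#'
#' @param rec a [nirs_recording()].
#' @param paradigm a [nirs_paradigm()] containing at least one block
#'   labelled `"baseline"`.
#' @return baseline-corrected recording.
#' @export
baseline_correct <- function(rec, paradigm) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(paradigm, "nirs_paradigm"))
  bl <- which(paradigm$blocks$label == "baseline")
  if (!length(bl)) stop("paradigm has no baseline block")
  idx <- unlist(lapply(bl, block_sample_idx, paradigm = paradigm,
                       fs = rec$fs, n_samples = ncol(rec$values)))
  if (!length(idx)) stop("baseline block contains no samples")
  mu <- rowMeans(rec$values[, idx, drop = FALSE])
  with_values(rec, rec$values - mu)
}

#' Standard preprocessing chain
#'
#' Band-pass -> Gaussian smoothing -> DCT detrend -> baseline correction,
#' each step as documented in [bandpass()], [gaussian_smooth()],
#' [dct_detrend()] and [baseline_correct()].
#'
#' @param rec a [nirs_recording()].
#' @param paradigm a [nirs_paradigm()] (needed for baseline correction;
#'   if it has no baseline block that step is skipped with a warning).
#' @param spec a [filter_spec()].
#' @return preprocessed recording.
#' @export
preprocess <- function(rec, paradigm, spec = filter_spec()) {
  rec <- bandpass(rec, spec)
  rec <- gaussian_smooth(rec, spec$fwhm_s)
  rec <- dct_detrend(rec, spec$dct_cutoff_s)
  if (any(paradigm$blocks$label == "baseline")) {
    rec <- baseline_correct(rec, paradigm)
  } else {
    warning("paradigm has no baseline block; baseline correction skipped")
  }
  rec
}
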