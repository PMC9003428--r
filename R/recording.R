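#' fNIRS time-series recording
#'
#' Container for a multi-channel fNIRS time series on a uniform sampling
#' grid. Rows are channels, columns are samples; sample `k` (0-based) sits
#' at time `k / fs` seconds, so the first sample is at t = 0.
#'
#' @param values numeric matrix, channels x samples. Concentration series
#'   are in micromolar (uM); optical-density series are dimensionless
#'   absorbance changes.
#' @param fs sampling rate in Hz (> 0).
#' @param kind one of `"hbo"`, `"hbr"`, `"optical_density"`.
#' @param channel_labels character vector of unique channel identifiers,
#'   one per row. Defaults to `"CH1"`, `"CH2"`, ... for concentration
#'   series; optical-density recordings carry a wavelength suffix.
#' @param wavelengths_nm numeric pair of wavelengths in nm. Required when
#'   (and only when) `kind = "optical_density"`, in which case the matrix
#'   must hold both wavelengths' channels (first wavelength block first).
#'
#' @return an object of class `nirs_recording`.
#' @export
nirs_recording <- function(values, fs,
                           kind = c("hbo", "hbr", "optical_density"),
                           channel_labels = NULL,
                           wavelengths_nm = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (channels x samples)")
  if (nrow(values) < 1L)
    stop("recording must contain at least one channel")
  if (!all(is.finite(values)))
    stop("recording contains NA/NaN/Inf values; missing data are rejected, not imputed")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")

  if (kind == "optical_density") {
    if (is.null(wavelengths_nm) || length(wavelengths_nm) != 2L ||
        !all(is.finite(wavelengths_nm)))
      stop("optical-density recordings require a pair of `wavelengths_nm`")
    if (nrow(values) %% 2L != 0L)
      stop("optical-density recordings need an even row count (both wavelengths per channel)")
  } else if (!is.null(wavelengths_nm)) {
    stop("`wavelengths_nm` is only meaningful for kind = \"optical_density\"")
  }

  if (is.null(channel_labels)) {
    channel_labels <- if (kind == "optical_density") {
      n <- nrow(values) / 2L
      c(paste0("CH", seq_len(n), "_", wavelengths_nm[1]),
        paste0("CH", seq_len(n), "_", wavelengths_nm[2]))
    } else {
      paste0("CH", seq_len(nrow(values)))
    }
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(values))
    stop("`channel_labels` length must equal the number of rows")
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique")
  rownames(values) <- channel_labels

  structure(
    list(values = values, fs = fs, kind = kind,
         channel_labels = channel_labels,
         wavelengths_nm = if (kind == "optical_density") as.numeric(wavelengths_nm) else NULL),
    class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %s: %d channel(s) x %d samples @ %.4g Hz (%.1f s)\n",
              x$kind, nrow(x$values), ncol(x$values), x$fs,
              ncol(x$values) / x$fs))
  if (!is.null(x$wavelengths_nm))
    cat(sprintf("  wavelengths: %g / %g nm\n",
                x$wavelengths_nm[1], x$wavelengths_nm[2]))
  cat("  channels:", paste(utils::head(x$channel_labels, 6), collapse = ", "),
      if (length(x$channel_labels) > 6) "..." else "", "\n")
  invisible(x)
}

#' Number of channels and samples of a recording
#' @param rec a `nirs_recording`.
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$values)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$values)

#' Sample times of a recording
#' @param rec a `nirs_recording`.
#' @return numeric vector of times in seconds, first sample at 0.
#' @export
sample_times <- function(rec) (seq_len(ncol(rec$values)) - 1L) / rec$fs

# Internal: replace the value matrix, keeping metadata.
with_values <- function(rec, values) {
  stopifnot(identical(dim(values), dim(rec$values)))
  rec$values <- values
  rownames(rec$values) <- rec$channel_labels
  rec
}
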