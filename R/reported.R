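#' Published subject-wise reference accuracies
#'
#' The subject-wise five-fold CV accuracies reported by the
#' treadmill-walking fNIRS study this pipeline re-implements, shipped as
#' a packaged delimited-text resource. Three methods: `lasso_selected`
#' (classification on homotopy-selected channels), `features_mpv`
#' (mean/peak/variance features of all channels) and `features_mpvs`
#' (adding skewness). Useful for checking the report-aggregation logic
#' against the study's printed summary row (the original recordings are
#' not publicly deposited, so the accuracies themselves are reference
#' values, not reproducible outputs).
#'
#' @param method optional filter: one of `"lasso_selected"`,
#'   `"features_mpv"`, `"features_mpvs"`.
#' @return data frame with columns `method`, `subject`, `lda`, `lr`,
#'   `svm` (accuracy in percent).
#' @export
reported_accuracies <- function(method = NULL) {
  path <- system.file("extdata", "reported_accuracies.csv",
                      package = "fnirsbci", mustWork = TRUE)
  df <- utils::read.csv(path)
  if (!is.null(method)) {
    method <- match.arg(method, unique(df$method))
    df <- df[df$method == method, ]
    rownames(df) <- NULL
  }
  df
}
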