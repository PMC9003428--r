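#' Read an fNIRS recording from delimited text
#'
#' The on-disk dialect is UTF-8 CSV: line 1 `# fs=<Hz>`, line 2
#' `# kind=<optical_density|hbo|hbr>[;wavelengths=<nm>,<nm>]`, line 3 a
#' header `time,CH1,...,CHn`, then one row per sample (time in seconds).
#'
#' @param path file to read.
#' @param kind optional expected kind; an error is raised if the file's
#'   declared kind differs.
#' @return a [nirs_recording()].
#' @export
read_timeseries <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4L)
    stop("format error at line ", length(lines),
         ": expected two header comments, a column header and data rows")

  m <- regmatches(lines[1], regexec("^#\\s*fs=([0-9.eE+-]+)\\s*$", lines[1]))[[1]]
  if (length(m) != 2L) stop("format error at line 1: expected `# fs=<Hz>`")
  fs <- as.numeric(m[2])

  m <- regmatches(lines[2], regexec(
    "^#\\s*kind=(optical_density|hbo|hbr)(;wavelengths=([0-9.]+),([0-9.]+))?\\s*$",
    lines[2]))[[1]]
  if (length(m) == 0L || m[2] == "")
    stop("format error at line 2: expected `# kind=<optical_density|hbo|hbr>[;wavelengths=<nm>,<nm>]`")
  file_kind <- m[2]
  wl <- if (m[3] != "") as.numeric(c(m[4], m[5])) else NULL
  if (!is.null(kind) && !identical(kind, file_kind))
    stop("file declares kind `", file_kind, "` but `", kind, "` was requested")

  header <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "time")
    stop("format error at line 3: header must be `time,<CH...>`")
  labels <- header[-1]
  if (anyDuplicated(labels))
    stop("format error at line 3: duplicate channel labels")

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) stop("format error: no data rows")
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop("format error at line ", bad[1] + 3L, ": expected ",
         length(header), " fields, found ", nfield[bad[1]])
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), nrow = length(header)))
  if (anyNA(vals)) {
    bad_row <- which(colSums(is.na(vals)) > 0)[1]
    stop("format error at line ", bad_row + 3L, ": non-numeric cell")
  }
  nirs_recording(vals[-1, , drop = FALSE], fs = fs, kind = file_kind,
                 channel_labels = labels, wavelengths_nm = wl)
}

#' Write an fNIRS recording as delimited text
#'
#' Inverse of [read_timeseries()]; the round trip preserves metadata
#' exactly and values to full double precision.
#'
#' @param rec a [nirs_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (nrow(rec$values) == 0L) stop("refusing to write a zero-channel recording")
  kind_line <- paste0("# kind=", rec$kind,
                      if (!is.null(rec$wavelengths_nm))
                        sprintf(";wavelengths=%g,%g",
                                rec$wavelengths_nm[1], rec$wavelengths_nm[2])
                      else "")
  t <- sample_times(rec)
  rows <- apply(rbind(sprintf("%.6f", t),
                      matrix(format(rec$values, digits = 17, scientific = TRUE,
                                    trim = TRUE),
                             nrow = nrow(rec$values))),
                2, paste, collapse = ",")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.17g", rec$fs), kind_line,
               paste(c("time", rec$channel_labels), collapse = ","), rows),
             con)
  invisible(path)
}

#' Read or write a paradigm file
#'
#' Plain CSV with a `label,onset_s,duration_s` header and one block per row.
#'
#' @param path file path.
#' @return [read_paradigm()]: a [nirs_paradigm()].
#' @export
read_paradigm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nirs_paradigm(df)
}

#' @rdname read_paradigm
#' @param paradigm a [nirs_paradigm()] to write.
#' @export
write_paradigm <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "nirs_paradigm"))
  utils::write.csv(paradigm$blocks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
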