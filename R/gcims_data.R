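# Data model and plain-text I/O for GC-IMS sample matrices.
#
# A GC-IMS run is a dense 2D intensity map: one row per GC retention time
# (seconds), one column per IMS drift time (milliseconds). Instrument
# vendors use proprietary native formats; this package defines a minimal
# tab-separated text dialect instead (see `read_spectrum` for the grammar),
# mirroring the common practice of exporting runs to text before analysis.

#' Construct a GC-IMS spectrum
#'
#' @param sample_id Character scalar identifying the sample.
#' @param retention Numeric vector of retention times in seconds, strictly
#'   increasing.
#' @param drift Numeric vector of drift times in milliseconds, strictly
#'   increasing.
#' @param intensities Numeric matrix of ion intensities with
#'   `length(retention)` rows and `length(drift)` columns; all values must
#'   be finite.
#'
#' @return An object of class `ims_spectrum`: a list with fields
#'   `sample_id`, `retention`, `drift` and `intensities`.
#' @export
#' @examples
#' sp <- ims_spectrum("s1", c(1, 2), c(5, 6), matrix(0:3, 2, 2))
#' dim(sp$intensities)
ims_spectrum <- function(sample_id, retention, drift, intensities) {
  sp <- structure(
    list(sample_id = as.character(sample_id)[1],
         retention = as.numeric(retention),
         drift = as.numeric(drift),
         intensities = intensities),
    class = "ims_spectrum"
  )
  validate_spectrum(sp)
  sp
}

#' Validate a GC-IMS spectrum object
#'
#' Checks the structural invariants: matrix dimensions match the axes, both
#' axes are strictly increasing and non-empty, and all intensities are
#' finite.
#'
#' @param sp An `ims_spectrum`.
#' @return `sp`, invisibly, if valid; otherwise an error.
#' @export
validate_spectrum <- function(sp) {
  if (!inherits(sp, "ims_spectrum")) stop_argument("not an ims_spectrum")
  m <- sp$intensities
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_format("intensities must be a numeric matrix")
  }
  if (length(sp$retention) < 1L || length(sp$drift) < 1L) {
    stop_format("axes must have length >= 1")
  }
  if (nrow(m) != length(sp$retention) || ncol(m) != length(sp$drift)) {
    stop_format(sprintf(
      "intensity matrix is %d x %d but axes have lengths %d (retention) and %d (drift)",
      nrow(m), ncol(m), length(sp$retention), length(sp$drift)))
  }
  if (anyNA(sp$retention) || any(diff(sp$retention) <= 0)) {
    stop_format("retention axis must be strictly increasing")
  }
  if (anyNA(sp$drift) || any(diff(sp$drift) <= 0)) {
    stop_format("drift axis must be strictly increasing")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop_format("intensities contain NA/NaN/Inf")
  }
  invisible(sp)
}

#' @export
print.ims_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ims_spectrum> %s: %d retention x %d drift, retention %.6g-%.6g s, drift %.6g-%.6g ms\n",
    x$sample_id, length(x$retention), length(x$drift),
    min(x$retention), max(x$retention), min(x$drift), max(x$drift)))
  invisible(x)
}

# Full-precision number formatting so a write/read cycle is the identity.
fmt_num <- function(x) sprintf("%.17g", x)

parse_numeric_fields <- function(fields, line_no, what) {
  suppressWarnings(v <- as.numeric(fields))
  if (anyNA(v)) {
    bad <- fields[is.na(v)][1]
    stop_format(sprintf("line %d: non-numeric %s value '%s'", line_no, what, bad))
  }
  v
}

#' Read a GC-IMS spectrum from its text export
#'
#' The dialect is UTF-8 text: any number of leading `#`-prefixed metadata
#' lines (`# sample_id: <id>` carries the sample identifier), one header
#' line whose first tab-separated field is the literal token `retention_s`
#' followed by the drift-time axis in milliseconds, then one line per
#' retention time holding the retention value (seconds) followed by the
#' intensity of every drift-time cell, all tab-separated.
#'
#' @param path Path to a spectrum text file.
#' @return An [ims_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sample_id <- NA_character_
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    meta <- sub("^#\\s*", "", lines[i])
    if (grepl("^sample_id\\s*:", meta)) {
      sample_id <- trimws(sub("^sample_id\\s*:", "", meta))
    }
    i <- i + 1L
  }
  if (i > length(lines)) stop_format("missing header line of drift times")
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "retention_s") {
    stop_format(sprintf(
      "line %d: header must start with 'retention_s' followed by drift times", i))
  }
  drift <- parse_numeric_fields(header[-1], i, "drift-time")
  n_drift <- length(drift)

  body <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  body_no <- seq.int(i + 1L, length.out = length(body))
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_no <- body_no[keep]
  if (length(body) == 0L) stop_format("no intensity rows after header")

  retention <- numeric(length(body))
  intens <- matrix(NA_real_, length(body), n_drift)
  for (j in seq_along(body)) {
    fields <- strsplit(body[j], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_drift + 1L) {
      stop_format(sprintf(
        "line %d: expected %d values (retention + %d drift cells), found %d",
        body_no[j], n_drift + 1L, n_drift, length(fields)))
    }
    v <- parse_numeric_fields(fields, body_no[j], "intensity")
    retention[j] <- v[1]
    intens[j, ] <- v[-1]
  }
  if (is.na(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  if (any(diff(retention) <= 0)) {
    stop_format(sprintf(
      "line %d: retention axis not strictly increasing",
      body_no[which(diff(retention) <= 0)[1] + 1L]))
  }
  if (any(diff(drift) <= 0)) {
    stop_format(sprintf("line %d: drift axis not strictly increasing", i))
  }
  ims_spectrum(sample_id, retention, drift, intens)
}

#' Write a GC-IMS spectrum to the text dialect
#'
#' Numbers are written at full double precision so that
#' `read_spectrum(write_spectrum(sp, path))` reproduces `sp` exactly.
#'
#' @param sp An [ims_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path) {
  validate_spectrum(sp)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop_io(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  out <- c(
    sprintf("# sample_id: %s", sp$sample_id),
    paste(c("retention_s", fmt_num(sp$drift)), collapse = "\t"),
    vapply(seq_along(sp$retention), function(r) {
      paste(c(fmt_num(sp$retention[r]), fmt_num(sp$intensities[r, ])),
            collapse = "\t")
    }, character(1))
  )
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
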