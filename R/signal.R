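#' Breathing surrogate signal
#'
#' A breathing signal is a tibble with columns `time_s` (seconds, strictly
#' increasing) and `pos_mm` (anterior-posterior surface displacement in mm),
#' carrying a sampling rate attribute (`rate_hz`, set only once the trace is
#' uniformly sampled) and a free-form metadata list (`meta`: subject id,
#' surrogate site, device, provenance).
#'
#' @param time_s Numeric vector of time stamps in seconds, strictly increasing.
#' @param pos_mm Numeric vector of displacements in millimetres, all finite.
#' @param rate_hz Sampling rate in Hz, or `NULL` for irregularly sampled data.
#' @param meta Named list of provenance fields.
#'
#' @return A `breathing_signal` tibble.
#' @examples
#' sig <- breathing_signal(seq(0, 1, by = 0.05), sin(seq(0, 1, by = 0.05)),
#'                         rate_hz = 20)
#' @export
breathing_signal <- function(time_s, pos_mm, rate_hz = NULL, meta = list()) {
  time_s <- as.double(time_s)
  pos_mm <- as.double(pos_mm)
  if (length(time_s) != length(pos_mm)) {
    bc_abort("bc_invalid_signal", "time_s and pos_mm must have equal length.")
  }
  if (anyNA(time_s) || anyNA(pos_mm) ||
      any(!is.finite(time_s)) || any(!is.finite(pos_mm))) {
    bc_abort("bc_invalid_signal", "breathing signal values must all be finite.")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    bc_abort("bc_invalid_signal", "timestamps must be strictly increasing.")
  }
  if (!is.null(rate_hz)) {
    rate_hz <- as.double(rate_hz)
    if (length(time_s) > 1 &&
        any(abs(diff(time_s) - 1 / rate_hz) > 1e-9)) {
      bc_abort("bc_invalid_signal",
               "rate_hz set but timestamps are not uniform at that rate.")
    }
  }
  new_breathing_signal(time_s, pos_mm, rate_hz, meta)
}

new_breathing_signal <- function(time_s, pos_mm, rate_hz, meta) {
  tibble::new_tibble(
    list(time_s = time_s, pos_mm = pos_mm),
    nrow = length(time_s),
    class = "breathing_signal",
    rate_hz = rate_hz,
    meta = meta
  )
}

#' Coerce a data frame to a breathing signal
#'
#' @param x Data frame with `time_s` and `pos_mm` columns.
#' @inheritParams breathing_signal
#' @return A `breathing_signal` tibble.
#' @export
as_breathing_signal <- function(x, rate_hz = NULL, meta = list()) {
  if (!all(c("time_s", "pos_mm") %in% names(x))) {
    bc_abort("bc_invalid_signal", "need `time_s` and `pos_mm` columns.")
  }
  breathing_signal(x$time_s, x$pos_mm, rate_hz = rate_hz, meta = meta)
}

#' @export
print.breathing_signal <- function(x, ...) {
  rate <- signal_rate(x)
  meta <- signal_meta(x)
  cat(sprintf("# breathing signal: %d samples, %.1f s, %s\n",
              nrow(x),
              if (nrow(x) > 1) x$time_s[nrow(x)] - x$time_s[1] else 0,
              if (is.null(rate)) "irregular" else sprintf("%g Hz", rate)))
  if (length(meta)) {
    cat("# meta:", paste(names(meta), unlist(lapply(meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Sampling rate of a breathing signal
#' @param sig A `breathing_signal`.
#' @return Rate in Hz, or `NULL` when irregularly sampled.
#' @export
signal_rate <- function(sig) attr(sig, "rate_hz")

#' Metadata of a breathing signal
#' @param sig A `breathing_signal`.
#' @return Named list.
#' @export
signal_meta <- function(sig) {
  m <- attr(sig, "meta")
  if (is.null(m)) list() else m
}

# rebuild a signal from the same provenance with new samples
signal_like <- function(sig, time_s, pos_mm, rate_hz = signal_rate(sig),
                        meta = signal_meta(sig)) {
  new_breathing_signal(time_s, pos_mm, rate_hz, meta)
}

#' Read a breathing trace from CSV
#'
#' Expects a header line and two numeric columns, `time_s,pos_mm` (decimal
#' point, comma separator, UTF-8). A sidecar JSON file (same path with
#' `.json` appended) with fields such as `subject`, `site`, `device` is
#' merged into the metadata when present.
#'
#' @param path Path to the CSV file.
#' @return A `breathing_signal`; `meta$source` records the path.
#' @export
read_breathing_csv <- function(path) {
  if (!file.exists(path)) {
    bc_parse_error(sprintf("file not found: %s", path))
  }
  df <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    # readr reports the physical file line (header included)
    bc_parse_error(
      sprintf("malformed value in %s at line %d", path, probs$row[1]),
      line = as.integer(probs$row[1])
    )
  }
  if (!all(c("time_s", "pos_mm") %in% names(df))) {
    bc_parse_error(sprintf("%s must have columns time_s,pos_mm", path))
  }
  if (nrow(df) == 0) {
    bc_parse_error(sprintf("no data rows in %s", path))
  }
  if (anyNA(df$time_s) || anyNA(df$pos_mm)) {
    bad <- which(is.na(df$time_s) | is.na(df$pos_mm))[1]
    bc_parse_error(sprintf("missing value in %s at line %d", path, bad + 1L),
                   line = bad + 1L)
  }
  meta <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- c(meta, jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  breathing_signal(df$time_s, df$pos_mm, meta = meta)
}

#' Write a breathing trace to CSV
#'
#' @param sig A `breathing_signal`.
#' @param path Output path; header `time_s,pos_mm`.
#' @return `path`, invisibly.
#' @export
write_breathing_csv <- function(sig, path) {
  readr::write_csv(tibble::tibble(time_s = sig$time_s, pos_mm = sig$pos_mm),
                   path, progress = FALSE)
  invisible(path)
}
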