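# Plain-text readers/writers for the formats the CLI and pipelines exchange.

#' Read an RR-interval series from plain text
#'
#' Accepts either one interval in ms per line (Kubios-compatible), or a CSV
#' with header `time_s,rr_ms` and optionally `flag`.
#'
#' @param path File path.
#' @return An [rr_series()].
#' @export
read_rr <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    df <- utils::read.csv(path)
    if (!all(c("time_s", "rr_ms") %in% names(df)))
      stop("RR CSV must have columns time_s, rr_ms")
    flags <- if ("flag" %in% names(df)) df$flag else rep("ok", nrow(df))
    rr_series(df$rr_ms, df$time_s, flags)
  } else {
    rr_series(scan(path, quiet = TRUE))
  }
}

#' Write an RR-interval series as CSV
#'
#' Columns `time_s,rr_ms,flag`.
#'
#' @param rr An [rr_series()].
#' @param path Output path.
#' @export
write_rr <- function(rr, path) {
  utils::write.csv(data.frame(time_s = rr$times, rr_ms = rr$intervals,
                              flag = rr$quality_flags),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a uniformly sampled signal from CSV
#'
#' Two-column `time_s,voltage`-style CSV with header (the rate is inferred
#' from the time column), or a single column of samples with the rate given
#' explicitly.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz; required for single-column input.
#' @param type `"ecg"` or `"resp"`.
#' @return An [ecg_recording()] or [resp_recording()].
#' @export
read_signal <- function(path, rate = NULL, type = c("ecg", "resp")) {
  type <- match.arg(type)
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    df <- utils::read.csv(path)
    tcol <- df[[1]]; v <- df[[2]]
    rate <- 1 / stats::median(diff(tcol))
    t0 <- tcol[1]
  } else {
    if (is.null(rate)) stop("single-column signal input requires a rate")
    v <- scan(path, quiet = TRUE)
    t0 <- 0
  }
  if (type == "ecg") ecg_recording(v, rate, t0) else
    resp_recording(v, rate, t0)
}

#' Read segment windows from CSV
#'
#' Expects header `label,start_s,end_s`.
#'
#' @param path File path.
#' @return A [segment_windows()] data frame.
#' @export
read_windows <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("label", "start_s", "end_s") %in% names(df)))
    stop("windows CSV must have columns label, start_s, end_s")
  segment_windows(df$label, df$start_s, df$end_s)
}
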