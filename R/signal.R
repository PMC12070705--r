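#' Uniformly sampled physiological waveform
#'
#' Light container for a single-channel waveform: samples (arbitrary units),
#' sampling rate, channel kind, and optional subject/phase labels. All
#' conditioning and detection functions in the package consume and return
#' `pw_signal` objects.
#'
#' @param samples Numeric vector of finite sample values, length >= 2.
#' @param fs Sampling rate in Hz (positive).
#' @param kind Channel kind: `"PPG"`, `"PPG_d1"`, `"PPG_d2"`, or `"ECG"`.
#' @param subject,phase Optional character labels carried through the pipeline.
#' @return An object of class `pw_signal`.
#' @examples
#' s <- pw_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 100)), fs = 100)
#' s
#' @export
pw_signal <- function(samples, fs, kind = c("PPG", "PPG_d1", "PPG_d2", "ECG"),
                      subject = NA_character_, phase = NA_character_) {
  kind <- match.arg(kind)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_invalid("`fs` must be a single positive number (Hz)")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop_invalid("a signal needs at least 2 samples")
  if (any(!is.finite(samples))) stop_invalid("signal samples must be finite")
  structure(
    list(samples = samples, fs = fs, kind = kind,
         subject = as.character(subject), phase = as.character(phase)),
    class = "pw_signal"
  )
}

#' @export
print.pw_signal <- function(x, ...) {
  cat(sprintf("<pw_signal> %s: %d samples @ %g Hz (%.2f s)",
              x$kind, length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.na(x$subject)) cat(sprintf("  subject=%s", x$subject))
  if (!is.na(x$phase)) cat(sprintf("  phase=%s", x$phase))
  cat("\n")
  invisible(x)
}

#' @export
length.pw_signal <- function(x) length(x$samples)

# Replace samples, keeping metadata; optionally relabel the channel kind.
with_samples <- function(sig, samples, kind = sig$kind) {
  pw_signal(samples, fs = sig$fs, kind = kind,
            subject = sig$subject, phase = sig$phase)
}

#' Time axis of a signal
#'
#' @param sig A [pw_signal()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_time <- function(sig) {
  (seq_along(sig$samples) - 1) / sig$fs
}

#' First derivative of a signal by central differences
#'
#' Interior samples use `(y[i+1] - y[i-1]) / 2 * fs`; the two edge samples use
#' one-sided differences. The channel kind is advanced (`PPG` -> `PPG_d1` ->
#' `PPG_d2`); differentiating an ECG keeps the `ECG` kind.
#'
#' @param sig A [pw_signal()].
#' @return A [pw_signal()] of the derivative in a.u./s.
#' @export
signal_derivative <- function(sig) {
  y <- sig$samples
  n <- length(y)
  d <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) * sig$fs
  kind <- switch(sig$kind, PPG = "PPG_d1", PPG_d1 = "PPG_d2", sig$kind)
  with_samples(sig, d, kind = kind)
}

#' Write / read a signal as two-column delimited text
#'
#' The on-disk format is a header line `time_s,amplitude` followed by one row
#' per sample. `read_signal()` recovers the sampling rate from the median time
#' step.
#'
#' @param sig A [pw_signal()].
#' @param path File path.
#' @return `write_signal()` returns `path` invisibly; `read_signal()` a
#'   [pw_signal()].
#' @export
write_signal <- function(sig, path) {
  utils::write.csv(
    data.frame(time_s = signal_time(sig), amplitude = sig$samples),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_signal
#' @param kind Channel kind to assign on read.
#' @export
read_signal <- function(path, kind = "PPG") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    stop_schema("signal file must have columns time_s, amplitude")
  }
  dt <- stats::median(diff(df$time_s))
  pw_signal(df$amplitude, fs = 1 / dt, kind = kind)
}
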