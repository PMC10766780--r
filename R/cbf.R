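#' Bead-displacement trace
#'
#' Uniformly sampled displacement series, the input of ciliary-beat-frequency
#' estimation. Traces with gaps must be interpolated upstream; missing values
#' are rejected here.
#'
#' @param displacement numeric vector of displacements (pixels), >= 64
#'   samples.
#' @param fs sampling rate in frames per second.
#' @param bead_id trace identifier.
#' @return an object of class `bead_trace`.
#' @export
bead_trace <- function(displacement, fs, bead_id = "bead1") {
  displacement <- as.numeric(displacement)
  fs <- check_number(fs, "fs", min = 1e-9)
  if (length(displacement) < 64) {
    stop("a trace needs at least 64 samples", call. = FALSE)
  }
  if (anyNA(displacement)) {
    stop("trace has missing samples; interpolate gaps before analysis",
         call. = FALSE)
  }
  structure(list(displacement = displacement, fs = fs,
                 bead_id = check_string(bead_id, "bead_id")),
            class = "bead_trace")
}

#' @export
print.bead_trace <- function(x, ...) {
  cat(sprintf("bead_trace '%s': %d samples at %g frames/s (%.2f s)\n",
              x$bead_id, length(x$displacement), x$fs,
              length(x$displacement) / x$fs))
  invisible(x)
}

#' Read a bead trace from CSV
#'
#' Accepts two layouts: (`time_s`, `displacement_px`), from which the
#' sampling rate is inferred, or (`frame`, `displacement_px`) with `fs`
#' supplied explicitly.
#'
#' @param path CSV file.
#' @param fs sampling rate in frames/s, required for the `frame` layout.
#' @param bead_id identifier; default the file name without extension.
#' @return a [bead_trace()].
#' @export
read_trace <- function(path, fs = NULL, bead_id = NULL) {
  df <- utils::read.csv(path)
  if (is.null(bead_id)) bead_id <- sub("\\.[^.]*$", "", basename(path))
  if ("time_s" %in% names(df)) {
    dt <- diff(df$time_s)
    if (max(abs(dt - median(dt))) > 1e-6 * median(dt)) {
      stop("trace is not uniformly sampled", call. = FALSE)
    }
    fs <- 1 / median(dt)
  } else if (!"frame" %in% names(df)) {
    stop("CSV needs a 'time_s' or 'frame' column", call. = FALSE)
  } else if (is.null(fs)) {
    stop("'fs' is required when the trace is indexed by frame", call. = FALSE)
  }
  bead_trace(df$displacement_px, fs, bead_id)
}

#' Write a bead trace as CSV
#' @param trace a [bead_trace()].
#' @param path output CSV (`time_s`, `displacement_px`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  n <- length(trace$displacement)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$fs,
                   displacement_px = trace$displacement)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate ciliary beat frequency from one trace
#'
#' Detrends the displacement series, applies a taper, takes the magnitude
#' spectrum via the FFT, finds the dominant bin within a physiological band,
#' and refines the frequency by parabolic interpolation over the peak and its
#' two neighbors. The estimate never leaves the band (Nyquist safety), and
#' the spectral resolution `fs/N` is reported alongside.
#'
#' @param trace a [bead_trace()].
#' @param band c(low, high) Hz search band (default c(2, 40)).
#' @param detrend `"linear"` (default) removes an ordinary-least-squares line;
#'   `"mean"` removes the mean only.
#' @param window `"hann"` (default) or `"none"`.
#' @return an object of class `cbf_estimate`: `frequency` (Hz),
#'   `power_fraction` (peak-bin power / band power), `resolution` (Hz),
#'   `band`, `harmonic_flag` (`TRUE` when the 2x bin carries more than half
#'   the dominant power), `bead_id`.
#' @export
estimate_cbf <- function(trace, band = c(2, 40),
                         detrend = c("linear", "mean"),
                         window = c("hann", "none")) {
  stopifnot(inherits(trace, "bead_trace"))
  detrend <- match.arg(detrend)
  window <- match.arg(window)
  fs <- trace$fs
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("'band' must be c(low, high) with 0 < low < high", call. = FALSE)
  }
  if (band[2] >= fs / 2) {
    stop("'band' upper edge must be below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  x <- trace$displacement
  n <- length(x)
  x <- switch(detrend,
    mean = x - mean(x),
    linear = {
      t <- seq_len(n)
      stats::lm.fit(cbind(1, t), x)$residuals
    }
  )
  if (stats::var(x) < 1e-20) {
    stop("no signal: trace has zero variance after detrending", call. = FALSE)
  }
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]
  freqs <- (seq_along(spec) - 1) * fs / n
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0) {
    stop("band contains no frequency bin; lengthen the trace or widen the band",
         call. = FALSE)
  }
  k <- in_band[which.max(spec[in_band])]
  # parabolic refinement on the magnitude spectrum
  delta <- 0
  if (k > 1 && k < length(spec)) {
    a <- spec[k - 1]; b <- spec[k]; cc <- spec[k + 1]
    den <- a - 2 * b + cc
    if (abs(den) > .Machine$double.eps) {
      delta <- max(-0.5, min(0.5, 0.5 * (a - cc) / den))
    }
  }
  freq <- min(max((k - 1 + delta) * fs / n, band[1]), band[2])
  band_power <- sum(spec[in_band]^2)
  # harmonic note: does the 2x bin carry more than half the dominant power?
  k2 <- which.min(abs(freqs - 2 * freq))
  harmonic <- freqs[k2] <= band[2] && spec[k2]^2 > 0.5 * spec[k]^2 && k2 != k
  structure(
    list(frequency = freq, power_fraction = spec[k]^2 / band_power,
         resolution = fs / n, band = band, harmonic_flag = harmonic,
         bead_id = trace$bead_id),
    class = "cbf_estimate"
  )
}

#' @export
print.cbf_estimate <- function(x, ...) {
  cat(sprintf(
    "cbf_estimate '%s': %.2f Hz (resolution %.3f Hz, %.0f%% of band power)%s\n",
    x$bead_id, x$frequency, x$resolution, 100 * x$power_fraction,
    if (x$harmonic_flag) " [harmonic noted]" else ""))
  invisible(x)
}

#' Estimate CBF for a batch of traces
#'
#' Runs [estimate_cbf()] per trace; traces that fail (e.g., no signal) are
#' listed separately and excluded from the summary.
#'
#' @param traces list of [bead_trace()] objects.
#' @param ... passed to [estimate_cbf()].
#' @return list with `estimates` (data.frame: `bead_id`, `frequency_hz`,
#'   `power_fraction`, `resolution_hz`), `failures` (data.frame: `bead_id`,
#'   `error`), and `summary` (`n`, `mean_hz`, `sd_hz`; SD is `NA` for a
#'   single success).
#' @export
batch_cbf <- function(traces, ...) {
  if (length(traces) == 0) stop("no traces supplied", call. = FALSE)
  res <- lapply(traces, function(tr) {
    tryCatch(list(ok = TRUE, est = estimate_cbf(tr, ...)),
             error = function(e) list(ok = FALSE, bead_id = tr$bead_id,
                                      error = conditionMessage(e)))
  })
  ok <- vapply(res, `[[`, TRUE, "ok")
  if (!any(ok)) stop("all traces failed CBF estimation", call. = FALSE)
  est <- do.call(rbind, lapply(res[ok], function(r) {
    data.frame(bead_id = r$est$bead_id, frequency_hz = r$est$frequency,
               power_fraction = r$est$power_fraction,
               resolution_hz = r$est$resolution, stringsAsFactors = FALSE)
  }))
  rownames(est) <- NULL
  failures <- if (any(!ok)) {
    do.call(rbind, lapply(res[!ok], function(r) {
      data.frame(bead_id = r$bead_id, error = r$error, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(bead_id = character(0), error = character(0))
  }
  list(
    estimates = est, failures = failures,
    summary = list(n = nrow(est), mean_hz = mean(est$frequency_hz),
                   sd_hz = if (nrow(est) > 1) sd(est$frequency_hz) else NA_real_)
  )
}
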