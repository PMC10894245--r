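#' Epoch a multichannel series into 2200 ms segments
#'
#' Cuts a continuous recording into consecutive non-overlapping 2200 ms
#' epochs (the trailing partial segment is discarded) and tags each epoch
#' with its recording condition. An epoch straddling a condition boundary is
#' assigned to the earlier condition when at least half of its samples
#' precede the boundary (equivalently, when its midpoint does not pass the
#' boundary).
#'
#' @param series Numeric matrix, samples x channels (a vector is treated as
#'   one channel).
#' @param rate Sampling rate (Hz); `rate * 2.2` must be within one sample of
#'   an integer.
#' @param boundaries Times (seconds) at which the condition changes;
#'   `length(conditions)` must equal `length(boundaries) + 1`.
#' @param conditions Condition labels, by default the study's
#'   pre/bolus/infusion blocks truncated to the number of segments present.
#' @return An object of class `epoched_series`: list with `data` (array
#'   epochs x channels x samples), `rate`, and tibble `epochs`
#'   (epoch, start_s, condition).
#' @export
epoch_series <- function(series, rate, boundaries = NULL,
                         conditions = c("pre", "bolus", "infusion")) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  n_len <- rate * 2.2
  if (abs(n_len - round(n_len)) > 1) {
    stop("sampling rate incompatible with 2200 ms epochs", call. = FALSE)
  }
  n_len <- round(n_len)
  n_total <- nrow(series)
  if (n_total < n_len) stop("series shorter than one 2200 ms epoch", call. = FALSE)
  n_ep <- floor(n_total / n_len)
  conditions <- conditions[seq_len(length(boundaries) + 1)]
  dat <- array(NA_real_, c(n_ep, ncol(series), n_len))
  start_s <- (seq_len(n_ep) - 1) * n_len / rate
  for (e in seq_len(n_ep)) {
    dat[e, , ] <- t(series[((e - 1) * n_len + 1):(e * n_len), , drop = FALSE])
  }
  mid <- start_s + 1.1
  # strict inequality with a tolerance: a boundary exactly at the midpoint
  # leaves the epoch in the earlier condition (half its samples precede)
  cond_idx <- vapply(mid, function(t) sum(boundaries < t - 1e-9),
                     integer(1)) + 1L
  structure(list(
    data = dat, rate = rate,
    epochs = tibble::tibble(epoch = seq_len(n_ep), start_s = start_s,
                            condition = conditions[cond_idx])
  ), class = "epoched_series")
}

#' @export
print.epoched_series <- function(x, ...) {
  cat("<epoched_series> ", dim(x$data)[1], " epochs x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples @ ", x$rate, " Hz\n", sep = "")
  print(table(x$epochs$condition))
  invisible(x)
}

# one-sided Hann-tapered cross-periodogram of one epoch pair (complex)
cross_periodogram <- function(x, y, rate) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  U <- mean(w^2)
  X <- stats::fft(w * (x - mean(x)))
  Y <- stats::fft(w * (y - mean(y)))
  j <- 2:(floor(n / 2))          # drop DC and Nyquist
  f <- (j - 1) * rate / n
  # one-sided density per Hz: 2 dt / (n U) X conj(Y)
  list(f = f, p = 2 * (1 / rate) / (n * U) * X[j] * Conj(Y[j]))
}

#' Welch cross-spectral density of an epoched recording
#'
#' Per-epoch Hann-tapered cross-periodograms (one per 2200 ms segment, no
#' overlap), averaged over epochs and linearly interpolated onto the
#' requested frequency grid. Returns a one-sided density: integrating an
#' auto-spectrum over frequency recovers the signal variance.
#'
#' @param x An `epoched_series` (or a samples x channels matrix together
#'   with `rate`, which is epoched on the fly).
#' @param channels Pair of channel indices forming the two virtual
#'   electrodes.
#' @param grid Output frequency grid (Hz).
#' @param rate Sampling rate, only when `x` is a plain matrix.
#' @param condition Optional: restrict to epochs of this condition; also
#'   stored in the result.
#' @param subject Metadata passed through.
#' @return A [spectral_data()] object.
#' @export
welch_csd <- function(x, channels = c(1, 2), grid = 4:90, rate = NULL,
                      condition = NA, subject = NA) {
  if (!inherits(x, "epoched_series")) {
    x <- epoch_series(x, rate)
  }
  keep <- if (is.na(condition)) x$epochs$epoch else
    x$epochs$epoch[x$epochs$condition == condition]
  if (length(keep) < 8) stop("need at least 8 epochs for a Welch estimate",
                             call. = FALSE)
  acc <- NULL
  for (e in keep) {
    a <- x$data[e, channels[1], ]
    b <- x$data[e, channels[2], ]
    p11 <- cross_periodogram(a, a, x$rate)
    p12 <- cross_periodogram(a, b, x$rate)
    p22 <- cross_periodogram(b, b, x$rate)
    m <- cbind(p11$p, p12$p, p22$p)
    acc <- if (is.null(acc)) m else acc + m
    f <- p11$f
  }
  acc <- acc / length(keep)
  interp <- function(v) stats::approx(f, v, xout = grid, rule = 2)$y
  s11 <- interp(Re(acc[, 1])); s22 <- interp(Re(acc[, 3]))
  s12 <- complex(real = interp(Re(acc[, 2])), imaginary = interp(Im(acc[, 2])))
  csd <- array(NA_complex_, c(2, 2, length(grid)))
  csd[1, 1, ] <- pmax(s11, 0); csd[2, 2, ] <- pmax(s22, 0)
  csd[1, 2, ] <- s12; csd[2, 1, ] <- Conj(s12)
  spectral_data(grid, csd, subject = subject, condition = condition)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and an effective
#' eighth-order magnitude response.
#'
#' @param series Numeric vector (one channel).
#' @param band Either a band name from [band_table()] or `c(lo, hi)` in Hz.
#' @param rate Sampling rate (Hz); the upper band edge must be below
#'   Nyquist.
#' @return Filtered series, same length.
#' @export
band_filter <- function(series, band, rate) {
  if (is.character(band)) {
    bt <- band_table()
    row <- bt[bt$band == band, ]
    if (!nrow(row)) stop("unknown band name: ", band, call. = FALSE)
    band <- c(row$lo, row$hi)
  }
  if (band[2] >= rate / 2) stop("band edge at or above Nyquist", call. = FALSE)
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, series))
}

#' Mean Hilbert amplitude envelope
#'
#' Modulus of the analytic signal (FFT construction), with 10% of samples
#' trimmed from each end before averaging to discard filter edge effects.
#'
#' @param series Numeric vector, at least 256 samples, finite.
#' @return Mean oscillatory amplitude (scalar).
#' @export
hilbert_envelope_mean <- function(series) {
  n <- length(series)
  if (n < 256) stop("series too short for a stable envelope (need >= 256 samples)",
                    call. = FALSE)
  if (any(!is.finite(series))) stop("non-finite values in series", call. = FALSE)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(stats::fft(series) * h, inverse = TRUE) / n
  env <- Mod(analytic)
  trim <- max(1, floor(0.1 * n))
  mean(env[(trim + 1):(n - trim)])
}

#' Read a multichannel series from delimited text
#'
#' Expects one column per channel (header optional, any of tab, comma or
#' whitespace separation) and returns a samples x channels numeric matrix.
#'
#' @param path File path.
#' @param header Does the first line name the channels?
#' @return Numeric matrix, samples x channels.
#' @export
read_series_text <- function(path, header = TRUE) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep)
  as.matrix(df)
}
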