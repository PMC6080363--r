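#' One-sided FFT magnitude spectrum
#'
#' Modulus of the discrete Fourier transform over the one-sided bins
#' `0..floor(N/2)` with the per-bin frequency axis `k * fs / N`. The modulus
#' of a real signal is symmetric, so the one-sided half carries the full
#' information used by the cutoff search.
#'
#' @param signal An [audio_signal] with at least 2 samples.
#' @return A list of class `spectral_envelope` with `fft_modulus`, `freq_hz`,
#'   `fs`, and (after [moving_average_envelope()]) the normalized envelope
#'   `env`.
#' @export
fft_modulus <- function(signal) {
  signal <- as_audio_signal(signal)
  n <- length(signal$samples)
  if (n < 2) stop("signal must have at least 2 samples", call. = FALSE)
  mod_full <- Mod(stats::fft(signal$samples))
  k <- 0:(n %/% 2)
  structure(list(fft_modulus = mod_full[k + 1L],
                 freq_hz = k * signal$fs / n,
                 env = NULL, l_f = NULL, fs = signal$fs),
            class = "spectral_envelope")
}

#' Moving-average envelope of a spectrum
#'
#' Smooths a nonnegative sequence with a centered moving average of
#' neighborhood radius `l_f`; at both edges the window is truncated to the
#' valid indices and the divisor is the number of terms actually summed
#' (`l_f + n + 1` at the head, `l_f + N - n` at the tail, `2 l_f + 1` in the
#' interior, with n the 0-based position). Too large a radius merges adjacent
#' spectral peaks, so the default is small.
#'
#' @param x Nonnegative numeric sequence (typically an FFT modulus), or a
#'   `spectral_envelope` from [fft_modulus()].
#' @param l_f Neighborhood radius in bins (default 5); must satisfy
#'   `l_f < length(x)`.
#' @param normalize Normalize the smoothed sequence to unit peak (default
#'   TRUE, producing the "FFT envelope" the cutoff search operates on).
#' @return Same type as `x`: a numeric vector, or the `spectral_envelope`
#'   with its `env` field populated.
#' @export
moving_average_envelope <- function(x, l_f = 5L, normalize = TRUE) {
  if (inherits(x, "spectral_envelope")) {
    x$env <- moving_average_envelope(x$fft_modulus, l_f, normalize)
    x$l_f <- l_f
    return(x)
  }
  n <- length(x)
  if (l_f < 1) stop("l_f must be >= 1", call. = FALSE)
  if (l_f >= n) stop("l_f must be smaller than the sequence length", call. = FALSE)
  cs <- c(0, cumsum(x))
  pos <- seq_len(n)                       # 1-based
  lo <- pmax(pos - l_f, 1L)
  hi <- pmin(pos + l_f, n)
  env <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (normalize) env <- unit_peak(env, "envelope")
  env
}

#' Automatic low-pass cutoff search
#'
#' Finds the primary peak of the FFT envelope (its global maximum — heart
#' sound component energy concentrates there) and then the first valley (a
#' local minimum between adjacent spikes) after it, within the search band,
#' whose envelope value is below `coeff_threshold`. That valley marks the
#' ending point of the primary peak and becomes the low-pass cutoff; if no
#' such valley exists the cutoff falls back to `search_hi`. Plateaus of equal
#' values collapse to their first bin. If the global maximum lies above
#' `search_hi` (not a plausible heart-sound spectrum) the peak search is
#' restricted to `[0, search_hi]` with a warning.
#'
#' @param env A `spectral_envelope` with its `env` field populated (see
#'   [moving_average_envelope()]), normalized to unit peak.
#' @param coeff_threshold Valley acceptance threshold on the normalized
#'   envelope (default 0.2).
#' @param search_lo,search_hi Search band in Hz (defaults 20 and 200).
#' @return A list of class `cutoff_result`: `cutoff_hz`, `primary_peak_hz`,
#'   `found_valley`.
#' @export
find_cutoff_frequency <- function(env, coeff_threshold = 0.2,
                                  search_lo = 20, search_hi = 200) {
  stopifnot(inherits(env, "spectral_envelope"), !is.null(env$env))
  e <- env$env
  f <- env$freq_hz
  if (length(e) < 3) stop("envelope must have at least 3 bins", call. = FALSE)
  peak_idx <- which.max(e)
  if (f[peak_idx] > search_hi) {
    warning("FFT envelope global maximum above ", search_hi,
            " Hz; restricting primary-peak search", call. = FALSE)
    sub <- which(f <= search_hi)
    peak_idx <- sub[which.max(e[sub])]
  }
  # local minima with plateau collapse: compare consecutive runs of equal value
  r <- rle(e)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  valley_idx <- integer(0)
  if (nr >= 3) {
    is_min <- c(FALSE, r$values[2:(nr - 1)] < r$values[1:(nr - 2)] &
                       r$values[2:(nr - 1)] < r$values[3:nr], FALSE)
    valley_idx <- starts[is_min]
  }
  cand <- valley_idx[valley_idx > peak_idx &
                     f[valley_idx] >= search_lo & f[valley_idx] <= search_hi &
                     e[valley_idx] < coeff_threshold]
  if (length(cand)) {
    res <- list(cutoff_hz = f[cand[1L]], primary_peak_hz = f[peak_idx],
                found_valley = TRUE)
  } else {
    res <- list(cutoff_hz = search_hi, primary_peak_hz = f[peak_idx],
                found_valley = FALSE)
  }
  structure(res, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> cutoff %.1f Hz (primary peak %.1f Hz, valley %s)\n",
              x$cutoff_hz, x$primary_peak_hz,
              if (x$found_valley) "found" else "not found - fallback"))
  invisible(x)
}

#' Apply the automatic low-pass filter
#'
#' Order-6 Butterworth low-pass applied forward-backward (zero phase, so
#' component onsets stay time-aligned for boundary detection), followed by
#' unit-peak normalization.
#'
#' @param signal An [audio_signal].
#' @param cutoff A `cutoff_result` from [find_cutoff_frequency()], or a
#'   cutoff frequency in Hz; must be below the Nyquist frequency.
#' @return The filtered, unit-peak [audio_signal].
#' @export
apply_alpf <- function(signal, cutoff) {
  signal <- as_audio_signal(signal)
  fc <- if (inherits(cutoff, "cutoff_result")) cutoff$cutoff_hz else cutoff
  if (!is.finite(fc) || fc <= 0 || fc >= signal$fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  bf <- signal::butter(6, fc / (signal$fs / 2), type = "low")
  y <- signal::filtfilt(bf, signal$samples)
  audio_signal(unit_peak(y), signal$fs)
}

#' Murmur elimination (ALPF stage)
#'
#' Full automatic-cutoff low-pass filtering: one-sided FFT modulus, moving
#' average envelope, cutoff search in the 20-200 Hz band, zero-phase low-pass
#' filtering and renormalization. Murmurs are band-limited noise above the
#' heart-sound component band; cutting at the primary peak's ending valley
#' removes them while preserving the component shapes.
#'
#' @param signal The preprocessed, unit-peak [audio_signal] (see
#'   [preprocess()]).
#' @param l_f Moving-average neighborhood radius in bins (default 5).
#' @param coeff_threshold Valley acceptance threshold (default 0.2).
#' @param search_lo,search_hi Cutoff search band in Hz (defaults 20, 200).
#' @return A list with `signal` (the murmur-reduced [audio_signal]) and
#'   `cutoff` (the `cutoff_result`).
#' @export
eliminate_murmurs <- function(signal, l_f = 5L, coeff_threshold = 0.2,
                              search_lo = 20, search_hi = 200) {
  signal <- as_audio_signal(signal)
  spec <- moving_average_envelope(fft_modulus(signal), l_f)
  cut <- find_cutoff_frequency(spec, coeff_threshold, search_lo, search_hi)
  list(signal = apply_alpf(signal, cut), cutoff = cut)
}
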