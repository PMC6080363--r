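#' Preprocessing parameters
#'
#' Controls the standardization of a raw recording before murmur elimination:
#' down-sampling to 2 kHz (heart-sound energy lies below 1 kHz, so 2 kHz
#' satisfies the sampling theorem), db4 wavelet denoising with soft
#' thresholding at decomposition level 7, and unit-peak normalization.
#'
#' @param target_fs Target sampling rate in Hz (default 2000).
#' @param wavelet Mother wavelet for denoising (only `"db4"` is built in; its
#'   shape resembles the heart-sound transients).
#' @param level Wavelet decomposition depth (default 7). Capped automatically
#'   for short signals inside [preprocess()], strict in [denoise()].
#' @param denoise Logical; set `FALSE` to skip the denoising stage.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(target_fs = 2000, wavelet = "db4", level = 7,
                              denoise = TRUE) {
  stopifnot(target_fs >= 2000, level >= 1)
  structure(list(target_fs = target_fs, wavelet = wavelet, level = level,
                 denoise = denoise),
            class = "preprocess_params")
}

#' Down-sample a recording
#'
#' Anti-alias filters with a zero-phase Butterworth low-pass (two cascaded
#' 4th-order forward-backward passes at 0.9 x the target Nyquist frequency),
#' then evaluates the filtered waveform on the target sampling grid by cubic
#' spline interpolation. Zero-phase filtering keeps onsets time-aligned.
#'
#' @param signal An [audio_signal].
#' @param target_fs Target rate in Hz; must not exceed `signal$fs`.
#' @return An [audio_signal] at `target_fs` with the same duration to within
#'   one sample.
#' @export
downsample <- function(signal, target_fs = 2000) {
  signal <- as_audio_signal(signal)
  if (signal$fs < target_fs)
    stop("cannot upsample: input rate ", signal$fs, " Hz is below target ",
         target_fs, " Hz", call. = FALSE)
  if (signal$fs == target_fs) return(signal)
  x <- signal$samples
  wc <- 0.9 * target_fs / signal$fs  # normalized to input Nyquist
  bf <- signal::butter(4, wc, type = "low")
  x <- signal::filtfilt(bf, x)
  x <- signal::filtfilt(bf, x)
  n_out <- round(length(x) * target_fs / signal$fs)
  t_out <- (seq_len(n_out) - 1) / target_fs
  t_in <- (seq_along(x) - 1) / signal$fs
  y <- stats::spline(t_in, x, xout = pmin(t_out, max(t_in)))$y
  audio_signal(y, target_fs)
}

#' Wavelet denoising with soft thresholding
#'
#' db4 decomposition (symmetric extension) to `params$level`; detail
#' coefficients at every level are soft-thresholded with the universal
#' threshold `sigma * sqrt(2 log N)` where `sigma` is estimated from the
#' median absolute deviation of the finest-scale details
#' (`median(|d1|) / 0.6745`); approximation coefficients are left untouched.
#' A zero signal passes through unchanged.
#'
#' @param signal An [audio_signal].
#' @param params A [preprocess_params()] list.
#' @return An [audio_signal] of the same length and rate.
#' @export
denoise <- function(signal, params = preprocess_params()) {
  signal <- as_audio_signal(signal)
  x <- signal$samples
  if (max(abs(x)) == 0) return(signal)
  dec <- wave_decompose(x, params$level, params$wavelet)
  sigma <- stats::median(abs(dec$cd[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$cd <- lapply(dec$cd, soft_threshold, thr = thr)
  audio_signal(wave_reconstruct(dec), signal$fs)
}

#' Unit-peak normalization
#'
#' Divides the waveform by its maximum absolute value so that
#' `max(abs(samples)) == 1`; sign and shape are preserved. An all-zero input
#' is an error.
#'
#' @param signal An [audio_signal].
#' @return A normalized [audio_signal].
#' @export
normalize_unit_peak <- function(signal) {
  signal <- as_audio_signal(signal)
  audio_signal(unit_peak(signal$samples), signal$fs)
}

#' Full preprocessing stage
#'
#' Down-sample to `params$target_fs`, wavelet-denoise, and normalize to unit
#' peak. For signals too short for the requested decomposition depth the
#' level is reduced to the deepest feasible one.
#'
#' @param signal An [audio_signal].
#' @param params A [preprocess_params()] list.
#' @return The standardized [audio_signal] (the "original signal" that all
#'   later stages refer to).
#' @export
preprocess <- function(signal, params = preprocess_params()) {
  signal <- as_audio_signal(signal)
  out <- downsample(signal, params$target_fs)
  if (isTRUE(params$denoise)) {
    f <- wave_filters(params$wavelet)
    feasible <- floor(log2(length(out$samples) / (f$L - 1)))
    lv <- min(params$level, max(1L, feasible))
    if (feasible >= 1L) {
      p <- params; p$level <- lv
      out <- denoise(out, p)
    }
  }
  normalize_unit_peak(out)
}
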