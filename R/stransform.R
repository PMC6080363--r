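#' Stockwell (S-) transform
#'
#' Time-frequency representation with frequency-dependent Gaussian windows.
#' Row `n >= 1` is computed from the signal's DFT `H` as
#' `S[n, j] = sum_m H[(m + n) mod N] * exp(-2 pi^2 m^2 / n^2) *
#' exp(2 pi i m j / N)` (one inverse FFT per frequency row); the
#' zero-frequency row is the signal mean. The per-row frequency axis is
#' reported as `F(m) = m * fs / (2 N)`: only the frequency *ordering* is used
#' downstream, which is invariant to the axis scale. Rows are computed up to
#' `max_freq_hz` on that axis (identical to the corresponding rows of the
#' full transform).
#'
#' @param signal An [audio_signal] (or numeric vector with `fs`) of length
#'   >= 4.
#' @param max_freq_hz Highest row frequency to compute, on the reported axis
#'   (default: Nyquist of that axis, i.e. all rows).
#' @param fs Sampling rate when `signal` is a plain vector.
#' @return A list of class `stransform`: complex matrix `S` (rows =
#'   frequencies, columns = time samples), modulus `mod`, `freq_hz`, `fs`.
#' @export
stockwell_transform <- function(signal, max_freq_hz = NULL, fs = NULL) {
  signal <- as_audio_signal(signal, fs)
  h <- signal$samples
  n_len <- length(h)
  if (n_len < 4) stop("signal must have at least 4 samples", call. = FALSE)
  # reported axis F(m) = m*fs/(2N); row m_max at max_freq_hz
  m_max <- if (is.null(max_freq_hz)) n_len - 1L
           else min(n_len - 1L, floor(max_freq_hz * 2 * n_len / signal$fs))
  H <- stats::fft(h)
  S <- matrix(0 + 0i, nrow = m_max + 1L, ncol = n_len)
  S[1L, ] <- mean(h)
  m <- 0:(n_len - 1L)
  for (vn in seq_len(m_max)) {
    shifted <- H[((m + vn) %% n_len) + 1L]
    gauss <- exp(-2 * pi^2 * m^2 / vn^2)
    S[vn + 1L, ] <- stats::fft(shifted * gauss, inverse = TRUE) / n_len
  }
  structure(list(S = S, mod = Mod(S),
                 freq_hz = (0:m_max) * signal$fs / (2 * n_len),
                 fs = signal$fs),
            class = "stransform")
}

#' Instantaneous frequency from an S-transform
#'
#' Per time sample, the amplitude-weighted mean row frequency of the
#' S-transform modulus: `f_H(j) = sum_m F(m) |S|[m, j] / sum_m |S|[m, j]`.
#' Columns with zero total mass get `f_H = 0` and are flagged.
#'
#' @param tf An `stransform` from [stockwell_transform()].
#' @return A list of class `instantaneous_frequency` with `f_hz` (per-sample
#'   frequency) and `undefined` (logical flags for zero-mass columns).
#' @export
instantaneous_frequency <- function(tf) {
  stopifnot(inherits(tf, "stransform"))
  mass <- colSums(tf$mod)
  num <- colSums(tf$mod * tf$freq_hz)
  undefined <- mass == 0
  f <- ifelse(undefined, 0, num / ifelse(mass == 0, 1, mass))
  structure(list(f_hz = f, undefined = undefined,
                 freq_range = range(tf$freq_hz)),
            class = "instantaneous_frequency")
}

#' Average instantaneous frequency per detected component
#'
#' For each boundary pair, evaluates the S-transform on a snippet of the
#' signal around the component (the span padded by `pad_s` on each side, so
#' the frequency-dependent Gaussian windows of the retained rows are
#' essentially fully supported over the span) and averages the instantaneous
#' frequency over the component span. The low-frequency gallop sounds S3/S4
#' score clearly below S1/S2 on this measure, which is what the classifier
#' relies on.
#'
#' @param signal The preprocessed [audio_signal] (identification runs on the
#'   original normalized sound, not the murmur-filtered one, to keep full
#'   time-frequency information).
#' @param bs A [boundary_set()] of detected components.
#' @param max_freq_hz Highest retained row frequency on the reported axis
#'   (default 300 Hz; all heart-sound component energy lies below it).
#' @param pad_s Snippet padding in seconds (default 0.1).
#' @return Numeric vector of per-component average frequencies (Hz, reported
#'   axis), length `bs$m`.
#' @export
component_avg_frequencies <- function(signal, bs, max_freq_hz = 300,
                                      pad_s = 0.1) {
  signal <- as_audio_signal(signal)
  if (bs$m == 0L) return(numeric(0))
  n_len <- length(signal$samples)
  pad <- round(pad_s * signal$fs)
  vapply(seq_len(bs$m), function(k) {
    a <- bs$onset[k] + 1L      # 1-based span
    b <- bs$offset[k] + 1L
    lo <- max(1L, a - pad)
    hi <- min(n_len, b + pad)
    snip <- signal$samples[lo:hi]
    if (all(snip == 0)) return(0)
    tf <- stockwell_transform(snip, max_freq_hz = max_freq_hz, fs = signal$fs)
    fh <- instantaneous_frequency(tf)
    cols <- (a - lo + 1L):(b - lo + 1L)
    mean(fh$f_hz[cols])
  }, numeric(1))
}
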