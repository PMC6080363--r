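#' Sample autocorrelation (biased and unbiased)
#'
#' `pacf_seq()` is the biased ("partial") autocorrelation with divisor `N` at
#' every lag, whose primary peaks attenuate with lag; `uacf_seq()` is the
#' unbiased form with divisor `N - m`, which averages only the terms actually
#' summed and therefore keeps the primary peaks of a quasi-periodic envelope
#' at full height. Both are computed over lags `m = 0..N-1` (at the last lag
#' the unbiased sum has a single term and divisor 1). They satisfy
#' `pacf_seq(x)[m] == uacf_seq(x)[m] * (N - m) / N` identically.
#'
#' @param x Numeric vector of length >= 2.
#' @return Numeric vector of length `length(x)` over lags `0..N-1`.
#' @export
uacf_seq <- function(x) {
  r <- raw_acf(x)
  n <- length(x)
  r / (n - 0:(n - 1L))
}

#' @rdname uacf_seq
#' @export
pacf_seq <- function(x) {
  raw_acf(x) / length(x)
}

# Raw lagged product sums sum_n x(n) x(n+m), m = 0..N-1, via FFT (O(N log N)).
raw_acf <- function(x) {
  n <- length(x)
  if (n < 2) stop("input must have at least 2 samples", call. = FALSE)
  fx <- stats::fft(c(x, numeric(n)))
  s <- Re(stats::fft(Mod(fx)^2, inverse = TRUE)) / (2 * n)
  s[seq_len(n)]
}

#' Side-peak suppression on the autocorrelation
#'
#' Squares the unbiased autocorrelation (expanding the amplitude gap between
#' primary and side peaks) and zeroes values below
#' `sigma_frac * max` of the squared sequence.
#'
#' @param r Unbiased autocorrelation sequence (from [uacf_seq()]).
#' @param sigma_frac Threshold fraction of the maximum squared value
#'   (default 0.4).
#' @return The thresholded energy sequence.
#' @export
suppress_side_peaks <- function(r, sigma_frac = 0.4) {
  e <- r^2
  sigma <- sigma_frac * max(e)
  ifelse(e < sigma, 0, e)
}

#' Forcible removal of the last peak
#'
#' The last peak of the thresholded autocorrelation energy is typically a
#' surviving side peak (generated by S1 x S2 products near the maximum lag),
#' so its last contiguous nonzero run is zeroed regardless of whether it is a
#' side or primary peak. If only a single nonzero run exists, removing it
#' would destroy the sequence: the run is kept and a warning is raised.
#'
#' @param e Thresholded energy sequence (from [suppress_side_peaks()]).
#' @return The sequence with its last nonzero run zeroed.
#' @export
remove_last_peak <- function(e) {
  runs <- true_runs(e != 0)
  if (!nrow(runs)) stop("all-zero input: no peak to remove", call. = FALSE)
  if (nrow(runs) == 1L) {
    warning("only one peak present; keeping it instead of removing",
            call. = FALSE)
    return(e)
  }
  last <- runs[nrow(runs), ]
  e[last["start"]:last["end"]] <- 0
  e
}

#' Cardiac-cycle failure condition
#'
#' Signalled (class `pcg_cycle_error`) when no non-origin peak survives the
#' final thresholding, e.g. for aperiodic envelopes or recordings shorter
#' than two cycles. [segment_recording()] catches it and labels components
#' "unknown" instead of guessing.
#' @noRd
cycle_failure <- function(msg) {
  stop(structure(class = c("pcg_cycle_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Average cardiac cycle estimation
#'
#' Pipeline on the final boundary-detection envelope: unbiased
#' autocorrelation, squaring with side-peak suppression, forcible removal of
#' the last peak, a second unbiased autocorrelation (`R_Final`), thresholding
#' at `final_frac * max(R_Final)`, and averaging the lags between adjacent
#' surviving peaks. A "peak" of a thresholded sequence is a maximal
#' contiguous nonzero run represented by its argmax lag; the run containing
#' lag 0 is always excluded. With a single surviving non-origin peak its lag
#' is taken as the cycle directly.
#'
#' @param env Numeric energy-filtered envelope (see [detect_boundaries()]),
#'   covering at least two heartbeats.
#' @param fs Sampling rate in Hz.
#' @param sigma_frac Side-peak suppression fraction (default 0.4).
#' @param final_frac Final threshold fraction of `max(R_Final)`
#'   (default 0.5).
#' @return A list of class `cycle_estimate`: `avg_cycle_samples`,
#'   `avg_cycle_s`, `peak_lags` (0-based), `n_intervals`.
#' @export
estimate_cycle <- function(env, fs, sigma_frac = 0.4, final_frac = 0.5) {
  if (max(env) == 0) cycle_failure("empty envelope: no components detected")
  r1 <- uacf_seq(env)
  e <- suppress_side_peaks(r1, sigma_frac)
  e <- withCallingHandlers(
    remove_last_peak(e),
    warning = function(w) invokeRestart("muffleWarning"))
  if (max(e) == 0) cycle_failure("no peak structure after side-peak removal")
  r_final <- uacf_seq(e)
  thr <- final_frac * max(r_final)
  kept <- ifelse(r_final < thr, 0, r_final)
  runs <- true_runs(kept != 0)
  if (!nrow(runs)) cycle_failure("no peaks survive the final threshold")
  lag0 <- 0:(length(kept) - 1L)
  peak_lags <- integer(0)
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, "start"]:runs[i, "end"]
    if (1L %in% seg) next                 # run containing lag 0
    peak_lags <- c(peak_lags, lag0[seg[which.max(kept[seg])]])
  }
  if (!length(peak_lags))
    cycle_failure("no non-origin peak: cardiac cycle could not be estimated")
  avg <- if (length(peak_lags) == 1L) as.numeric(peak_lags)
         else mean(diff(peak_lags))
  structure(list(avg_cycle_samples = avg, avg_cycle_s = avg / fs,
                 peak_lags = peak_lags, n_intervals = max(1L, length(peak_lags) - 1L)),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  cat(sprintf("<cycle_estimate> %.1f samples (%.3f s) from %d interval(s)\n",
              x$avg_cycle_samples, x$avg_cycle_s, x$n_intervals))
  invisible(x)
}
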