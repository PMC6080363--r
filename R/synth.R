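#' Gaussian-windowed transient heart-sound component
#'
#' Models a heart-sound transient as a sinusoid under a Gaussian window
#' spanning the requested duration. The window standard deviation is
#' duration/6, so the span edges sit at 3 sigma where the window has decayed
#' to about 1.1% of peak — i.e. the -40 dB points that define the
#' ground-truth boundaries coincide with the nominal span. Deterministic:
#' identical parameters always produce identical output.
#'
#' @param center_freq_hz Oscillation frequency in Hz.
#' @param duration_s Duration in seconds (`duration_s * fs >= 8` samples).
#' @param amplitude Peak absolute amplitude.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
make_component <- function(center_freq_hz, duration_s, amplitude, fs = 2000) {
  n <- round(duration_s * fs)
  if (n < 8) stop("component duration too short (needs >= 8 samples)", call. = FALSE)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  sd_t <- duration_s / 6
  w <- exp(-t^2 / (2 * sd_t^2))
  x <- sin(2 * pi * center_freq_hz * t) * w
  if (amplitude == 0) return(numeric(n))
  x * amplitude / max(abs(x))
}

#' Synthetic phonocardiogram configuration
#'
#' Describes a quasi-periodic train of heartbeats: per-beat transient
#' components, an optional band-limited murmur confined to a window of the
#' cycle, optional per-beat click artifacts, additive white noise, and
#' per-beat timing jitter. Component timing defaults across presets place S1
#' at the start of the cycle, S2 at 0.30 s, S3 shortly after S2's offset and
#' S4 shortly before the next S1, consistent with the physiological interval
#' ordering (the S1-S2 gap is shorter than S2-S1; S2-S3 shorter than S3-S1;
#' S2-S4 longer than S4-S1) and with inter-component gaps of at least 100 ms.
#'
#' @param components List of component specs, each a list with `label`,
#'   `center_freq_hz`, `duration_s`, `amplitude`, `offset_in_cycle_s`
#'   (component onset relative to the beat start); spans must not overlap.
#' @param murmur `NULL`, or a list with `band_lo_hz`, `band_hi_hz`,
#'   `window_s` (length-2 onset/offset within the cycle), `amplitude`.
#' @param click `NULL`, or a list with `time_s` (onset within the cycle),
#'   `duration_s`, `amplitude`, `center_freq_hz`.
#' @param fs Sampling rate (default 2000 Hz).
#' @param n_cycles Number of heartbeats (default 3).
#' @param cycle_s Nominal cycle length in seconds (default 0.8).
#' @param noise_std Additive white-noise standard deviation (default 0).
#' @param noise_snr_db If non-`NULL`, overrides `noise_std` so the white
#'   noise sits at this SNR (dB) relative to the clean signal RMS.
#' @param timing_jitter_frac Per-beat uniform cycle-length jitter fraction
#'   (default 0).
#' @param seed RNG seed driving all randomness (default 0).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(components, murmur = NULL, click = NULL, fs = 2000,
                         n_cycles = 3, cycle_s = 0.8, noise_std = 0,
                         noise_snr_db = NULL, timing_jitter_frac = 0,
                         seed = 0) {
  stopifnot(length(components) >= 1, n_cycles >= 1, cycle_s > 0, fs > 0)
  ons <- vapply(components, function(cs) cs$offset_in_cycle_s, numeric(1))
  offs <- ons + vapply(components, function(cs) cs$duration_s, numeric(1))
  o <- order(ons)
  if (any(ons[o][-1] < offs[o][-length(o)]))
    stop("component spans within a cycle must not overlap", call. = FALSE)
  if (max(offs) > cycle_s)
    stop("component spans must fit within the cycle", call. = FALSE)
  structure(list(components = components[o], murmur = murmur, click = click,
                 fs = fs, n_cycles = n_cycles, cycle_s = cycle_s,
                 noise_std = noise_std, noise_snr_db = noise_snr_db,
                 timing_jitter_frac = timing_jitter_frac, seed = seed),
            class = "synth_config")
}

# -40 dB (1% of peak) boundary of a component placed at `start` (1-based)
comp_truth_span <- function(wave, start) {
  nz <- which(abs(wave) >= 0.01 * max(abs(wave)))
  c(start + nz[1] - 1L, start + nz[length(nz)] - 1L)
}

#' Generate a ground-truthed synthetic phonocardiogram
#'
#' Deterministic given `config$seed`. Murmurs are white noise band-passed to
#' the configured band (4th-order Butterworth, forward-backward) and scaled
#' to the configured peak amplitude inside a smooth (Tukey-tapered) cycle
#' window. Ground-truth component boundaries are the -40 dB points of each
#' component's envelope, so the truth is insensitive to window tails; the
#' region mask holds the component spans (`u`) and murmur spans (`v`).
#'
#' @param config A [synth_config()].
#' @return A list with `signal` (an [audio_signal]), and `truth` (a list with
#'   `annotations`, `region_mask`, `true_cycle_s` (nominal), and
#'   `realized_cycle_s` (mean of the jittered beat-to-beat spacings)).
#' @export
generate_pcg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  with_seed(config$seed, {
    jit <- if (config$timing_jitter_frac > 0)
      stats::runif(config$n_cycles, -config$timing_jitter_frac,
                   config$timing_jitter_frac)
    else rep(0, config$n_cycles)
    cycle_len <- config$cycle_s * (1 + jit)
    starts_s <- cumsum(c(0, cycle_len[-config$n_cycles]))
    total_s <- sum(cycle_len)
    n <- ceiling(total_s * fs) + round(0.05 * fs)
    x <- numeric(n)

    lab <- character(0); on <- integer(0); off <- integer(0)
    u <- list()
    for (b in seq_len(config$n_cycles)) {
      for (cs in config$components) {
        wave <- make_component(cs$center_freq_hz, cs$duration_s,
                               cs$amplitude, fs)
        start <- round((starts_s[b] + cs$offset_in_cycle_s) * fs) + 1L
        idx <- start:(start + length(wave) - 1L)
        x[idx] <- x[idx] + wave
        span <- comp_truth_span(wave, start)
        lab <- c(lab, cs$label)
        on <- c(on, span[1] - 1L)          # 0-based
        off <- c(off, span[2] - 1L)
        u[[length(u) + 1L]] <- span - 1L
      }
      if (!is.null(config$click)) {
        ck <- config$click
        wave <- make_component(ck$center_freq_hz %||% 180, ck$duration_s,
                               ck$amplitude, fs)
        start <- round((starts_s[b] + ck$time_s) * fs) + 1L
        idx <- start:(start + length(wave) - 1L)
        x[idx] <- x[idx] + wave
      }
    }

    v <- list()
    if (!is.null(config$murmur)) {
      mm <- config$murmur
      bf <- signal::butter(4, c(mm$band_lo_hz, mm$band_hi_hz) / (fs / 2),
                           type = "pass")
      for (b in seq_len(config$n_cycles)) {
        w0 <- starts_s[b] + mm$window_s[1]
        w1 <- starts_s[b] + mm$window_s[2]
        a <- round(w0 * fs) + 1L
        bnd <- round(w1 * fs) + 1L
        m_len <- bnd - a + 1L
        noise <- stats::rnorm(m_len + 2L * round(0.05 * fs))
        band <- signal::filtfilt(bf, noise)
        band <- band[(round(0.05 * fs) + 1L):(round(0.05 * fs) + m_len)]
        taper <- tukey_window(m_len, 0.25)
        band <- band * taper
        band <- band * mm$amplitude / max(abs(band))
        x[a:bnd] <- x[a:bnd] + band
        v[[length(v) + 1L]] <- c(a - 1L, bnd - 1L)
      }
    }

    clean_rms <- rms(x)
    noise_std <- config$noise_std
    if (!is.null(config$noise_snr_db))
      noise_std <- clean_rms / 10^(config$noise_snr_db / 20)
    if (noise_std > 0) x <- x + stats::rnorm(n, sd = noise_std)

    ann <- annotations(lab, on, off, fs = fs)
    list(signal = audio_signal(x, fs),
         truth = list(annotations = ann,
                      region_mask = region_mask(u, v),
                      true_cycle_s = config$cycle_s,
                      realized_cycle_s = mean(cycle_len)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

# default per-preset component specs
spec_s1 <- function() list(label = "S1", center_freq_hz = 100,
                           duration_s = 0.10, amplitude = 1.0,
                           offset_in_cycle_s = 0.00)
spec_s2 <- function() list(label = "S2", center_freq_hz = 120,
                           duration_s = 0.09, amplitude = 0.8,
                           offset_in_cycle_s = 0.30)
spec_s3 <- function() list(label = "S3", center_freq_hz = 45,
                           duration_s = 0.05, amplitude = 0.4,
                           offset_in_cycle_s = 0.51)
spec_s4 <- function() list(label = "S4", center_freq_hz = 35,
                           duration_s = 0.05, amplitude = 0.4,
                           offset_in_cycle_s = 0.68)
systolic_murmur <- function() list(band_lo_hz = 150, band_hi_hz = 400,
                                   window_s = c(0.12, 0.28), amplitude = 0.25)
diastolic_murmur <- function() list(band_lo_hz = 150, band_hi_hz = 400,
                                    window_s = c(0.42, 0.64), amplitude = 0.25)

#' Catalog of synthetic presets
#'
#' Ready-made [synth_config()]s spanning the heart-sound categories the
#' pipeline must handle: two-component beats with and without systolic or
#' diastolic murmurs, S3 and S4 gallops with and without murmurs, the full
#' four-component beat, and a click artifact case. Component frequencies and
#' durations follow the usual physiology (S1/S2 around 80-150 Hz and
#' 90-100 ms; S3/S4 around 20-70 Hz and 50 ms; murmurs band-limited noise
#' above 150 Hz).
#'
#' @param n_cycles Heartbeats per preset (default 3).
#' @param seed RNG seed stored in every preset (default 0).
#' @param ... Further arguments passed to every [synth_config()] (e.g.
#'   `noise_snr_db`, `timing_jitter_frac`).
#' @return Named list of `synth_config` objects.
#' @export
preset_catalog <- function(n_cycles = 3, seed = 0, ...) {
  base <- list(n_cycles = n_cycles, seed = seed, ...)
  mk <- function(components, murmur = NULL, click = NULL)
    do.call(synth_config, c(list(components = components, murmur = murmur,
                                 click = click), base))
  list(
    "normal" = mk(list(spec_s1(), spec_s2())),
    "systolic-murmur" = mk(list(spec_s1(), spec_s2()), murmur = systolic_murmur()),
    "diastolic-murmur" = mk(list(spec_s1(), spec_s2()), murmur = diastolic_murmur()),
    "s3" = mk(list(spec_s1(), spec_s2(), spec_s3())),
    "s4" = mk(list(spec_s1(), spec_s2(), spec_s4())),
    "s3-murmur" = mk(list(spec_s1(), spec_s2(), spec_s3()),
                     murmur = systolic_murmur()),
    "s4-murmur" = mk(list(spec_s1(), spec_s2(), spec_s4()),
                     murmur = systolic_murmur()),
    "four-component" = mk(list(spec_s1(), spec_s2(), spec_s3(), spec_s4())),
    "click" = mk(list(spec_s1(), spec_s2()),
                 click = list(time_s = 0.19, duration_s = 0.01,
                              amplitude = 0.3, center_freq_hz = 180))
  )
}
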