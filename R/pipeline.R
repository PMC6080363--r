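#' Pipeline parameters
#'
#' Aggregates the parameters of every stage with the method's defaults:
#' 2 kHz target rate, db4/level-7 denoising, moving-average radius 5,
#' cutoff search 20-200 Hz with valley threshold 0.2, closing length 30 and
#' opening length 50 samples, lambda 0.8, theta_C 0.025, eta 0.25, side-peak
#' fraction 0.4, final autocorrelation threshold fraction 0.5, and a 300 Hz
#' row ceiling for the S-transform.
#'
#' @param preprocess A [preprocess_params()].
#' @param morphology A [morphology_params()].
#' @param thresholds A [threshold_params()].
#' @param l_f,coeff_threshold,search_lo,search_hi Murmur-elimination
#'   parameters (see [eliminate_murmurs()]).
#' @param sigma_frac,final_frac Cycle-estimation thresholds (see
#'   [estimate_cycle()]).
#' @param max_freq_hz S-transform row ceiling in Hz.
#' @param s3s4_rule `"priors"` or `"verbatim"` (see
#'   [recognize_components()]).
#' @param tol_s Evaluation matching tolerance in seconds.
#' @return A list of class `pcg_params`.
#' @export
pcg_params <- function(preprocess = preprocess_params(),
                       morphology = morphology_params(),
                       thresholds = threshold_params(),
                       l_f = 5L, coeff_threshold = 0.2,
                       search_lo = 20, search_hi = 200,
                       sigma_frac = 0.4, final_frac = 0.5,
                       max_freq_hz = 300, s3s4_rule = "priors",
                       tol_s = 0.05) {
  structure(list(preprocess = preprocess, morphology = morphology,
                 thresholds = thresholds, l_f = l_f,
                 coeff_threshold = coeff_threshold, search_lo = search_lo,
                 search_hi = search_hi, sigma_frac = sigma_frac,
                 final_frac = final_frac, max_freq_hz = max_freq_hz,
                 s3s4_rule = s3s4_rule, tol_s = tol_s),
            class = "pcg_params")
}

#' Segment a heart-sound recording
#'
#' Runs the full pipeline: preprocessing (down-sample, denoise, normalize),
#' murmur elimination (ALPF), boundary detection (morphological envelope +
#' thresholds), cardiac-cycle estimation (unbiased autocorrelation), and
#' component identification (S-transform instantaneous frequency + timing
#' rules). If cycle estimation fails (aperiodic or too-short input) the
#' detected boundaries are still returned with all labels `"unknown"`.
#'
#' @param signal An [audio_signal] (any rate >= 2 kHz) or numeric vector
#'   with `fs`.
#' @param params A [pcg_params()] list.
#' @param fs Sampling rate when `signal` is a plain vector.
#' @return A `pcg_segmentation` (see [build_segmentation()]) whose
#'   `diagnostics` field records the ALPF cutoff, envelope threshold theta,
#'   candidate/final pair counts, the cycle estimate or failure message, and
#'   per-beat component counts.
#' @export
segment_recording <- function(signal, params = pcg_params(), fs = NULL) {
  signal <- as_audio_signal(signal, fs)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "pcg_cycle_error")) stop(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  hs_n <- stage("preprocess", preprocess(signal, params$preprocess))
  me <- stage("murmur_elimination",
              eliminate_murmurs(hs_n, params$l_f, params$coeff_threshold,
                                params$search_lo, params$search_hi))
  bd <- stage("boundary_detection",
              detect_boundaries(me$signal, params$morphology,
                                params$thresholds))
  bs <- bd$bs
  fs2 <- hs_n$fs

  cycle <- NULL
  cycle_msg <- NULL
  if (bs$m > 0L) {
    cycle <- tryCatch(
      estimate_cycle(bd$env, fs2, params$sigma_frac, params$final_frac),
      pcg_cycle_error = function(e) {
        cycle_msg <<- conditionMessage(e)
        NULL
      })
  } else {
    cycle_msg <- "no components detected"
  }

  avg_freqs <- if (bs$m > 0L)
    stage("component_identification",
          component_avg_frequencies(hs_n, bs, params$max_freq_hz))
  else numeric(0)

  if (!is.null(cycle)) {
    beats <- group_into_beats(bs, cycle, avg_freqs)
    labels <- stage("component_identification",
                    recognize_components(beats, bs, avg_freqs, cycle,
                                         params$s3s4_rule))
  } else {
    beats <- NULL
    labels <- rep("unknown", bs$m)
  }

  seg <- build_segmentation(bs, labels, avg_freqs, beats, cycle, fs2)
  seg$diagnostics <- list(
    fs = fs2,
    cutoff_hz = me$cutoff$cutoff_hz,
    primary_peak_hz = me$cutoff$primary_peak_hz,
    found_valley = me$cutoff$found_valley,
    theta = bd$diagnostics$theta,
    n_candidates = bd$diagnostics$n_candidates,
    n_final = bs$m,
    cycle_failure = cycle_msg,
    beat_sizes = if (!is.null(beats))
      vapply(beats, function(b) length(b$components), integer(1))
    else integer(0))
  seg
}

#' Windowed segmentation with overlap reconciliation
#'
#' Splits the recording into three-cycle windows overlapping by one cycle
#' (the windowing used when long recordings are reviewed piecewise), runs
#' [segment_recording()] per window, and reconciles components detected in
#' more than one window by majority label (ties become `"unknown"`).
#' Requires the cycle to be estimable on a leading chunk (or, failing that,
#' the whole recording).
#'
#' @inheritParams segment_recording
#' @param window_cycles Cycles per window (default 3).
#' @param overlap_cycles Overlap between adjacent windows (default 1).
#' @return A `pcg_segmentation` over the whole recording.
#' @export
run_windowed <- function(signal, params = pcg_params(), fs = NULL,
                         window_cycles = 3, overlap_cycles = 1) {
  signal <- as_audio_signal(signal, fs)
  hs_n <- preprocess(signal, params$preprocess)
  fs2 <- hs_n$fs
  n <- length(hs_n$samples)
  # size the windows from a short leading chunk: the autocorrelation
  # estimator is designed for inputs of about three cycles, where the
  # forcible last-peak removal cancels the unbiased-divisor amplification
  est_on <- function(x) {
    me <- eliminate_murmurs(audio_signal(x, fs2), params$l_f,
                            params$coeff_threshold, params$search_lo,
                            params$search_hi)
    bd <- detect_boundaries(me$signal, params$morphology, params$thresholds)
    estimate_cycle(bd$env, fs2, params$sigma_frac, params$final_frac)
  }
  cycle0 <- tryCatch(est_on(hs_n$samples[seq_len(min(n, round(4 * fs2)))]),
                     error = function(e) NULL)
  if (is.null(cycle0))
    cycle0 <- tryCatch(est_on(hs_n$samples), error = function(e)
      stop("cycle estimation failed; cannot window the recording",
           call. = FALSE))
  cyc_n <- cycle0$avg_cycle_samples
  step <- (window_cycles - overlap_cycles) * cyc_n
  starts <- seq(0, max(0, n - 1), by = step)
  starts <- starts[starts < n - cyc_n / 2]

  votes <- list()   # key: onset sample -> list(labels, onset, offset)
  for (s0 in starts) {
    a <- floor(s0) + 1L
    b <- min(n, floor(s0 + window_cycles * cyc_n))
    if (b - a < cyc_n) next
    seg <- tryCatch(
      segment_recording(audio_signal(hs_n$samples[a:b], fs2), params),
      error = function(e) NULL)
    if (is.null(seg)) next
    comp <- seg$components
    for (i in seq_len(nrow(comp))) {
      key <- as.character(round((comp$onset_sample[i] + a - 1L) / 20))
      rec <- votes[[key]] %||% list(labels = character(0),
                                    onset = comp$onset_sample[i] + a - 1L,
                                    offset = comp$offset_sample[i] + a - 1L)
      rec$labels <- c(rec$labels, comp$label[i])
      votes[[key]] <- rec
    }
  }
  if (!length(votes))
    return(segment_recording(signal, params))
  ord <- order(vapply(votes, function(v) v$onset, numeric(1)))
  votes <- votes[ord]
  onset <- vapply(votes, function(v) v$onset, numeric(1))
  offset <- vapply(votes, function(v) v$offset, numeric(1))
  labels <- vapply(votes, function(v) {
    lab <- v$labels[v$labels != "unknown"]   # a real label outvotes "unknown"
    if (!length(lab)) return("unknown")
    tab <- sort(table(lab), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "unknown" else names(tab)[1]
  }, character(1))
  keep <- c(TRUE, diff(onset) > 0 & onset[-1] > offset[-length(offset)])
  bs <- boundary_set(onset[keep], offset[keep])
  seg <- build_segmentation(bs, labels[keep],
                            rep(NA_real_, sum(keep)), NULL, cycle0, fs2)
  seg$diagnostics <- list(fs = fs2, windowed = TRUE,
                          window_cycle_samples = cyc_n,
                          n_windows = length(starts))
  seg
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper: boundary confusion counts and Se/PPV/Acc at the
#' matching tolerance, plus label accuracy.
#'
#' @param seg A `pcg_segmentation` (or annotation data frame).
#' @param truth Truth annotations (see [annotations()]).
#' @param tol_s Matching tolerance in seconds (default 0.05).
#' @param fs Sampling rate for converting a segmentation (default 2000).
#' @return A list with `counts`, `se`, `ppv`, `acc`, `label_acc`.
#' @export
evaluate_segmentation <- function(seg, truth, tol_s = 0.05, fs = 2000) {
  pred <- if (inherits(seg, "pcg_segmentation"))
    segmentation_to_annotations(seg, fs) else seg
  cc <- match_detections(pred, truth, tol_s)
  m <- confusion_metrics(cc)
  list(counts = cc, se = m$se, ppv = m$ppv, acc = m$acc,
       label_acc = label_accuracy(pred, truth, tol_s))
}
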