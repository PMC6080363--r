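#' Morphology and threshold parameters for boundary detection
#'
#' `q` (closing element length, default 30 samples = 15 ms at 2 kHz) must stay
#' below the shortest inter-component gap (>= 100 ms = 200 samples) so that
#' distinct components are never merged; `q_open` (opening element length,
#' default 50 samples = 25 ms) must stay below the shortest component duration
#' (S3/S4, about 50 ms = 100 samples) so that true components survive while
#' narrow residues are removed.
#'
#' @param q Closing structuring-element length in samples (0 < q < 200).
#' @param q_open Opening structuring-element length in samples
#'   (0 < q_open < 100).
#' @return A list of class `morphology_params`.
#' @export
morphology_params <- function(q = 30L, q_open = 50L) {
  stopifnot(q >= 1, q < 200, q_open >= 1, q_open < 100)
  structure(list(q = as.integer(q), q_open = as.integer(q_open)),
            class = "morphology_params")
}

#' @param lambda Scale on the envelope standard deviation in the adaptive
#'   threshold (default 0.8).
#' @param theta_c Fixed reference threshold capping the adaptive one
#'   (default 0.025).
#' @param eta Energy threshold on per-pair envelope energy (default 0.25).
#' @return A list of class `threshold_params`.
#' @rdname morphology_params
#' @export
threshold_params <- function(lambda = 0.8, theta_c = 0.025, eta = 0.25) {
  stopifnot(lambda > 0, theta_c > 0, eta > 0)
  structure(list(lambda = lambda, theta_c = theta_c, eta = eta),
            class = "threshold_params")
}

#' Adaptive amplitude thresholding of the envelope
#'
#' Zeroes envelope samples below `theta = min(theta_a, theta_c)` where
#' `theta_a = lambda * sd(env)` (population standard deviation, divisor N) and
#' `theta_c` is the fixed cap. The small threshold separates murmur residues
#' that remain attached to component boundaries while preserving as much
#' boundary information as possible.
#'
#' @param env Numeric envelope (normalized closing output).
#' @param params A [threshold_params()] list.
#' @return A list with `env` (thresholded envelope), `theta`, `theta_a`, `mu`.
#' @export
adaptive_threshold <- function(env, params = threshold_params()) {
  if (!length(env)) stop("empty envelope", call. = FALSE)
  mu <- mean(env)
  theta_a <- params$lambda * sqrt(mean((env - mu)^2))
  theta <- min(theta_a, params$theta_c)
  out <- ifelse(env < theta, 0, env)
  list(env = out, theta = theta, theta_a = theta_a, mu = mu)
}

#' Boundary-pair container
#'
#' Candidate component onsets and offsets as 0-based sample indices,
#' strictly interleaved
#' (`onset[k] < offset[k] < onset[k+1]`), with the per-pair envelope energy.
#'
#' @param onset,offset Integer 0-based sample indices.
#' @param energy Per-pair energies (optional until [energy_filter()]).
#' @return A list of class `boundary_set` with fields `onset`, `offset`,
#'   `energy`, `m` (pair count).
#' @export
boundary_set <- function(onset = integer(), offset = integer(),
                         energy = rep(NA_real_, length(onset))) {
  onset <- as.integer(onset); offset <- as.integer(offset)
  if (length(onset) != length(offset))
    stop("onsets and offsets must pair up", call. = FALSE)
  if (length(onset)) {
    if (any(offset <= onset))
      stop("each offset must exceed its onset", call. = FALSE)
    if (length(onset) > 1L && any(onset[-1L] <= offset[-length(offset)]))
      stop("boundary pairs must be strictly interleaved", call. = FALSE)
  }
  structure(list(onset = onset, offset = offset, energy = as.numeric(energy),
                 m = length(onset)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set> %d onset/offset pair(s)\n", x$m))
  invisible(x)
}

#' Candidate boundaries from the opened envelope
#'
#' An onset is a zero sample immediately followed by a nonzero sample; an
#' offset is a zero sample immediately preceded by a nonzero one (0-based
#' indices, so each pair brackets its nonzero run with the adjacent
#' zeros). A nonzero run touching the sequence edge takes
#' the edge index as its onset/offset. Runs separated by a single zero sample
#' (whose bracketing onset and offset would coincide) are merged into one
#' pair: at envelope resolution they are one component.
#'
#' @param env Numeric envelope containing exact zeros (opening output).
#' @return A [boundary_set()] (possibly empty).
#' @export
extract_candidate_boundaries <- function(env) {
  runs <- true_runs(env != 0)
  if (!nrow(runs)) return(boundary_set())
  if (nrow(runs) > 1L) {
    keep <- matrix(runs[1L, ], ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - keep[nrow(keep), "end"] <= 2L)
        keep[nrow(keep), "end"] <- runs[i, "end"]
      else keep <- rbind(keep, runs[i, ])
    }
    runs <- keep
  }
  onset <- pmax(runs[, "start"] - 1L, 1L) - 1L   # zero before the run, edge-clamped
  offset <- pmin(runs[, "end"] + 1L, length(env)) - 1L
  boundary_set(onset, offset)
}

#' Energy filtering of candidate pairs
#'
#' Computes each pair's energy `E_k = sum(env[onset_k..offset_k]^2)`
#' (inclusive; the bracketing zero samples contribute nothing) and removes
#' pairs with `E_k < eta`, zeroing their envelope samples. Ties (`E_k == eta`)
#' are kept. Surviving pairs are the final component boundaries.
#'
#' @param env Numeric opened, unit-peak envelope.
#' @param bs The [boundary_set()] extracted from `env`.
#' @param eta Energy threshold (default 0.25).
#' @return A list with `env` (energy-filtered envelope) and `bs` (surviving
#'   [boundary_set()] carrying energies).
#' @export
energy_filter <- function(env, bs, eta = 0.25) {
  if (bs$m == 0L) return(list(env = env, bs = bs))
  if (max(bs$offset) > length(env) - 1L)
    stop("boundary set does not match the envelope", call. = FALSE)
  energy <- vapply(seq_len(bs$m), function(k) {
    sum(env[(bs$onset[k] + 1L):(bs$offset[k] + 1L)]^2)
  }, numeric(1))
  drop <- energy < eta
  for (k in which(drop)) env[(bs$onset[k] + 1L):(bs$offset[k] + 1L)] <- 0
  list(env = env,
       bs = boundary_set(bs$onset[!drop], bs$offset[!drop], energy[!drop]))
}

#' Boundary detection stage
#'
#' Full pipeline from the murmur-reduced signal to final component
#' boundaries: full-wave rectification, morphological closing (envelope
#' extraction) with normalization, adaptive amplitude thresholding,
#' morphological opening with normalization, candidate onset/offset
#' extraction, and per-pair energy filtering. The closing is applied to the
#' rectified signal so the envelope bounds both polarities of the oscillatory
#' waveform.
#'
#' @param signal The murmur-reduced, unit-peak [audio_signal] at 2 kHz.
#' @param mp A [morphology_params()] list.
#' @param tp A [threshold_params()] list.
#' @return A list with `bs` (final [boundary_set()]), `env` (energy-filtered
#'   envelope), and `diagnostics` (theta, theta_a, mu, candidate count).
#' @export
detect_boundaries <- function(signal, mp = morphology_params(),
                              tp = threshold_params()) {
  signal <- as_audio_signal(signal)
  closed <- morph_close(abs(signal$samples), mp$q)
  if (max(closed) == 0) {
    return(list(bs = boundary_set(), env = closed,
                diagnostics = list(theta = NA_real_, theta_a = NA_real_,
                                   mu = NA_real_, n_candidates = 0L)))
  }
  e_nlp <- closed / max(closed)
  th <- adaptive_threshold(e_nlp, tp)
  opened <- morph_open(th$env, mp$q_open)
  if (max(opened) == 0) {
    return(list(bs = boundary_set(), env = opened,
                diagnostics = list(theta = th$theta, theta_a = th$theta_a,
                                   mu = th$mu, n_candidates = 0L)))
  }
  e_no <- opened / max(opened)
  cand <- extract_candidate_boundaries(e_no)
  ef <- energy_filter(e_no, cand, tp$eta)
  list(bs = ef$bs, env = ef$env,
       diagnostics = list(theta = th$theta, theta_a = th$theta_a, mu = th$mu,
                          n_candidates = cand$m))
}
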