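# Discrete wavelet transform (Daubechies family) with symmetric boundary
# extension, used only for the soft-threshold denoising step. The filter bank
# and coefficient-length bookkeeping follow the usual pyramid algorithm:
# analysis pads by (filter length - 1) on each side, convolves, and keeps every
# second sample; synthesis upsamples, convolves with the reconstruction
# filters, and trims back to the stored length.

# db4 scaling (low-pass decomposition) filter, 8 taps, sum = sqrt(2).
DB4_DEC_LO <- c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.18703481171888114,
                -0.02798376941698385,  0.6308807679295904,
                 0.7148465705525415,   0.23037781330885523)

wave_filters <- function(wavelet = "db4") {
  if (!identical(wavelet, "db4"))
    stop("only the db4 wavelet is built in", call. = FALSE)
  dec_lo <- DB4_DEC_LO
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^seq_len(L)             # QMF
  rec_lo <- rev(dec_lo)
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi, L = L)
}

# Symmetric (half-point, edge-repeating) extension by `k` samples per side.
sym_ext <- function(x, k) {
  n <- length(x)
  left <- x[pmin(pmax(k:1, 1L), n)]
  right <- x[pmin(pmax(n:(n - k + 1L), 1L), n)]
  c(left, x, right)
}

conv_full <- function(x, h) {
  # true full convolution, length(x) + length(h) - 1; filter is short so
  # O(N*L) via stats::filter is fine
  n <- length(x); L <- length(h)
  xp <- c(rep(0, L - 1L), x, rep(0, L - 1L))
  out <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(out[L:(n + 2L * L - 2L)])
}

dwt_step <- function(x, f) {
  L <- f$L
  xe <- sym_ext(x, L - 1L)
  full_lo <- conv_full(xe, f$dec_lo)
  full_hi <- conv_full(xe, f$dec_hi)
  # decimation phase chosen to match the usual symmetric-mode convention
  idx <- seq(L + 1L, length(full_lo), by = 2L)
  ca <- full_lo[idx]
  cd <- full_hi[idx]
  keep <- floor((length(x) + L - 1) / 2)
  list(ca = ca[seq_len(keep)], cd = cd[seq_len(keep)])
}

idwt_step <- function(ca, cd, f, out_len) {
  L <- f$L
  up <- function(c) { u <- numeric(2L * length(c)); u[seq(1L, length(u), 2L)] <- c; u }
  y <- conv_full(up(ca), f$rec_lo) + conv_full(up(cd), f$rec_hi)
  y <- y[(L - 1L):length(y)]            # cancel analysis/synthesis delay
  y[seq_len(out_len)]
}

#' Multilevel discrete wavelet decomposition
#'
#' @param x Numeric vector.
#' @param level Number of decomposition levels (>= 1).
#' @param wavelet Wavelet name; only `"db4"` is built in.
#' @return A list with the final approximation (`ca`), detail coefficient
#'   vectors per level (`cd`, finest first), and the per-level input lengths
#'   needed for reconstruction.
#' @seealso [wave_reconstruct()], [denoise()]
#' @export
wave_decompose <- function(x, level, wavelet = "db4") {
  f <- wave_filters(wavelet)
  if (level < 1) stop("level must be >= 1", call. = FALSE)
  max_level <- floor(log2(length(x) / (f$L - 1)))
  if (max_level < level)
    stop(sprintf("signal too short (%d samples) for a level-%d decomposition",
                 length(x), level), call. = FALSE)
  cds <- vector("list", level)
  lens <- integer(level)
  cur <- x
  for (j in seq_len(level)) {
    lens[j] <- length(cur)
    st <- dwt_step(cur, f)
    cds[[j]] <- st$cd
    cur <- st$ca
  }
  list(ca = cur, cd = cds, lengths = lens, wavelet = wavelet, level = level)
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' Exact inverse of [wave_decompose()] when coefficients are unmodified.
#'
#' @param dec A decomposition as returned by [wave_decompose()].
#' @return Numeric vector of the original length.
#' @export
wave_reconstruct <- function(dec) {
  f <- wave_filters(dec$wavelet)
  cur <- dec$ca
  for (j in rev(seq_len(dec$level))) {
    cur <- idwt_step(cur, dec$cd[[j]], f, dec$lengths[j])
  }
  cur
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
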