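# Independent brute-force oracles used by the property and acceptance tests.
# Each oracle is a direct, unoptimized transcription of the defining formula
# and shares no code with the package implementation.

# windowed max/min morphology with centered window of radius floor(q/2)
brute_dilate <- function(x, q) {
  r <- floor(q / 2); n <- length(x)
  vapply(seq_len(n), function(i) max(x[max(1, i - r):min(n, i + r)]), numeric(1))
}
brute_erode <- function(x, q) {
  r <- floor(q / 2); n <- length(x)
  vapply(seq_len(n), function(i) min(x[max(1, i - r):min(n, i + r)]), numeric(1))
}
brute_close <- function(x, q) brute_erode(brute_dilate(x, q), q)
brute_open <- function(x, q) brute_dilate(brute_erode(x, q), q)

# three-branch moving-average smoothing, double loop (0-based n as written)
brute_moving_average <- function(x, l_f) {
  n_len <- length(x)
  out <- numeric(n_len)
  for (n0 in 0:(n_len - 1)) {
    if (n0 <= l_f - 1) {
      ks <- 0:(n0 + l_f)
      div <- l_f + n0 + 1
    } else if (n0 <= n_len - l_f - 1) {
      ks <- (n0 - l_f):(n0 + l_f)
      div <- 2 * l_f + 1
    } else {
      ks <- (n0 - l_f):(n_len - 1)          # window clipped at the end
      div <- l_f + n_len - n0
    }
    out[n0 + 1] <- sum(x[ks + 1]) / div
  }
  out
}

# direct lagged-product autocorrelations, double loop
brute_uacf <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(m) {
    sum(x[1:(n - m)] * x[(1 + m):n]) / (n - m)
  }, numeric(1))
}
brute_pacf <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(m) {
    sum(x[1:(n - m)] * x[(1 + m):n]) / n
  }, numeric(1))
}

# direct double-sum Stockwell transform (H normalized by N; zero row = mean)
brute_stockwell <- function(h) {
  n_len <- length(h)
  H <- stats::fft(h) / n_len
  S <- matrix(0 + 0i, nrow = n_len, ncol = n_len)
  S[1, ] <- mean(h)
  m <- 0:(n_len - 1)
  for (vn in 1:(n_len - 1)) {
    w <- H[((m + vn) %% n_len) + 1] * exp(-2 * pi^2 * m^2 / vn^2)
    for (j in 0:(n_len - 1)) {
      S[vn + 1, j + 1] <- sum(w * exp(2i * pi * m * j / n_len))
    }
  }
  S
}

# random valid component annotation set (sorted, non-overlapping)
random_annotations <- function(n, fs = 2000) {
  if (n == 0) return(annotations(fs = fs))
  len <- sample(50:200, n, replace = TRUE)
  gap <- sample(10:300, n, replace = TRUE)
  onset <- cumsum(gap + c(0, len[-n]))
  annotations(sample(c("S1", "S2", "S3", "S4", "unknown"), n, replace = TRUE),
              onset, onset + len, fs = fs)
}
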