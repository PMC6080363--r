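# Internal helpers shared across modules.

# Unit-peak normalization of a plain numeric vector. Errors on all-zero input
# (division by zero) and on non-finite values.
unit_peak <- function(x, what = "signal") {
  if (!length(x)) stop(what, " is empty", call. = FALSE)
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  m <- max(abs(x))
  if (m == 0) stop("cannot normalize an all-zero ", what, call. = FALSE)
  x / m
}

# Running windowed extremum with a centered window of length 2*radius + 1.
# Edges shrink to the valid part of the window (pad value is the identity
# element of `fun`, so padded entries never win).
running_extreme <- function(x, radius, fun = pmax, pad = -Inf) {
  n <- length(x)
  if (radius < 1) return(x)
  xp <- c(rep(pad, radius), x, rep(pad, radius))
  out <- x
  for (s in c(-radius:-1, 1:radius)) {
    out <- fun(out, xp[(radius + 1 + s):(radius + n + s)])
  }
  out
}

# Maximal runs of entries for which `flag` is TRUE; returns a two-column
# matrix of 1-based [start, end] indices (zero rows when no run exists).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rms <- function(x) sqrt(mean(x^2))
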