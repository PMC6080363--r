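#' Region mask for signal-murmur ratio
#'
#' `u` holds the sample ranges occupied by heart-sound components (S1-S4),
#' `v` the ranges occupied by murmurs. Ranges are two-column matrices (or
#' lists of length-2 vectors) of 0-based inclusive `[start, end]` indices;
#' the two sets must be disjoint.
#'
#' @param u,v Component / murmur ranges.
#' @return A list of class `region_mask`.
#' @export
region_mask <- function(u, v) {
  norm <- function(r) {
    if (is.null(r) || !length(r)) return(matrix(integer(0), ncol = 2))
    if (is.list(r)) r <- do.call(rbind, r)
    r <- matrix(as.integer(r), ncol = 2)
    if (any(r[, 2] < r[, 1])) stop("range end before start", call. = FALSE)
    r
  }
  u <- norm(u); v <- norm(v)
  expand <- function(r) unlist(lapply(seq_len(nrow(r)), function(i) r[i, 1]:r[i, 2]))
  if (length(intersect(expand(u), expand(v))))
    stop("component and murmur regions must be disjoint", call. = FALSE)
  structure(list(u = u, v = v), class = "region_mask")
}

mask_indices <- function(r) {
  if (!nrow(r)) return(integer(0))
  unique(unlist(lapply(seq_len(nrow(r)), function(i) r[i, 1]:r[i, 2])))
}

#' Signal-murmur ratio (SMR)
#'
#' `10 log10` of the energy in the component regions over the energy in the
#' murmur regions: the higher the SMR, the smaller the murmur energy
#' proportion, i.e. the stronger the murmur-removal effect. Invariant under
#' global amplitude scaling of the signal.
#'
#' @param signal An [audio_signal] or numeric vector.
#' @param mask A [region_mask()] with nonempty `u` and `v`, within the
#'   signal length.
#' @return SMR in dB.
#' @export
smr <- function(signal, mask) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
  stopifnot(inherits(mask, "region_mask"))
  ui <- mask_indices(mask$u); vi <- mask_indices(mask$v)
  if (!length(ui) || !length(vi))
    stop("both component (u) and murmur (v) regions are required", call. = FALSE)
  if (max(ui, vi) > length(x) - 1L)
    stop("mask exceeds the signal length", call. = FALSE)
  ev <- sum(x[vi + 1L]^2)
  if (ev == 0) stop("murmur-region energy is zero; SMR undefined", call. = FALSE)
  10 * log10(sum(x[ui + 1L]^2) / ev)
}

#' SMR gain and relative gain
#'
#' `smr_gain()` subtracts the SMR of the unfiltered sound from the filtered
#' one (dB); `percent_gain()` expresses the excess of one dB gain over
#' another as a percentage of the latter.
#'
#' @param filtered_smr,original_smr SMR values in dB.
#' @return Gain in dB.
#' @export
smr_gain <- function(filtered_smr, original_smr) {
  stopifnot(is.finite(filtered_smr), is.finite(original_smr))
  filtered_smr - original_smr
}

#' @param a_db,b_db dB gains to compare.
#' @rdname smr_gain
#' @return `percent_gain()`: `(a_db - b_db) / b_db * 100`.
#' @export
percent_gain <- function(a_db, b_db) {
  stopifnot(is.finite(a_db), is.finite(b_db))
  if (b_db == 0) stop("reference gain is zero; percent gain undefined", call. = FALSE)
  (a_db - b_db) / b_db * 100
}

#' Confusion counts and the Se/PPV/Acc metrics
#'
#' @param tp,fn,fp,tn Nonnegative integer counts. For pure event detection
#'   there is no negative class, so `tn` is structurally 0 and accuracy
#'   reduces to `TP / (TP + FN + FP)`.
#' @return `confusion_counts()`: a list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fn = 0L, fp = 0L, tn = 0L) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' @param counts A `confusion_counts` object.
#' @rdname confusion_counts
#' @return `confusion_metrics()`: a list with `se`, `ppv`, `acc` in percent.
#'   A zero denominator for a metric is an error.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (tp + fn == 0) stop("Se undefined: TP + FN == 0", call. = FALSE)
    if (tp + fp == 0) stop("PPV undefined: TP + FP == 0", call. = FALSE)
    list(se = tp / (tp + fn) * 100,
         ppv = tp / (tp + fp) * 100,
         acc = (tp + tn) / (tp + tn + fp + fn) * 100)
  })
}

#' Match detected components against ground truth
#'
#' Greedy one-to-one matching of predicted component annotations to truth by
#' onset time: predictions are visited in onset order and matched to the
#' closest unmatched truth component within `tol_s` seconds. Matched pairs
#' are TP, unmatched predictions FP, unmatched truth FN (TN is structurally
#' 0). With `label_aware = TRUE`, a time-matched pair with differing labels
#' counts as FP + FN instead of TP. Murmur annotations are excluded on both
#' sides.
#'
#' @param predicted,truth Annotation data frames (see [annotations()]).
#' @param tol_s Matching tolerance on the onset difference in seconds
#'   (default 0.05, half the minimum inter-component gap).
#' @param label_aware Require label equality for a TP (default FALSE).
#' @return A `confusion_counts` with an additional attribute
#'   `"label_matches"`: for time-matched pairs, a logical vector of label
#'   agreement.
#' @export
match_detections <- function(predicted, truth, tol_s = 0.05,
                             label_aware = FALSE) {
  if (tol_s < 0) stop("tolerance must be nonnegative", call. = FALSE)
  keep <- function(a) a[a$label != "murmur", , drop = FALSE]
  p <- keep(predicted); t <- keep(truth)
  p <- p[order(p$onset_s), , drop = FALSE]
  t <- t[order(t$onset_s), , drop = FALSE]
  matched_t <- rep(FALSE, nrow(t))
  tp <- 0L; fp <- 0L
  label_ok <- logical(0)
  for (i in seq_len(nrow(p))) {
    d <- abs(t$onset_s - p$onset_s[i])
    d[matched_t] <- Inf
    j <- if (nrow(t)) which.min(d) else integer(0)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      matched_t[j] <- TRUE
      same <- identical(p$label[i], t$label[j])
      label_ok <- c(label_ok, same)
      if (!label_aware || same) tp <- tp + 1L else fp <- fp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  fn <- sum(!matched_t) + if (label_aware) sum(!label_ok) else 0L
  out <- confusion_counts(tp = tp, fn = fn, fp = fp, tn = 0L)
  attr(out, "label_matches") <- label_ok
  out
}

#' Fraction of truth components recovered with the correct label
#'
#' @inheritParams match_detections
#' @return Percentage in `[0, 100]`.
#' @export
label_accuracy <- function(predicted, truth, tol_s = 0.05) {
  cc <- match_detections(predicted, truth, tol_s, label_aware = FALSE)
  ok <- attr(cc, "label_matches")
  n_truth <- sum(truth$label != "murmur")
  if (n_truth == 0) stop("no truth components", call. = FALSE)
  sum(ok) / n_truth * 100
}

#' Paired two-sample t statistic and critical value
#'
#' `paired_t()` computes `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y`
#' and the sample standard deviation (divisor n-1). `t_critical()` is the
#' upper `alpha/2` quantile of Student's t distribution (two-sided test at
#' level `alpha`), computed from the distribution quantile function, not a
#' table.
#'
#' @param x,y Equal-length numeric vectors (n >= 2) of paired measurements.
#' @return `paired_t()`: the t statistic.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of the differences; t undefined", call. = FALSE)
  mean(d) / (s / sqrt(n))
}

#' @param alpha Two-sided significance level in (0, 1).
#' @param df Degrees of freedom.
#' @rdname paired_t
#' @return `t_critical()`: the critical value.
#' @export
t_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}
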