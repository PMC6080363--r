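#' Group detected components into heartbeats
#'
#' Beats are found from the average cardiac cycle by re-anchoring: the first
#' beat starts at the onset of the first detected component, and each next
#' beat starts at the component whose onset is closest to the previous
#' anchor plus one cycle (searched within a quarter cycle of that
#' prediction, wide enough for beat-to-beat timing jitter but narrower than
#' the offset of any within-beat component from the next beat start).
#' Re-anchoring on actual component onsets keeps beats aligned when the
#' rhythm drifts, where a rigid grid of cycle-length windows would
#' accumulate the beat-to-beat timing error. A beat holds every component
#' from its anchor up to the next anchor; beats holding 2, 3 or 4 components
#' are classifiable, other counts are flagged (their components will be
#' labelled "unknown").
#'
#' @param bs A [boundary_set()] of final component boundaries.
#' @param cycle A `cycle_estimate` from [estimate_cycle()], or cycle length
#'   in samples.
#' @param avg_freqs Optional per-component average instantaneous frequencies
#'   (Hz). When given, a trailing single-component "beat" whose frequency
#'   lies below every component of the preceding beat — the signature of a
#'   gallop sound whose following S1 lies beyond the end of the recording —
#'   is merged back into that beat.
#' @return A list of beats; each beat is a list with `components` (indices
#'   into `bs`) and `classifiable` (logical).
#' @export
group_into_beats <- function(bs, cycle, avg_freqs = NULL) {
  if (bs$m == 0L) return(list())
  cyc <- if (inherits(cycle, "cycle_estimate")) cycle$avg_cycle_samples else cycle
  stopifnot(is.finite(cyc), cyc > 0)
  anchors <- 1L
  repeat {
    pred <- bs$onset[anchors[length(anchors)]] + cyc
    cand <- which(bs$onset > pred - cyc / 4 & bs$onset <= pred + cyc / 4)
    cand <- cand[cand > anchors[length(anchors)]]
    if (!length(cand)) break
    anchors <- c(anchors, cand[which.min(abs(bs$onset[cand] - pred))])
  }
  if (length(anchors) >= 2L && !is.null(avg_freqs)) {
    last <- anchors[length(anchors)]
    prev_idx <- anchors[length(anchors) - 1L]:(last - 1L)
    if (last == bs$m &&                      # trailing singleton
        length(prev_idx) %in% 2:3 &&
        avg_freqs[last] < min(avg_freqs[prev_idx])) {
      anchors <- anchors[-length(anchors)]
    }
  }
  bounds <- c(anchors, bs$m + 1L)
  lapply(seq_along(anchors), function(k) {
    idx <- bounds[k]:(bounds[k + 1L] - 1L)
    list(components = idx, classifiable = length(idx) %in% 2:4)
  })
}

#' Recognize heart-sound components within each beat
#'
#' Applies the per-beat rules of the segmentation method. Two components:
#' the intra-beat gap `T12` is compared with the gap `T21` to the next beat's
#' first component; the smaller intra-beat gap means systole, i.e. (S1, S2),
#' otherwise (S2, S1). Three components: the component with the lowest
#' average instantaneous frequency is the extra (gallop) sound; its immediate
#' predecessor is S2 and its successor S1, and the extra sound is resolved to
#' S3 or S4 from the timing priors (the S2-S3 gap is shorter than the S3-S1
#' gap, while the S2-S4 gap is longer than the S4-S1 gap). Four components:
#' the earlier of the two lowest-frequency components is S3 and the later S4;
#' the component preceding S3 is S2 and the one following S4 is the next S1.
#' A final beat lacking a successor reuses the majority orientation of the
#' earlier beats (two-component case) or a cycle-predicted next onset.
#'
#' All gaps are measured from the offset of the earlier component to the
#' onset of the later one (the silent interval between components).
#'
#' @param beats Beat grouping from [group_into_beats()].
#' @param bs The [boundary_set()] the beats index into.
#' @param avg_freqs Per-component average instantaneous frequencies (Hz),
#'   from [component_avg_frequencies()].
#' @param cycle A `cycle_estimate` or cycle length in samples (used for
#'   tail-beat fallbacks).
#' @param s3s4_rule Either `"priors"` (default; the timing priors above) or
#'   `"verbatim"` (the alternative published comparison: extra sound is S4
#'   when the gap before it is smaller than the gap after).
#' @return Character vector of labels (`S1`/`S2`/`S3`/`S4`/`unknown`), one
#'   per component of `bs`.
#' @export
recognize_components <- function(beats, bs, avg_freqs, cycle,
                                 s3s4_rule = c("priors", "verbatim")) {
  s3s4_rule <- match.arg(s3s4_rule)
  cyc <- if (inherits(cycle, "cycle_estimate")) cycle$avg_cycle_samples else cycle
  labels <- rep("unknown", bs$m)
  orientation_votes <- character(0)   # "S1" or "S2" first, from 2-comp beats

  gap <- function(i, j) bs$onset[j] - bs$offset[i]   # silent interval, samples

  for (b in seq_along(beats)) {
    idx <- beats[[b]]$components
    if (!beats[[b]]$classifiable) next
    nb <- length(idx)

    if (nb == 2L) {
      t12 <- gap(idx[1], idx[2])
      nxt <- if (b < length(beats)) beats[[b + 1L]]$components[1L] else NA_integer_
      if (!is.na(nxt)) {
        t21 <- gap(idx[2], nxt)
        first <- if (t12 < t21) "S1" else "S2"
      } else if (length(orientation_votes)) {
        tab <- table(orientation_votes)
        first <- names(tab)[which.max(tab)]
      } else {
        predicted_next <- bs$onset[idx[1]] + cyc
        t21 <- predicted_next - bs$offset[idx[2]]
        first <- if (t12 < t21) "S1" else "S2"
      }
      labels[idx] <- if (first == "S1") c("S1", "S2") else c("S2", "S1")
      orientation_votes <- c(orientation_votes, first)

    } else if (nb == 3L) {
      x <- which.min(avg_freqs[idx])            # extra (gallop) sound
      rest <- setdiff(seq_len(nb), x)
      # immediate predecessor of the extra sound is S2, successor is S1
      before <- rest[rest < x]
      after <- rest[rest > x]
      if (length(before)) labels[idx[max(before)]] <- "S2"
      if (length(after)) labels[idx[min(after)]] <- "S1"
      unlabeled <- idx[rest][labels[idx[rest]] == "unknown"]
      if (length(unlabeled) == 1L) {
        labels[unlabeled] <- setdiff(c("S1", "S2"), labels[idx[rest]])
      }
      # S3/S4 from the surrounding gaps
      gx <- idx[x]
      gap_before <- if (gx > 1L) gap(gx - 1L, gx) else NA_real_
      gap_after <- if (gx < bs$m) gap(gx, gx + 1L)
                   else (bs$onset[idx[1L]] + cyc) - bs$offset[gx]
      if (is.na(gap_before)) gap_before <- cyc - gap_after  # leading-edge beat
      labels[gx] <- if (s3s4_rule == "priors") {
        if (gap_before < gap_after) "S3" else "S4"
      } else {
        if (gap_before < gap_after) "S4" else "S3"
      }

    } else if (nb == 4L) {
      low2 <- sort(order(avg_freqs[idx])[1:2])  # time order of the two lowest
      s3 <- low2[1L]; s4 <- low2[2L]
      labels[idx[s3]] <- "S3"
      labels[idx[s4]] <- "S4"
      if (s3 > 1L) labels[idx[s3 - 1L]] <- "S2"
      rest <- which(labels[idx] == "unknown")
      if (length(rest) == 1L)
        labels[idx[rest]] <- setdiff(c("S1", "S2"), labels[idx])
    }
    # per-beat labels must be distinct; degrade the beat on any collision
    lab_b <- labels[idx]
    if (anyDuplicated(lab_b[lab_b != "unknown"])) labels[idx] <- "unknown"
  }
  labels
}

#' Build the final segmentation
#'
#' Assembles labelled components and the named inter-component intervals
#' (S1S2, S2S1, S2S3, S3S1, S2S4, S4S1, ...) between consecutive labelled
#' components; components labelled "unknown" do not contribute intervals.
#'
#' @param bs The final [boundary_set()].
#' @param labels Per-component labels from [recognize_components()].
#' @param avg_freqs Per-component average frequencies (Hz).
#' @param beats Beat grouping from [group_into_beats()] (used for the beat
#'   index column); may be `NULL`.
#' @param cycle A `cycle_estimate` or `NULL` when estimation failed.
#' @param fs Sampling rate in Hz.
#' @return A list of class `pcg_segmentation` with `components` (data frame:
#'   beat, label, onset/offset samples and seconds, avg_freq_hz), `intervals`
#'   (data frame: name, from/to component rows, duration_s), `cycle`.
#' @export
build_segmentation <- function(bs, labels, avg_freqs, beats = NULL,
                               cycle = NULL, fs = 2000) {
  beat_of <- rep(NA_integer_, bs$m)
  if (!is.null(beats)) {
    for (b in seq_along(beats)) beat_of[beats[[b]]$components] <- b
  }
  comps <- data.frame(beat = beat_of,
                      label = labels,
                      onset_sample = bs$onset,
                      offset_sample = bs$offset,
                      onset_s = bs$onset / fs,
                      offset_s = bs$offset / fs,
                      avg_freq_hz = if (length(avg_freqs)) avg_freqs
                                    else rep(NA_real_, bs$m),
                      stringsAsFactors = FALSE)
  ints <- data.frame(name = character(0), from = integer(0), to = integer(0),
                     duration_s = numeric(0), stringsAsFactors = FALSE)
  if (bs$m >= 2L) {
    for (k in seq_len(bs$m - 1L)) {
      if (labels[k] == "unknown" || labels[k + 1L] == "unknown") next
      ints <- rbind(ints, data.frame(
        name = paste0(labels[k], labels[k + 1L]),
        from = k, to = k + 1L,
        duration_s = (bs$onset[k + 1L] - bs$offset[k]) / fs,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(components = comps, intervals = ints, cycle = cycle),
            class = "pcg_segmentation")
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  n <- nrow(x$components)
  lab <- table(x$components$label)
  cat(sprintf("<pcg_segmentation> %d component(s): %s\n", n,
              paste(sprintf("%s=%d", names(lab), lab), collapse = ", ")))
  if (!is.null(x$cycle) && inherits(x$cycle, "cycle_estimate"))
    cat(sprintf("  cycle: %.3f s\n", x$cycle$avg_cycle_s))
  invisible(x)
}

#' Convert a segmentation to an annotation table
#'
#' @param seg A `pcg_segmentation`.
#' @param fs Sampling rate in Hz.
#' @return An annotation `data.frame` (see [annotations()]).
#' @export
segmentation_to_annotations <- function(seg, fs = 2000) {
  annotations(seg$components$label,
              seg$components$onset_sample,
              seg$components$offset_sample,
              fs = fs)
}
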