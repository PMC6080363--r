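# 1-D mathematical morphology with a flat (zero-valued) structuring element.
# With a flat element, dilation is a windowed maximum and erosion a windowed
# minimum; windows are centered with radius floor(Q/2) and shrink to the valid
# samples at the edges, so the output keeps the input length with no phase
# shift.

#' Morphological dilation and erosion
#'
#' @param x Numeric vector.
#' @param q Structuring-element length (>= 1); the effective centered window
#'   has radius `floor(q / 2)`.
#' @return Numeric vector of the same length.
#' @export
morph_dilate <- function(x, q) {
  if (q < 1) stop("structuring element length must be >= 1", call. = FALSE)
  running_extreme(x, floor(q / 2), pmax, -Inf)
}

#' @rdname morph_dilate
#' @export
morph_erode <- function(x, q) {
  if (q < 1) stop("structuring element length must be >= 1", call. = FALSE)
  running_extreme(x, floor(q / 2), pmin, Inf)
}

#' Morphological closing and opening
#'
#' Closing (dilation followed by erosion) fills valleys narrower than the
#' structuring element and is extensive (`output >= input`); opening (erosion
#' followed by dilation) removes positive spikes narrower than the element and
#' is anti-extensive (`output <= input`). Both are idempotent.
#'
#' @param x Numeric vector (for envelope extraction, the rectified signal).
#' @param q Structuring-element length in samples.
#' @return Numeric vector of the same length.
#' @export
morph_close <- function(x, q) morph_erode(morph_dilate(x, q), q)

#' @rdname morph_close
#' @export
morph_open <- function(x, q) morph_dilate(morph_erode(x, q), q)
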