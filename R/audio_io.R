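#' Audio signal container
#'
#' A single-channel sampled waveform. All heart-sound processing in this
#' package operates on `audio_signal` objects: the raw recording, the
#' preprocessed/normalized signal, and the murmur-reduced signal are all
#' carried in this container.
#'
#' @param samples Numeric vector of finite amplitudes (dimensionless).
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_signal` with fields `samples` and `fs`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), fs = 100)
#' s
#' @export
audio_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("audio signal must contain at least one sample", call. = FALSE)
  if (!all(is.finite(samples))) stop("audio samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs)), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), peak %.4g\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              max(abs(x$samples))))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

as_audio_signal <- function(x, fs = NULL) {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(fs)) stop("fs is required when passing a plain numeric vector", call. = FALSE)
  audio_signal(x, fs)
}

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for PCM (16/24/32-bit) and IEEE float32 encodings.
#' Integer PCM is rescaled to `[-1, 1]` by dividing by the full-scale value
#' (e.g. 32768 for 16-bit), so a full-scale positive 16-bit sample reads as
#' 32767/32768. Multi-channel files are reduced to channel 0 with a warning;
#' heart-sound recordings are assumed to be single-channel.
#'
#' @param path Path to an existing `.wav` file.
#' @return An [audio_signal].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels  = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        fs        = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path, call. = FALSE)
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; sub-format assumed PCM/float per `bits`.
  if (!fmt$format %in% c(1L, 3L, 65534L))
    stop("unsupported WAV encoding (format tag ", fmt$format, ")", call. = FALSE)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  if (n_total == 0L) stop("zero-length audio in ", path, call. = FALSE)
  if (fmt$format == 3L) {
    x <- readBin(data_raw, "numeric", n_total, size = 4, endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_total, size = 2, endian = "little") / 32768
  } else if (fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n_total, size = 4, endian = "little") / 2147483648
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
  }
  if (fmt$channels > 1L) {
    warning("multi-channel WAV: using channel 0 only", call. = FALSE)
    x <- x[seq(1L, length(x), by = fmt$channels)]
  }
  if (!length(x)) stop("zero-length audio in ", path, call. = FALSE)
  audio_signal(x, fmt$fs)
}

#' Write a WAV file
#'
#' @param signal An [audio_signal]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @param bits Either 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16L) {
  signal <- as_audio_signal(signal)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32", call. = FALSE)
  x <- pmin(pmax(signal$samples, -1), 1)
  n <- length(x)
  bytes <- bits %/% 8L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(round(signal$fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(signal$fs) * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(pmin(pmax(round(x * 32768), -32768), 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

component_labels <- c("S1", "S2", "S3", "S4")
annotation_labels <- c(component_labels, "unknown", "murmur")

#' Build an annotation table
#'
#' Annotations mark labelled spans of a recording with sample-accurate
#' boundaries. Sample indices are 0-based (so `onset_s == onset_sample / fs`
#' exactly); times are in seconds. Component annotations (S1-S4/unknown) must
#' be sorted by onset and non-overlapping.
#'
#' @param label Character vector drawn from S1, S2, S3, S4, unknown, murmur.
#' @param onset_sample,offset_sample Integer 0-based sample indices,
#'   `onset_sample < offset_sample`.
#' @param fs Sampling rate of the annotated recording (Hz).
#' @return A `data.frame` with columns `label`, `onset_sample`,
#'   `offset_sample`, `onset_s`, `offset_s`.
#' @export
annotations <- function(label = character(), onset_sample = integer(),
                        offset_sample = integer(), fs = 2000) {
  label <- as.character(label)
  onset_sample <- as.integer(onset_sample)
  offset_sample <- as.integer(offset_sample)
  if (length(label) != length(onset_sample) || length(label) != length(offset_sample))
    stop("label, onset_sample and offset_sample must have equal length", call. = FALSE)
  ann <- data.frame(label = label,
                    onset_sample = onset_sample,
                    offset_sample = offset_sample,
                    onset_s = onset_sample / fs,
                    offset_s = offset_sample / fs,
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  if (!nrow(ann)) return(invisible(ann))
  if (!all(ann$label %in% annotation_labels))
    stop("invalid annotation label(s): ",
         paste(setdiff(ann$label, annotation_labels), collapse = ", "), call. = FALSE)
  if (any(ann$offset_sample <= ann$onset_sample))
    stop("annotation offset must be greater than onset", call. = FALSE)
  comp <- ann[ann$label %in% c(component_labels, "unknown"), , drop = FALSE]
  if (nrow(comp) > 1L) {
    o <- order(comp$onset_sample)
    comp <- comp[o, ]
    if (any(diff(comp$onset_sample) < 0))
      stop("component annotations must be sorted by onset", call. = FALSE)
    if (any(comp$onset_sample[-1L] < comp$offset_sample[-nrow(comp)]))
      stop("component annotations must not overlap", call. = FALSE)
  }
  invisible(ann)
}

#' Write / read annotations
#'
#' JSON (a list of objects, one per annotation) is the canonical on-disk
#' format; CSV with header `label,onset_sample,offset_sample,onset_s,offset_s`
#' is written when `path` ends in `.csv`. Round-trips are lossless for
#' `label`, `onset_sample` and `offset_sample`.
#'
#' @param ann Annotation `data.frame` (see [annotations()]).
#' @param path Output (input) file path; format chosen by extension.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns the annotation `data.frame`.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(ann, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  if (!nrow(ann)) {
    ann <- annotations()
  } else {
    need <- c("label", "onset_sample", "offset_sample", "onset_s", "offset_s")
    if (!all(need %in% names(ann)))
      stop("malformed annotation file (missing columns): ", path, call. = FALSE)
    ann <- ann[, need]
    ann$onset_sample <- as.integer(ann$onset_sample)
    ann$offset_sample <- as.integer(ann$offset_sample)
    validate_annotations(ann)
  }
  ann
}
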