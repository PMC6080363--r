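test_that("WAV write/read round-trips a known waveform", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(rep(0, 8000), 8000), path)
  s <- read_wav(path)
  expect_equal(s$fs, 8000)
  expect_length(s$samples, 8000)
  expect_true(all(s$samples == 0))

  # 16-bit full-scale square wave: +1 clips to 32767/32768, -1 is exact
  sq <- audio_signal(rep(c(1, -1), 100), 2000)
  write_wav(sq, path, bits = 16L)
  r <- read_wav(path)
  expect_equal(sort(unique(r$samples)), c(-1, 32767 / 32768))

  # float32 round-trip preserves values to single precision
  x <- sin(2 * pi * 7 * (0:499) / 500) * 0.5
  write_wav(audio_signal(x, 4000), path, bits = 32L)
  rf <- read_wav(path)
  expect_equal(rf$samples, x, tolerance = 1e-6)
})

test_that("stereo WAV reduces to channel 0 with a warning", {
  path <- withr::local_tempfile(fileext = ".wav")
  ch0 <- as.integer(round(sin(2 * pi * (0:99) / 25) * 10000))
  ch1 <- rep(0L, 100)
  inter <- as.vector(rbind(ch0, ch1))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(inter) * 2), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  expect_warning(s <- read_wav(path), "channel 0")
  expect_equal(s$samples, ch0 / 32768)
})

test_that("read_wav raises distinct errors for bad inputs", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "not found")
  path <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav", path)
  expect_error(read_wav(path), "RIFF")
})

test_that("annotation JSON and CSV round-trips are lossless", {
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    empty <- annotations()
    write_annotations(empty, path)
    expect_equal(nrow(read_annotations(path)), 0L)

    one <- annotations("S1", 100, 300, fs = 2000)
    write_annotations(one, path)
    expect_equal(read_annotations(path), one)

    withr::with_seed(42, {
      for (n in c(1, 5, 20)) {
        ann <- random_annotations(n)
        write_annotations(ann, path)
        expect_equal(read_annotations(path), ann)
      }
    })
  }
})

test_that("invalid annotations are rejected", {
  expect_error(annotations("S1", 300, 100, fs = 2000), "greater than onset")
  expect_error(annotations(c("S1", "S2"), c(0, 50), c(100, 150), fs = 2000),
               "overlap")
  expect_error(annotations("S9", 0, 10, fs = 2000), "label")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"label":"S1","onset_sample":300,"offset_sample":100,"onset_s":0.15,"offset_s":0.05}]',
             path)
  expect_error(read_annotations(path), "greater than onset")
})
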