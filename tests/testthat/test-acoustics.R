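test_that("peak frequency nails pure tones, mixtures and degenerate segments", {
  fs <- 44100
  t <- seq_len(fs / 2) / fs  # 0.5 s
  expect_lt(abs(as.numeric(peak_frequency(sin(2 * pi * 1000 * t), fs)) - 1000), 2)

  mix <- sin(2 * pi * 1000 * t) + 0.5 * sin(2 * pi * 2000 * t)
  expect_lt(abs(as.numeric(peak_frequency(mix, fs)) - 1000), 2)

  expect_equal(as.numeric(peak_frequency(rep(0.7, 512), fs)), 0)  # DC
  expect_true(is.na(peak_frequency(rep(0, 100), fs)))             # silent
  expect_error(peak_frequency(1, fs), ">= 2 samples")
})

test_that("peak frequency is invariant to amplitude and phase", {
  fs <- 22050
  t <- seq_len(4096) / fs
  base <- as.numeric(peak_frequency(sin(2 * pi * 730 * t), fs))
  scaled <- as.numeric(peak_frequency(0.01 * sin(2 * pi * 730 * t), fs))
  shifted <- as.numeric(peak_frequency(sin(2 * pi * 730 * t + 1.1), fs))
  expect_equal(scaled, base, tolerance = 1e-6)
  expect_lt(abs(shifted - base), 1)
})

test_that("the band limit suppresses low-frequency noise when asked", {
  fs <- 22050
  t <- seq_len(8192) / fs
  seg <- 2 * sin(2 * pi * 30 * t) + sin(2 * pi * 900 * t)  # rumble + call
  expect_lt(abs(as.numeric(peak_frequency(seg, fs, fmin = 0)) - 30), 5)
  expect_lt(abs(as.numeric(peak_frequency(seg, fs, fmin = 100)) - 900), 5)
})

test_that("recording summaries average element peaks per recording and species", {
  spectra <- data.frame(
    recording_id = c("r1", "r1", "r1", "r2"),
    species = c("a", "a", "a", "a"),
    peak_hz = c(1000, 1010, 990, 1234))
  s <- summarize_recordings(spectra)
  expect_equal(s$mean_peak_hz[s$recording_id == "r1"], 1000)
  expect_equal(s$n_elements[s$recording_id == "r1"], 3)
  expect_equal(s$mean_peak_hz[s$recording_id == "r2"], 1234)  # single element
})

test_that("Mann-Whitney p equals exhaustive rank enumeration for small layouts", {
  # canonical case: {1,2} vs {3,4} -> U = 0, exact two-tailed p = 1/3
  spectra <- data.frame(recording_id = "r", species = rep(c("a", "b"), each = 2),
                        onset_s = c(0, 1, 2, 3), offset_s = c(0.5, 1.5, 2.5, 3.5),
                        peak_hz = c(1, 2, 3, 4))
  ct <- compare_chorus(spectra)
  expect_equal(ct$method, "mann-whitney")
  expect_equal(ct$p, 1 / 3)
  expect_equal(mw_exact_p(c(1, 2), c(3, 4)), 1 / 3)

  set.seed(14)
  for (nx in 2:4) {
    for (ny in 2:4) {
      x <- sample(seq(1, 100, by = 1), nx)
      y <- sample(setdiff(seq(1, 100, by = 1), x), ny)
      spectra <- data.frame(
        recording_id = "r",
        species = rep(c("a", "b"), c(nx, ny)),
        onset_s = seq_len(nx + ny), offset_s = seq_len(nx + ny) + 0.4,
        peak_hz = c(x, y))
      expect_equal(compare_chorus(spectra)$p, mw_exact_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("ANOVA route reports capped Bonferroni p for identical groups", {
  set.seed(15)
  vals <- rnorm(10)
  spectra <- data.frame(
    recording_id = "r", species = rep(c("a", "b", "c"), each = 10),
    onset_s = seq_len(30), offset_s = seq_len(30) + 0.4,
    peak_hz = rep(vals, 3) + 1000)
  ct <- compare_chorus(spectra)
  expect_equal(ct$method, "anova+bonferroni")
  expect_lt(ct$statistic, 1e-10)
  expect_equal(ct$pairs$p_adj, rep(1, 3))
  expect_true(all(ct$pairs$p_adj >= ct$pairs$p_raw))
})

test_that("widely separated species are all declared distinct", {
  set.seed(16)
  mus <- c(800, 1600, 2400)  # ~10 pooled sd apart at sd 80
  spectra <- data.frame(
    recording_id = "r", species = rep(c("a", "b", "c"), each = 20),
    onset_s = seq_len(60), offset_s = seq_len(60) + 0.4,
    peak_hz = rep(mus, each = 20) + rnorm(60, 0, 80))
  ct <- compare_chorus(spectra)
  expect_lt(ct$p, 0.01)
  expect_true(all(ct$pairs$p_adj < 0.01))
})

test_that("overlapping elements and under-sampled species are handled", {
  spectra <- data.frame(recording_id = "r", species = c("a", "b"),
                        onset_s = c(0, 0.2), offset_s = c(0.5, 0.7),
                        peak_hz = c(500, 900))
  expect_error(compare_chorus(spectra), "overlap in time")

  spectra <- data.frame(
    recording_id = "r", species = c("a", "a", "a", "b", "b", "c"),
    onset_s = 0:5, offset_s = 0:5 + 0.4,
    peak_hz = c(500, 510, 490, 900, 910, 1400))
  expect_warning(ct <- compare_chorus(spectra), "excluding species")
  expect_equal(ct$method, "mann-whitney")
  expect_equal(ct$excluded, "c")
})
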