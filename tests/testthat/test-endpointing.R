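test_that("EMD reconstructs its input and isolates a pure tone", {
  x <- as.numeric(tone(100, dur_s = 1, sr = 8000))
  d <- emd(x)
  recon <- Reduce(`+`, d$imfs, accumulate = FALSE) + d$residual
  expect_lt(sqrt(sum((recon - x)^2) / sum(x^2)), 1e-8)
  expect_gt(abs(cor(d$imfs[[1]], x)), 0.99)
})

test_that("the first IMF captures the fastest oscillation of a mixture", {
  sr <- 8000
  t <- seq_len(sr) / sr
  x <- sin(2 * pi * 50 * t) + 0.8 * sin(2 * pi * 500 * t)
  d <- emd(x)
  sp <- Mod(fft(d$imfs[[1]]))[1:(sr %/% 2)]
  peak_hz <- which.max(sp) - 1
  expect_lt(abs(peak_hz - 500) / 500, 0.1)
})

test_that("IMFs satisfy the extrema/zero-crossing acceptance rule", {
  set.seed(5)
  x <- as.numeric(generate_vocalization(default_class_specs()$howling,
                                        8000, seed = 5)$audio)
  d <- emd(x, max_imfs = 6L)
  for (im in d$imfs) {
    ext <- pigvoc:::find_extrema(im)
    zc <- sum(diff(sign(ifelse(im == 0, .Machine$double.eps, im))) != 0)
    expect_lte(abs(length(ext$max) + length(ext$min) - zc), 1L)
  }
})

test_that("signals with too few extrema return as residual", {
  d <- emd(seq(0, 1, length.out = 100))
  expect_length(d$imfs, 0)
  expect_equal(d$residual, seq(0, 1, length.out = 100))
})

test_that("Teager energy obeys its closed forms", {
  expect_true(all(teager_energy(rep(0.7, 50)) == 0))
  # A cos(wn): psi = A^2 sin(w)^2 everywhere
  A <- 0.8; w <- 0.31
  psi <- teager_energy(A * cos(w * (0:999)))
  expect_lt(max(abs(psi - A^2 * sin(w)^2)), 1e-9)
  # alternating +-A is the w = pi case: psi = 0
  psi2 <- teager_energy(rep(c(0.5, -0.5), 50))
  expect_lt(max(abs(psi2)), 1e-12)
  expect_error(teager_energy(c(1, 2)), "3 samples")
})

test_that("cepstral distance ignores gain and phase but sees spectrum", {
  sr <- 8000
  set.seed(9)
  noise <- rnorm(sr) * 0.05
  # non-overlapping frames of a frame-periodic signal are all identical
  # to the reference mean: zero distance
  d0 <- short_time_cepstral_distance(rep(noise[1:160], 50), hop_s = 0.02,
                                     sample_rate = sr)
  expect_lt(max(d0), 1e-8)
  # phase shift leaves the magnitude cepstrum unchanged
  a <- as.numeric(tone(500, 0.1, sr, phase = 0))
  b <- as.numeric(tone(500, 0.1, sr, phase = 1.1))
  ca <- short_time_cepstral_distance(c(noise[1:800], a), sample_rate = sr,
                                     n_noise_frames = 4L)
  cb <- short_time_cepstral_distance(c(noise[1:800], b), sample_rate = sr,
                                     n_noise_frames = 4L)
  expect_equal(tail(ca, 3), tail(cb, 3), tolerance = 0.05)
  # a harmonic frame sits far from a white-noise reference
  harm <- as.numeric(tone(500, 0.5, sr, amp = 0.5))
  dh <- short_time_cepstral_distance(c(noise, harm), sample_rate = sr)
  expect_gt(mean(tail(dh, 10)), 3 * mean(head(dh, 10)))
})

test_that("a single centered burst is found with tight boundaries", {
  cl <- generate_vocalization(default_class_specs()$howling, 16000,
                              seed = 21, snr_db = 12)
  segs <- detect_endpoints(cl$audio)
  expect_equal(nrow(segs), 1)
  # the onset is sharp (20 ms attack); the offset fades over 30 ms, so its
  # detectable edge is correspondingly looser
  expect_lt(abs(segs$start[1] - cl$true_segments$start[1]), 0.03 * 16000)
  expect_lt(abs(segs$end[1] - cl$true_segments$end[1]), 0.045 * 16000)
})

test_that("two separated bursts give two ordered non-overlapping segments", {
  sr <- 16000
  c1 <- generate_vocalization(default_class_specs()$howling, sr,
                              seed = 31, snr_db = 15)
  c2 <- generate_vocalization(default_class_specs()$estrus, sr,
                              seed = 32, snr_db = 15)
  x <- audio_signal(c(as.numeric(c1$audio), as.numeric(c2$audio)), sr)
  segs <- detect_endpoints(x)
  expect_equal(nrow(segs), 2)
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$end[-nrow(segs)] <= segs$start[-1]))
})

test_that("silence yields no segments", {
  set.seed(2)
  x <- audio_signal(rnorm(16000, sd = 1e-3), 16000)
  segs <- detect_endpoints(x)
  expect_equal(nrow(segs), 0)
})

test_that("segments are sorted, disjoint and in bounds on arbitrary input", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(4000:20000, 1)
    x <- audio_signal(pmin(1, pmax(-1, rnorm(n, sd = 0.1) *
      (1 + sin(2 * pi * seq_len(n) / n * sample(1:5, 1))))), 8000)
    segs <- detect_endpoints(x)
    if (nrow(segs) == 0) succeed() else {
      expect_true(all(segs$start >= 0))
      expect_true(all(segs$end <= n))
      expect_true(all(segs$end > segs$start))
      if (nrow(segs) > 1)
        expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
    }
  }
})

test_that("doubling the waveform does not move the detected segments", {
  cl <- generate_vocalization(default_class_specs()$eating, 16000,
                              seed = 55, snr_db = 12)
  s1 <- detect_endpoints(cl$audio)
  s2 <- detect_endpoints(audio_signal(pmin(1, pmax(-1,
    1.5 * as.numeric(cl$audio))), 16000))
  expect_equal(s1$start, s2$start)
  expect_equal(s1$end, s2$end)
})
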