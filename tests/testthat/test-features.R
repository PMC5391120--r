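make_sine_recording <- function(freq, fs = 1000, dur_s = 12, onsets = 5000L) {
  t <- seq(0, dur_s, by = 1 / fs)[-1]
  continuous_recording(
    matrix(sin(2 * pi * freq * t), 1, length(t)),
    fs, onsets, "Cz"
  )
}

rms <- function(x) sqrt(mean(x^2))

test_that("the band-pass keeps the ERP band and rejects out-of-band power", {
  cfg <- feature_config()
  # 20 Hz is deep in the stopband
  rec20 <- make_sine_recording(20)
  out20 <- preprocess(rec20, cfg)
  expect_lt(
    rms(out20$samples[1, -(1:200)]),
    0.1 * rms(rec20$samples[1, ])
  )
  # 4 Hz is in the passband (after the filter transient)
  rec4 <- make_sine_recording(4)
  out4 <- preprocess(rec4, cfg)
  expect_equal(
    rms(out4$samples[1, -(1:200)]),
    rms(rec4$samples[1, ]),
    tolerance = 0.25
  )
  # DC is in the stopband of the high-pass edge
  rec_dc <- continuous_recording(matrix(1, 1, 12000), 1000, 5000L, "Cz")
  out_dc <- preprocess(rec_dc, cfg)
  expect_lt(rms(out_dc$samples[1, -(1:400)]), 0.02)
  # onsets are re-indexed onto the 100 Hz grid
  expect_equal(out20$onsets, 500L)
  expect_equal(out20$rate, 100)

  expect_error(
    preprocess(rec20, feature_config(target_rate = 300)),
    "does not divide"
  )
  rec_slow <- continuous_recording(matrix(rnorm(200), 1, 200), 10, 100L)
  expect_error(preprocess(rec_slow, cfg), "Nyquist")
})

test_that("epoch extraction windows, baselines and overlaps behave", {
  fs <- 100
  n <- 2000
  set.seed(55)
  x <- matrix(rnorm(3 * n), 3, n)
  onsets <- c(500L, 525L) # 250 ms apart at 100 Hz
  rec <- continuous_recording(x, fs, onsets, c("O1", "Cz", "Pz"))
  cfg <- feature_config()
  ew <- extract_epochs(rec, cfg)
  # [-200, 700) ms at 100 Hz is 90 samples
  expect_equal(dim(ew$data), c(2, 3, 90))
  expect_equal(ew$times[1], -200)
  expect_equal(ew$times[90], 690)
  # baseline mean is zero per epoch and channel
  bl <- ew$times >= -200 & ew$times < 0
  expect_equal(sum(bl), 20)
  bl_means <- apply(ew$data[, , bl], c(1, 2), mean)
  expect_lt(max(abs(bl_means)), 1e-9)
  # baseline correction is idempotent
  ew2 <- baseline_correct(ew, cfg)
  expect_equal(ew2$data, ew$data, tolerance = 1e-12)
  # events 250 ms apart share signal: window 2 re-reads window 1's samples
  raw <- extract_epochs(rec, cfg, baseline = FALSE)
  expect_equal(unname(raw$data[2, , 1:(90 - 25)]), unname(x[, (525 - 20):(500 + 69)]))
  # an event too close to the edge is reported by index
  expect_error(
    extract_epochs(continuous_recording(x, fs, c(10L, 500L)), cfg),
    "event 1"
  )
})

test_that("interval means give the 174-feature study layout", {
  fs <- 100
  cfg <- feature_config()
  ch <- default_channels()
  set.seed(66)
  x <- matrix(rnorm(length(ch) * 5000), length(ch), 5000)
  rec <- continuous_recording(x, fs, c(1000L, 1500L, 2000L), ch)
  ew <- extract_epochs(rec, cfg)
  feats <- interval_means(ew, cfg)
  expect_equal(dim(feats), c(3, 174)) # 29 channels x 6 intervals
  expect_false("Fp1" %in% sub("_.*", "", colnames(feats)))
  # channel-major ordering: first six features belong to one channel
  expect_equal(length(unique(sub("_.*", "", colnames(feats)[1:6]))), 1)

  # constant epoch: all features equal the constant before baselining
  rec_c <- continuous_recording(
    matrix(3, 2, 3000), fs, 1000L, c("O1", "Cz")
  )
  ew_c <- extract_epochs(rec_c, cfg, baseline = FALSE)
  f_c <- interval_means(ew_c, cfg, channels = c("O1", "Cz"))
  expect_true(all(abs(f_c - 3) < 1e-12))
  # and zero after baselining
  f_c0 <- interval_means(extract_epochs(rec_c, cfg), cfg,
    channels = c("O1", "Cz")
  )
  expect_true(all(abs(f_c0) < 1e-12))

  # linear ramp: each feature is the ramp value at the interval midpoint
  ramp <- matrix(seq_len(3000), 1, 3000)
  rec_r <- continuous_recording(ramp, fs, 1000L, "Cz")
  ew_r <- extract_epochs(rec_r, cfg, baseline = FALSE)
  f_r <- interval_means(ew_r, cfg, channels = "Cz")
  for (k in seq_along(cfg$intervals)) {
    iv <- cfg$intervals[[k]]
    sel <- ew_r$times >= iv[1] & ew_r$times <= iv[2]
    mid <- mean(ew_r$times[sel])
    expect_equal(unname(f_r[1, k]), 1000 + mid / 10, tolerance = 1e-9)
  }
  # the six intervals tile the post-onset samples of the half-open
  # [-200, 700) ms window from 50 ms on, without overlap at 100 Hz
  covered <- unlist(lapply(cfg$intervals, function(iv) {
    ew_r$times[ew_r$times >= iv[1] & ew_r$times <= iv[2]]
  }))
  expect_equal(sort(covered), seq(50, 690, by = 10))
  expect_equal(anyDuplicated(covered), 0)
})

test_that("feature extraction is linear in the input signal", {
  fs <- 100
  cfg <- feature_config()
  set.seed(67)
  xa <- matrix(rnorm(2 * 2000), 2, 2000)
  xb <- matrix(rnorm(2 * 2000), 2, 2000)
  mk <- function(x) {
    continuous_recording(x, fs, c(600L, 900L), c("O1", "Cz"))
  }
  fx <- function(x) {
    interval_means(extract_epochs(mk(x), cfg), cfg, channels = c("O1", "Cz"))
  }
  expect_equal(fx(2 * xa - 3 * xb), 2 * fx(xa) - 3 * fx(xb),
    tolerance = 1e-10
  )
})

test_that("peak statistics find extrema with earliest-time tie-breaks", {
  fs <- 100
  t_ms <- seq(-200, 690, by = 10)
  trough <- -8 * exp(-(t_ms - 150)^2 / (2 * 25^2))
  bump <- 2 * exp(-(t_ms - 400)^2 / (2 * 60^2))
  wf <- rbind(O1 = trough, Cz = bump)
  p1 <- peak_statistics(wf, t_ms, "O1", c(100, 200), mode = "min")
  expect_equal(p1$amplitude, -8, tolerance = 1e-6)
  expect_equal(p1$latency, 150)
  p2 <- peak_statistics(wf, t_ms, "Cz", c(250, 500), mode = "max")
  expect_equal(p2$amplitude, 2, tolerance = 1e-6)
  expect_equal(p2$latency, 400)
  # constant waveform: amplitude is the constant, latency the interval start
  wc <- rbind(Cz = rep(1.5, length(t_ms)))
  pc <- peak_statistics(wc, t_ms, "Cz", c(100, 200), mode = "min")
  expect_equal(pc$amplitude, 1.5)
  expect_equal(pc$latency, 100)
  expect_error(
    peak_statistics(wf, t_ms, "Fz", c(100, 200)),
    "not present"
  )
})

test_that("recordings round-trip through the binary container", {
  set.seed(71)
  rec <- continuous_recording(
    matrix(rnorm(400), 4, 100), 100, c(30L, 60L),
    c("O1", "Oz", "O2", "Cz")
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(unname(back$samples), unname(rec$samples))
  expect_equal(back$onsets, rec$onsets)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$rate, rec$rate)
})
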