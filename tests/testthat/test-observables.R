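test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 200
  t <- (0:(fs * 20 - 1)) / fs
  tone10 <- sin(2 * pi * 10 * t)
  amp <- function(x) diff(range(x[(2 * fs):(18 * fs)])) / 2
  in_band <- bandpass(tone10, fs, eeg_bands("alpha"))
  expect_gt(amp(in_band), 0.9)
  out_band <- bandpass(tone10, fs, eeg_bands("delta"))
  expect_lt(amp(out_band), 0.1)
  expect_error(bandpass(tone10, fs, c(8, 150)), "Nyquist")
})

test_that("filtered white noise concentrates its energy inside the band", {
  fs <- 200
  set.seed(5)
  x <- rnorm(fs * 60)
  y <- bandpass(x, fs, eeg_bands("alpha"))
  psd <- welch_psd(y, fs)
  total <- sum(psd$power)
  inside <- sum(psd$power[psd$freq >= 8 & psd$freq <= 13])
  expect_gt(inside / total, 0.8)
})

test_that("envelope tracks a slow amplitude modulation and is DC-free after high-pass", {
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  a_t <- 1 + 0.5 * sin(2 * pi * 1 * t)
  x <- a_t * sin(2 * pi * 10 * t)
  raw <- envelope(x, fs, highpass = NULL)
  core <- (5 * fs):(55 * fs)
  expect_equal(raw[core], a_t[core], tolerance = 0.05)
  hp <- envelope(x, fs)
  expect_lt(abs(mean(hp[core])), 0.02)
})

test_that("envelope FC is 1 for duplicated channels and near 0 for independent noise", {
  fs <- 100
  set.seed(7)
  x <- rnorm(fs * 60)
  dup <- cbind(x, x)
  fc <- envelope_fc(dup, fs, eeg_bands("alpha"))
  expect_equal(fc[1, 2], 1, tolerance = 1e-10)
  expect_equal(diag(unclass(fc)), c(1, 1), ignore_attr = TRUE)
  ind <- cbind(rnorm(fs * 60), rnorm(fs * 60))
  fc2 <- envelope_fc(ind, fs, eeg_bands("alpha"))
  expect_lt(abs(fc2[1, 2]), 0.1)
  # shared slow modulation on independent carriers couples the envelopes
  t <- (0:(fs * 60 - 1)) / fs
  mod <- 1 + 0.8 * sin(2 * pi * 0.7 * t + 0.3)
  pair <- cbind(mod * sin(2 * pi * 10 * t), mod * sin(2 * pi * 11 * t))
  fc3 <- envelope_fc(pair, fs, eeg_bands("alpha"))
  expect_gt(fc3[1, 2], 0.8)
  expect_error(envelope_fc(cbind(x, rep(1, length(x))), fs, eeg_bands("alpha")),
               "constant")
})

test_that("BOLD FC handles duplicated, sign-flipped and independent regions", {
  tr <- 2.08
  set.seed(9)
  n <- 300   # 624 s
  base <- as.numeric(stats::filter(rnorm(n), rep(1 / 5, 5), sides = 1))
  base[is.na(base)] <- 0
  x <- cbind(base, base, -base, rnorm(n))
  fc <- bold_fc(x, tr)
  expect_equal(fc[1, 2], 1, tolerance = 1e-10)
  expect_equal(fc[1, 3], -1, tolerance = 1e-10)
  expect_lt(abs(fc[1, 4]), 0.35)
  expect_true(isSymmetric(unclass(fc)))
  expect_error(bold_fc(x[1:50, ], tr), "too short")
})

test_that("Welch PSD localises tones at 0.5 Hz resolution", {
  fs <- 200
  t <- (0:(fs * 30 - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(psd$freq[2] - psd$freq[1], 0.5)
  expect_equal(psd$freq[which.max(psd$power)], 10)
  two <- welch_psd(sin(2 * pi * 10 * t) + sin(2 * pi * 45 * t), fs)
  pk <- order(two$power, decreasing = TRUE)[1:2]
  expect_setequal(two$freq[pk], c(10, 45))
  # white-noise flatness improves with length (coefficient of variation)
  set.seed(1)
  cv <- function(sec) {
    p <- welch_psd(rnorm(fs * sec), fs)$power
    keep <- p[-c(1, length(p))]
    sd(keep) / mean(keep)
  }
  expect_lt(cv(240), cv(15))
})

test_that("normalised PSD has unit maximum and is scale invariant", {
  fs <- 200
  t <- (0:(fs * 10 - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t) + 0.2 * rnorm(length(t)), fs)
  n1 <- normalized_psd(psd)
  expect_equal(max(n1$power), 1)
  psd7 <- psd; psd7$power <- psd$power * 7
  expect_equal(normalized_psd(psd7)$power, n1$power)
  # tie preservation
  tie <- structure(list(freq = c(1, 2, 3), power = c(2, 1, 2)), class = "psd")
  expect_equal(normalized_psd(tie)$power, c(1, 0.5, 1))
})

test_that("relative band power normalises over the tiling bands", {
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t) + 0.05 * rnorm(length(t)), fs)
  rp <- relative_band_power(psd, eeg_bands())
  expect_equal(sum(rp), 1, tolerance = 1e-6)
  expect_gt(rp[["alpha"]], 0.9)
  # a 20 Hz tone loads the beta entry of the theta/alpha/beta vector
  psd20 <- welch_psd(sin(2 * pi * 20 * t), fs)
  rp3 <- relative_band_power(psd20, eeg_bands(c("theta", "alpha", "beta")))
  expect_gt(rp3[["beta"]], 0.95)
  expect_lt(rp3[["theta"]] + rp3[["alpha"]], 0.05)
})

test_that("dominant frequency finds spectral peaks and breaks ties downward", {
  fs <- 200
  t <- (0:(fs * 30 - 1)) / fs
  psd45 <- welch_psd(sin(2 * pi * 45 * t), fs)
  expect_equal(dominant_frequency(psd45), 45)
  # constructed 1/f background plus alpha bump
  f <- seq(0.5, 60, by = 0.5)
  p <- 1 / f + 3 * exp(-(f - 10)^2 / 2)
  psd <- structure(list(freq = f, power = p), class = "psd")
  expect_equal(dominant_frequency(psd, range = c(2, 60)), 10)
  tie <- structure(list(freq = c(5, 10, 15), power = c(1, 0.5, 1)),
                   class = "psd")
  expect_equal(dominant_frequency(tie, range = c(0, 20)), 5)
})
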