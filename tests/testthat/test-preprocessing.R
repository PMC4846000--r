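sin_session <- function(freqs_hz, amps, n = 24000, fs = 1200) {
  t <- seq_len(n) / fs
  x <- rep(0, n)
  for (i in seq_along(freqs_hz)) x <- x + amps[i] * sin(2 * pi * freqs_hz[i] * t)
  data_session(matrix(rep(x, each = 32), 32, n, byrow = FALSE))
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass filter: stop band, pass band, zero phase", {
  fs <- 1200; n <- 48000; t <- seq_len(n) / fs
  slow <- data_session(matrix(sin(2 * pi * 0.05 * t), 32, n, byrow = TRUE))
  out <- bandpass_filter(slow)
  expect_lt(rms(out$data[1, ]) / rms(slow$data[1, ]), 0.10)

  mid <- data_session(matrix(sin(2 * pi * 10 * t), 32, n, byrow = TRUE))
  out <- bandpass_filter(mid)
  expect_lt(abs(rms(out$data[1, ]) / rms(mid$data[1, ]) - 1), 0.05)
  # zero phase: pass-band sinusoid essentially unchanged pointwise
  expect_lt(max(abs(out$data[1, ] - mid$data[1, ])), 0.05)

  expect_error(bandpass_filter(mid, high = 700), "fs too low")
})

test_that("band-pass filter removes out-of-band white-noise power (periodogram oracle)", {
  set.seed(4)
  s <- data_session(matrix(rnorm(32 * 24000), 32, 24000))
  out <- bandpass_filter(s)
  x <- out$data[1, ]
  inside <- periodogram_band_power(x, 1200, 0.5, 100.0001)
  total <- periodogram_band_power(x, 1200, 0, 600)
  expect_lt((total - inside) / total, 0.01)
})

test_that("notch filter: 50 Hz removed, neighbors untouched", {
  fs <- 1200; n <- 24000; t <- seq_len(n) / fs
  s50 <- data_session(matrix(sin(2 * pi * 50 * t), 32, n, byrow = TRUE))
  expect_lt(rms(notch_filter(s50)$data[1, ]) / rms(s50$data[1, ]), 0.10)

  s10 <- data_session(matrix(sin(2 * pi * 10 * t), 32, n, byrow = TRUE))
  expect_lt(abs(rms(notch_filter(s10)$data[1, ]) / rms(s10$data[1, ]) - 1), 0.02)

  # < 1 dB at 40 and 60 Hz
  for (f0 in c(40, 60)) {
    sf <- data_session(matrix(sin(2 * pi * f0 * t), 32, n, byrow = TRUE))
    ratio <- rms(notch_filter(sf)$data[1, ]) / rms(sf$data[1, ])
    expect_gt(20 * log10(ratio), -1)
  }

  mixed <- sin_session(c(10, 50), c(1, 1))
  out <- notch_filter(mixed)
  x <- out$data[1, ]
  expect_gt(periodogram_band_power(x, 1200, 9.5, 10.5),
            0.9 * periodogram_band_power(mixed$data[1, ], 1200, 9.5, 10.5))
  expect_lt(periodogram_band_power(x, 1200, 49.5, 50.5),
            1e-4 * periodogram_band_power(mixed$data[1, ], 1200, 49.5, 50.5))
  expect_error(notch_filter(mixed, f0 = 700), "Nyquist")
})

test_that("bad-channel detection thresholds strictly", {
  n <- 4800
  data <- matrix(rnorm(32 * n, sd = 5), 32, n)
  s <- data_session(data)
  expect_identical(detect_bad_channels(s), character(0))

  data2 <- data
  data2[7, ] <- 200
  expect_identical(detect_bad_channels(data_session(data2)),
                   s$montage$names[7])

  # exactly frac of samples out of range -> not flagged (strict >)
  data3 <- data * 0
  k <- round(0.05 * n)
  data3[3, seq_len(k)] <- 60
  expect_identical(detect_bad_channels(data_session(data3)), character(0))
  data3[3, k + 1L] <- 60
  expect_identical(detect_bad_channels(data_session(data3)),
                   s$montage$names[3])
})

test_that("reconstruction equals the neighbor mean", {
  m <- standard_montage()
  n <- 2400
  data <- matrix(rnorm(32 * n), 32, n)
  s <- data_session(data)

  # neighbors of CZ all constant 3 -> CZ becomes 3
  cz_nb <- match(m$neighbors$CZ, m$names)
  data1 <- data
  data1[cz_nb, ] <- 3
  r <- reconstruct_channels(data_session(data1), "CZ")
  expect_equal(unname(r$data[match("CZ", m$names), ]), rep(3, n))

  # two good neighbors at 1 and 3 -> mean 2 (others in CZ's hood marked bad)
  data2 <- data
  data2[match(c("FCZ", "CPZ"), m$names), ] <- c(1, 3)  # recycled per column
  r2 <- reconstruct_channels(data_session(data2), c("CZ", "C1", "C2"))
  expect_equal(unname(r2$data[match("CZ", m$names), ]), rep(2, n))

  # brute-force oracle on a random session
  bad <- c("C3", "PO7")
  r3 <- reconstruct_channels(s, bad)
  for (lab in bad) {
    good_nb <- setdiff(m$neighbors[[lab]], bad)
    expected <- rep(0, n)
    for (tt in seq_len(n)) {
      acc <- 0
      for (nb in good_nb) acc <- acc + data[match(nb, m$names), tt]
      expected[tt] <- acc / length(good_nb)
    }
    expect_identical(unname(r3$data[match(lab, m$names), ]), expected)
  }
  # good channels untouched
  keep <- setdiff(m$names, bad)
  expect_identical(r3$data[match(keep, m$names), ], data[match(keep, m$names), ])

  # no good neighbors -> error (PO7's whole neighborhood bad)
  expect_error(
    reconstruct_channels(s, c("PO7", m$neighbors$PO7)),
    "no good neighbors")
  expect_error(reconstruct_channels(s, "NOPE"), "unknown label")
})

test_that("mv_threshold matches forced examples and the two-loop oracle", {
  expect_identical(mv_threshold(rep(5, 100), 10), 5)
  expect_identical(mv_threshold(c(1, 2, 3, 4, 5, 6), 2), 4)
  expect_error(mv_threshold(1:5, 10), "shorter")

  set.seed(77)
  x <- rnorm(5000)
  # independent two-loop oracle
  oracle <- function(x, L) {
    N <- floor(length(x) / L)
    maxima <- rep(-Inf, N)
    for (i in seq_len(N)) {
      for (j in ((i - 1) * L + 1):(i * L)) {
        if (x[j] > maxima[i]) maxima[i] <- x[j]
      }
    }
    sum(maxima) / N
  }
  expect_identical(mv_threshold(x, 1200), oracle(x, 1200))
  expect_identical(mv_threshold(x, 7), oracle(x, 7))  # remainder dropped
  # absolute-value option dominates the signed version
  expect_gte(mv_threshold(x, 100, use_abs = TRUE), mv_threshold(x, 100))
})

test_that("mv_threshold is scale-equivariant and monotone in nested L", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(2400) * runif(1, 0.1, 10)
    a <- runif(1, 0.1, 20)
    expect_equal(mv_threshold(a * x, 120), a * mv_threshold(x, 120))
    for (L1 in c(10, 50)) {
      for (mult in c(2, 4)) {
        expect_gte(mv_threshold(x, L1 * mult) + 1e-12, mv_threshold(x, L1))
      }
    }
  }
  # L = 1: every sample is its own epoch -> signal mean
  x <- rnorm(500)
  curve <- mv_threshold_curve(x, c(1, 10, 100))
  expect_equal(curve$threshold[1], mean(x))
  # constant signal -> flat curve
  cc <- mv_threshold_curve(rep(2.5, 600), c(1, 5, 60, 600))
  expect_true(all(cc$threshold == 2.5))
  expect_error(mv_threshold_curve(x, 1000), "exceeds")
})

test_that("standardization divides by the cross-channel mean threshold", {
  n <- 2400
  # 16 channels constant 2, 16 constant 4 -> thresholds 2 and 4, denom 3
  data <- matrix(rep(c(2, 4), each = 16), 32, n)
  data[1, 1] <- 2  # keep constant
  s <- data_session(data)
  th <- mv_thresholds(s, L = 1200)
  expect_equal(unname(th$values), rep(c(2, 4), each = 16))
  std <- standardize(s, th)
  expect_equal(std$denominator, 3)
  expect_equal(unname(std$data[1, 5]), 2 / 3)
  expect_equal(unname(std$data[32, 5]), 4 / 3)

  # gain invariance
  set.seed(21)
  raw <- matrix(rnorm(32 * n, sd = 8), 32, n)
  s1 <- data_session(raw)
  s2 <- data_session(5.5 * raw)
  expect_equal(standardize(s1)$data, standardize(s2)$data)

  # all-zero session cannot be standardized
  expect_error(standardize(data_session(matrix(0, 32, n))), "zero denominator")
})

test_that("standardization is idempotent up to gain", {
  set.seed(22)
  n <- 24000
  s <- data_session(matrix(rnorm(32 * n, sd = 15), 32, n))
  std1 <- standardize(s)
  std2 <- standardize(std1)
  expect_lt(abs(std2$denominator - 1), 0.15)
})

test_that("reconstructed channels are linear combinations of good channels", {
  s <- fixture_session()
  bad <- "C3"
  r <- reconstruct_channels(s, bad)
  nb <- match(s$montage$neighbors$C3, s$montage$names)
  expect_equal(r$data[match("C3", s$montage$names), ],
               colMeans(s$data[nb, ]))
})
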