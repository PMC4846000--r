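test_that("drop_breaks keeps only task segments in order", {
  s <- fixture_session()
  d <- drop_breaks(s)
  expect_identical(nrow(d$segments), 32L)
  expect_true(all(d$segments$kind %in% c("A", "B", "C", "D")))
  expect_identical(d$segments$start[1], 0L)
  expect_identical(d$segments$end[32], ncol(d$data))
  # order preserved: run 1 tasks first, data of task A run 1 unchanged
  expect_identical(d$data[, 1:100], s$data[, 1:100])
  # session with no breaks -> identity
  expect_identical(drop_breaks(d)$data, d$data)
})

test_that("epoching follows the step-slot convention with reflection padding", {
  # a segment of exactly 1200 samples -> 2 epochs (second right-padded)
  set.seed(2)
  data <- matrix(rnorm(32 * 4800), 32, 4800)
  s <- data_session(data)  # 4 tasks x 1200 samples
  es <- epoch_tasks(s)
  expect_identical(length(es$starts), 8L)
  expect_identical(es$labels, rep(c("A", "B", "C", "D"), each = 2L))
  # second epoch of task A: starts at 600, samples 600..1199 then reflection
  ep <- epoch_signal(es, 2L)
  expect_identical(ep[, 1:600], data[, 601:1200])
  expect_identical(ep[, 601:1200], data[, 1200:601])
  # no epoch crosses a task boundary
  for (i in seq_along(es$starts)) {
    expect_lte(es$starts[i] + es$epoch_len, es$seg_end[i] + es$step)
  }
  expect_error(epoch_tasks(data_session(matrix(0, 32, 4 * 600))), "shorter")
})

test_that("small default session epochs count and labels are consistent", {
  s <- fixture_session()  # 6 s tasks -> 12 epochs per task segment
  es <- epoch_tasks(s)
  expect_identical(length(es$starts), 8L * 4L * 12L)
  expect_identical(sum(es$labels == "A"), 8L * 12L)
  expect_true(all(table(es$runs) == 48L))
})

test_that("burg spectrum locates a pure tone and handles degenerate input", {
  t <- (1:1200) / 1200
  sp <- burg_spectrum(sin(2 * pi * 10 * t))
  expect_identical(length(sp), 100L)
  expect_identical(unname(which.max(sp)), 10L)
  expect_true(all(sp >= 0))
  expect_equal(unclass(burg_spectrum(rep(0, 1200)))[1:100],
               rep(0, 100), ignore_attr = TRUE)
  expect_error(burg_spectrum(rnorm(30), order = 16), "2 \\* order")
})

test_that("burg spectrum of white noise is flat within 3x (averaged)", {
  set.seed(14)
  acc <- rep(0, 100)
  for (i in 1:200) acc <- acc + unclass(burg_spectrum(rnorm(1200)))
  acc <- acc / 200
  expect_lt(max(acc) / min(acc), 3)
})

test_that("burg spectrum matches the closed-form AR(2) spectrum at the peak", {
  # AR(2): x_t = a1 x_{t-1} + a2 x_{t-2} + e_t with a resonance near 20 Hz
  fs <- 1200
  r <- 0.95; f0 <- 20
  a1 <- 2 * r * cos(2 * pi * f0 / fs); a2 <- -r^2
  closed_form <- function(f) {
    z <- exp(-2i * pi * f / fs)
    1 / Mod(1 - a1 * z - a2 * z^2)^2
  }
  set.seed(15)
  acc <- rep(0, 100)
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    x <- as.numeric(stats::filter(rnorm(1500), c(a1, a2), method = "recursive"))
    acc <- acc + unclass(burg_spectrum(x[301:1500], order = 16))
  }
  acc <- acc / n_rep
  expected <- vapply(as.numeric(1:100), closed_form, 0)
  peak <- which.max(expected)
  # resonance peak recovered to within one 1 Hz bin
  expect_lte(abs(unname(which.max(acc)) - peak), 1)
  # compare shape at the peak after normalizing total power
  ratio <- (acc[peak] / sum(acc)) / (expected[peak] / sum(expected))
  expect_lt(abs(ratio - 1), 0.10)
})

test_that("band_power sums half-open integer bins", {
  sp <- structure(rep(1, 100), names = as.character(1:100))
  expect_identical(band_power(sp, "alpha"), 4)   # bins 8..11
  expect_identical(band_power(sp, "delta"), 3)   # bins 1..3
  expect_identical(band_power(sp, "theta"), 4)
  expect_identical(band_power(sp, "beta"), 18)
  expect_identical(band_power(sp, "gamma_low"), 20)
  expect_identical(band_power(sp, "gamma_high"), 40)
  expect_identical(band_power(0 * sp, "alpha"), 0)
  expect_error(band_power(sp, "mu"), "unknown band")

  set.seed(16)
  rsp <- stats::runif(100)
  # loop-based oracle
  acc <- 0
  for (f in 30:49) acc <- acc + rsp[f]
  expect_identical(band_power(rsp, "gamma_low"), acc)
})

test_that("extract_features agrees with the burg_spectrum + band_power path", {
  s <- generate_session(small_cfg(task_duration_s = 2, break_duration_s = 1,
                                  seed = 19))
  std <- standardize(s)
  f <- extract_features(std)
  expect_identical(names(f), names(eeg_bands()))
  es <- epoch_tasks(std)
  expect_identical(nrow(f$alpha$values), length(es$starts))
  for (i in c(1L, 7L, length(es$starts))) {
    ep <- epoch_signal(es, i)
    sp <- burg_spectrum(ep, order = 16L, fs = std$fs)
    for (b in c("delta", "alpha", "gamma_high")) {
      expect_equal(unname(f[[b]]$values[i, ]), unname(band_power(sp, b)),
                   tolerance = 1e-12)
    }
  }
})

test_that("features share labels/runs across bands and average to 24 vectors", {
  f <- fixture_features()
  for (b in names(f)) {
    expect_identical(f[[b]]$labels, f$delta$labels)
    expect_identical(f[[b]]$runs, f$delta$runs)
    expect_identical(ncol(f[[b]]$values), 32L)
    expect_true(all(f[[b]]$values >= 0))
  }
  av <- average_feature_vectors(f)
  expect_identical(nrow(av), 24L)
  expect_identical(ncol(av), 34L)
})

test_that("band powers are invariant to a common gain applied before standardization", {
  set.seed(23)
  s <- generate_session(small_cfg(task_duration_s = 2, break_duration_s = 1,
                                  seed = 23))
  f1 <- extract_features(standardize(s))
  s2 <- s
  s2$data <- 3.7 * s2$data
  f2 <- extract_features(standardize(s2))
  expect_equal(f1$gamma_high$values, f2$gamma_high$values, tolerance = 1e-8)
})

test_that("dominant band captures >= 80% of summed power for band-limited input", {
  set.seed(24)
  n <- 4800 * 4
  x <- gaitatt:::band_noise_pair(n, 1200, 8, 12)[[1]]
  s <- data_session(matrix(rep(x, each = 32), 32, n, byrow = FALSE))
  f <- extract_features(s)
  tot <- Reduce(`+`, lapply(f, function(bf) mean(bf$values)))
  expect_gt(mean(f$alpha$values) / tot, 0.8)
})

test_that("gamma-gain sessions separate occipital gamma_high features by task", {
  f <- fixture_features()  # default gains: B gamma_high 2.0 vs A 1.0
  occ <- c("PO7", "PO3", "POZ", "PO4", "PO8")
  vb <- mean(f$gamma_high$values[f$gamma_high$labels == "B", occ])
  va <- mean(f$gamma_high$values[f$gamma_high$labels == "A", occ])
  expect_gt(vb, va)
})

test_that("features CSV round-trips", {
  f <- fixture_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(f, path)
  back <- read_features_csv(path)
  expect_identical(names(back), names(f))
  expect_equal(back$gamma_low$values, f$gamma_low$values,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_identical(back$gamma_low$labels, f$gamma_low$labels)
})
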