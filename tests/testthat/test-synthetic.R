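test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg(task_duration_s = 2, break_duration_s = 1, seed = 5)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$data, s2$data)
  s3 <- generate_session(small_cfg(task_duration_s = 2, break_duration_s = 1,
                                   seed = 6))
  expect_false(identical(s1$data, s3$data))
})

test_that("all amplitudes and gains zero give an all-zero session", {
  cfg <- small_cfg(task_duration_s = 2, break_duration_s = 1,
                   background_scale = 0, line_noise_amp = 0,
                   alpha_motor_amp = 0, gait_artifact_amp = 0, blink_rate = 0,
                   blink_amp = 0, gamma_base_amp = 0)
  s <- generate_session(cfg)
  expect_true(all(s$data == 0))
})

test_that("default layout and invariants hold", {
  s <- fixture_session()
  seg <- s$segments
  expect_identical(sum(seg$kind %in% c("A", "B", "C", "D")), 32L)
  expect_identical(sum(seg$kind == "break"), 7L)
  for (r in 1:8) {
    expect_identical(seg$kind[which(!is.na(seg$run) & seg$run == r)],
                     c("A", "B", "C", "D"))
  }
})

test_that("clean channels stay within the +/-50 uV EEG range", {
  s <- fixture_session()
  inside <- rowMeans(abs(s$data) <= 50)
  expect_true(all(inside >= 0.99))
})

test_that("line noise concentrates at the 50 Hz bin", {
  cfg <- small_cfg(task_duration_s = 2, break_duration_s = 1,
                   background_scale = 0, alpha_motor_amp = 0,
                   gait_artifact_amp = 0, blink_rate = 0, gamma_base_amp = 0,
                   line_noise_amp = 5)
  s <- generate_session(cfg)
  x <- s$data[1, ]
  near <- periodogram_band_power(x, s$fs, 49.5, 50.5)
  total <- periodogram_band_power(x, s$fs, 0, 600)
  expect_gt(near / total, 0.99)
})

test_that("gait artifact power is concentrated below 8 Hz", {
  cfg <- small_cfg(task_duration_s = 2, break_duration_s = 1,
                   background_scale = 0, alpha_motor_amp = 0, line_noise_amp = 0,
                   blink_rate = 0, gamma_base_amp = 0, gait_artifact_amp = 8)
  s <- generate_session(cfg)
  x <- s$data[1, ]  # FZ, frontal: strongest gait artifact
  low <- periodogram_band_power(x, s$fs, 0, 8)
  total <- periodogram_band_power(x, s$fs, 0, 600)
  expect_gt(low / total, 0.99)
})

test_that("configured gamma gain scales occipital band power (periodogram oracle)", {
  gains <- list(A = c(gamma_low = 1, gamma_high = 1),
                B = c(gamma_low = 1, gamma_high = 2),
                C = c(gamma_low = 1, gamma_high = 1),
                D = c(gamma_low = 1, gamma_high = 1))
  cfg <- small_cfg(task_duration_s = 10, break_duration_s = 1, seed = 31,
                   line_noise_amp = 0, class_gain = gains)
  s <- generate_session(cfg)
  seg <- s$segments
  po <- match(c("PO7", "PO3", "POZ", "PO4", "PO8"), s$montage$names)
  power_for <- function(task) {
    rows <- which(seg$kind == task)
    mean(vapply(rows, function(r) {
      idx <- (seg$start[r] + 1L):seg$end[r]
      mean(vapply(po, function(ch) {
        periodogram_band_power(s$data[ch, idx], s$fs, 50, 90)
      }, 0))
    }, 0))
  }
  ratio <- power_for("B") / power_for("A")
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("null sessions have no task-dependent gamma structure", {
  # two-sample t between per-run gamma powers of tasks A and B; expect
  # non-significance at alpha = 0.01 in >= 95% of 100 seeds
  n_sig <- 0L
  for (seed in 1:100) {
    cfg <- small_cfg(task_duration_s = 2, break_duration_s = 1, seed = seed)
    s <- generate_null_session(cfg)
    seg <- s$segments
    po <- match(c("PO7", "PO8"), s$montage$names)
    pw <- function(task) {
      rows <- which(seg$kind == task)
      vapply(rows, function(r) {
        idx <- (seg$start[r] + 1L):seg$end[r]
        mean(vapply(po, function(ch) {
          periodogram_band_power(s$data[ch, idx], s$fs, 50, 90)
        }, 0))
      }, 0)
    }
    p <- stats::t.test(pw("A"), pw("B"))$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 5L)
})

test_that("null sessions are reproducible and marked", {
  cfg <- small_cfg(task_duration_s = 2, break_duration_s = 1, seed = 8)
  s1 <- generate_null_session(cfg)
  s2 <- generate_null_session(cfg)
  expect_identical(s1$data, s2$data)
  expect_true(isTRUE(s1$meta$null))
  expect_null(s1$meta$class_gain)
})

test_that("corrupt_channels is local, detectable and validated", {
  s <- generate_session(small_cfg(task_duration_s = 2, break_duration_s = 1,
                                  seed = 12))
  bad <- corrupt_channels(s, c(PO7 = 200))
  expect_identical(detect_bad_channels(bad), "PO7")

  trio <- corrupt_channels(s, c(PO7 = 200, C5 = 150, CPZ = 300))
  expect_setequal(detect_bad_channels(trio), c("PO7", "C5", "CPZ"))
  untouched <- setdiff(s$montage$names, c("PO7", "C5", "CPZ"))
  idx <- match(untouched, s$montage$names)
  expect_identical(trio$data[idx, ], s$data[idx, ])

  expect_identical(corrupt_channels(s, numeric(0))$data, s$data)
  expect_error(corrupt_channels(s, c(XX9 = 100)), "unknown label")
})

test_that("config validation rejects negative amplitudes and bad gain maps", {
  expect_error(sim_config(background_scale = -1), ">= 0")
  expect_error(sim_config(class_gain = list(A = c(gamma_low = 1))), "A,B,C,D")
  cg <- gaitatt:::default_class_gain()
  cg$B["gamma_high"] <- -2
  expect_error(sim_config(class_gain = cg), ">= 0")
})
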