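# Synthetic treadmill-walking EEG sessions.
#
# The generator emulates the statistical structure the analysis relies on:
# spatially correlated 1/f-type cortical background bounded to the typical
# +/-50 uV range, 50 Hz line interference, delta/theta gait-locked motion
# artifacts strongest frontally, frontal blink transients, a left/right
# alternating motor-cortex alpha rhythm, and the class signal proper: a
# per-task multiplicative power gain on band-limited gamma processes over
# occipito-parietal electrodes.

OCCIPITO_PARIETAL <- c("P5", "P3", "PZ", "P4", "P6",
                       "PO7", "PO3", "POZ", "PO4", "PO8")

default_class_gain <- function() {
  list(
    A = c(gamma_low = 1.0, gamma_high = 1.0),
    B = c(gamma_low = 1.6, gamma_high = 2.0),
    C = c(gamma_low = 1.5, gamma_high = 1.8),
    D = c(gamma_low = 0.8, gamma_high = 0.6)
  )
}

#' Configuration for the synthetic session generator
#'
#' Defaults describe one session of the dual-task treadmill paradigm: 8 runs
#' of four 1-minute attention tasks (A normal walking, B arithmetic, C video,
#' D following marks) with 1-minute breaks between runs, walking at 2 km/h
#' (stride fundamental ~0.8 Hz), recorded on the 32-channel montage at
#' 1200 Hz. Amplitudes are free parameters of the simulated world, chosen so
#' that clean channels stay in the typical +/-50 uV EEG range.
#'
#' @param fs Sampling rate, Hz.
#' @param n_runs Number of runs.
#' @param task_duration_s,break_duration_s Task and inter-run break length, s.
#' @param background_scale RMS amplitude (uV) of the 1/f-type correlated
#'   cortical background.
#' @param line_noise_amp Peak amplitude (uV) of the 50 Hz mains component.
#' @param alpha_motor_amp Peak amplitude (uV) of the 10 Hz motor rhythm over
#'   the C row, amplitude-modulated left/right at the stride rate.
#' @param gait_artifact_amp Peak amplitude (uV) of the stride-locked artifact
#'   fundamental; harmonics up to the 6th with 1/k amplitude decay, strongest
#'   frontally (delta/theta band energy).
#' @param blink_rate Blink events per minute (frontal raised-cosine bumps).
#' @param blink_amp Peak blink amplitude (uV) at the most frontal site.
#' @param stride_hz Stride fundamental frequency, Hz (~0.8 at 2 km/h).
#' @param gamma_base_amp RMS amplitude (uV) of each band-limited gamma process
#'   (30-50 and 50-90 Hz) on the effect region at gain 1.
#' @param class_gain Named list task code -> named numeric vector of
#'   multiplicative power gains per gamma band (`gamma_low`, `gamma_high`).
#' @param task_broadband_gain Named numeric vector task code -> multiplicative
#'   power gain applied to the background during that task (1 = none); used to
#'   give one task a broadband offset.
#' @param region Electrode labels carrying the class signal.
#' @param bad_channels Named numeric vector label -> amplitude (uV) of
#'   channels to corrupt after generation.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 1200, n_runs = 8L, task_duration_s = 60,
                       break_duration_s = 60, background_scale = 12,
                       line_noise_amp = 5, alpha_motor_amp = 6,
                       gait_artifact_amp = 8, blink_rate = 15, blink_amp = 30,
                       stride_hz = 0.8, gamma_base_amp = 3,
                       class_gain = default_class_gain(),
                       task_broadband_gain = c(A = 1, B = 1, C = 1, D = 1),
                       region = OCCIPITO_PARIETAL,
                       bad_channels = numeric(0), seed = 1L) {
  cfg <- list(fs = fs, n_runs = as.integer(n_runs),
              task_duration_s = task_duration_s,
              break_duration_s = break_duration_s,
              background_scale = background_scale,
              line_noise_amp = line_noise_amp,
              alpha_motor_amp = alpha_motor_amp,
              gait_artifact_amp = gait_artifact_amp,
              blink_rate = blink_rate, blink_amp = blink_amp,
              stride_hz = stride_hz, gamma_base_amp = gamma_base_amp,
              class_gain = class_gain,
              task_broadband_gain = task_broadband_gain,
              region = region, bad_channels = bad_channels,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  amps <- c(cfg$background_scale, cfg$line_noise_amp, cfg$alpha_motor_amp,
            cfg$gait_artifact_amp, cfg$blink_rate, cfg$blink_amp,
            cfg$gamma_base_amp)
  if (any(amps < 0)) stop("all amplitudes and rates must be >= 0")
  if (!setequal(names(cfg$class_gain), TASK_CODES)) {
    stop("class_gain must cover task codes A,B,C,D")
  }
  if (any(unlist(cfg$class_gain) < 0)) stop("class gains must be >= 0")
  if (!all(TASK_CODES %in% names(cfg$task_broadband_gain))) {
    stop("task_broadband_gain must cover task codes A,B,C,D")
  }
  if (any(cfg$task_broadband_gain < 0)) stop("broadband gains must be >= 0")
  if (cfg$fs <= 0 || cfg$n_runs < 1L) stop("invalid fs or n_runs")
  cfg
}

# 1/f-type noise: a discretized Ornstein-Uhlenbeck process with a ~1 Hz knee
# (power flat below the knee, falling as 1/f^2 above, i.e. amplitude ~ 1/f);
# unit RMS. A single recursive filter keeps this O(n).
pink_noise <- function(n, fs, knee_hz = 1) {
  x <- .ar1_filter(stats::rnorm(n), exp(-2 * pi * knee_hz / fs))
  x / sd(x)
}

# Two independent unit-RMS Gaussian noises band-limited to [lo, hi) Hz,
# synthesized in the frequency domain. The real and imaginary parts of the
# inverse FFT of an (unsymmetrized) complex Gaussian band spectrum are two
# independent real band-limited processes, so one FFT yields both.
band_noise_pair <- function(n, fs, lo, hi) {
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  keep <- which(f >= lo & f < hi)
  z <- complex(length.out = n)
  z[keep] <- complex(real = stats::rnorm(length(keep)),
                     imaginary = stats::rnorm(length(keep)))
  x <- stats::fft(z, inverse = TRUE)
  re <- Re(x); im <- Im(x)
  list(re / sd(re), im / sd(im))
}

#' Generate a synthetic EEG session
#'
#' @param config A [sim_config()].
#' @return An [eeg_session()] laid out as `n_runs` runs of tasks A,B,C,D with
#'   breaks between runs. Identical seeds give identical samples.
#' @export
generate_session <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  mont <- standard_montage()
  labels <- mont$names
  nch <- length(labels)
  seg <- paradigm_segments(config$fs, config$n_runs, config$task_duration_s,
                           config$break_duration_s)
  n <- seg$end[nrow(seg)]
  t <- seq_len(n) / config$fs

  # Work sample-major (columns = channels, contiguous) and transpose once at
  # the end; the per-channel updates below are all O(n) column operations.

  # Correlated 1/f background: independent pink sources mixed through the
  # Cholesky factor of a distance-decaying correlation (volume conduction).
  pos <- mont$positions
  d2 <- as.matrix(stats::dist(pos))^2
  C <- exp(-d2 / (2 * 0.35^2))
  a_knee <- exp(-2 * pi * 1 / config$fs)
  X <- matrix(stats::rnorm(n * nch), n, nch)
  for (i in seq_len(nch)) {
    xi <- .ar1_filter(X[, i], a_knee)
    X[, i] <- xi / sd(xi)
  }
  X <- (X %*% chol(C)) * config$background_scale
  colnames(X) <- labels

  # Per-task broadband power offset on the background.
  if (any(config$task_broadband_gain != 1)) {
    g <- rep(1, n)
    for (k in seq_len(nrow(seg))) {
      if (seg$kind[k] %in% TASK_CODES) {
        idx <- (seg$start[k] + 1L):seg$end[k]
        g[idx] <- sqrt(config$task_broadband_gain[[seg$kind[k]]])
      }
    }
    for (i in seq_len(nch)) X[, i] <- X[, i] * g
  }

  y <- pos[, "y"]
  # 50 Hz line interference, common phase, equal amplitude on all channels.
  if (config$line_noise_amp > 0) {
    line <- config$line_noise_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    for (i in seq_len(nch)) X[, i] <- X[, i] + line
    rm(line)
  }

  # Gait-locked motion artifact: stride harmonics (delta/theta), frontal bias.
  if (config$gait_artifact_amp > 0) {
    wg <- 0.3 + 0.7 * (y - min(y)) / (max(y) - min(y))
    gait <- rep(0, n)
    for (k in 1:6) {
      gait <- gait + (config$gait_artifact_amp / k) *
        sin(2 * pi * k * config$stride_hz * t + runif(1, 0, 2 * pi))
    }
    for (i in seq_len(nch)) X[, i] <- X[, i] + wg[i] * gait
    rm(gait)
  }

  # Alternating motor-cortex alpha: 10 Hz carrier, left/right envelopes in
  # antiphase at the stride rate over the C row.
  if (config$alpha_motor_amp > 0) {
    carrier <- sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
    env <- 0.5 + 0.5 * sin(2 * pi * config$stride_hz * t)
    crow <- grepl("^C[1-6Z]$", labels)
    side <- ifelse(pos[, "x"] < 0, 1, ifelse(pos[, "x"] > 0, -1, 0))
    for (i in which(crow)) {
      e <- if (side[i] > 0) env else if (side[i] < 0) 1 - env else rep(0.5, n)
      X[, i] <- X[, i] + config$alpha_motor_amp * e * carrier
    }
    rm(carrier, env)
  }

  # Frontal blink transients: Poisson events, 0.25 s raised-cosine bumps.
  if (config$blink_rate > 0 && config$blink_amp > 0) {
    n_blinks <- stats::rpois(1, config$blink_rate * n / config$fs / 60)
    wb <- pmax(0, y) / max(y)
    width <- round(0.25 * config$fs)
    bump <- config$blink_amp * 0.5 * (1 - cos(2 * pi * seq_len(width) / width))
    if (n_blinks > 0) {
      starts <- sort(sample.int(max(n - width, 1L), n_blinks, replace = TRUE))
      blink <- rep(0, n)
      for (s0 in starts) {
        idx <- s0:(s0 + width - 1L)
        blink[idx] <- blink[idx] + bump
      }
      for (i in which(wb > 0)) X[, i] <- X[, i] + wb[i] * blink
      rm(blink)
    }
  }

  # Class signal: band-limited gamma processes on the effect region whose
  # amplitude is scaled by sqrt(gain) per task (multiplicative power gain).
  if (config$gamma_base_amp > 0) {
    bands <- list(gamma_low = c(30, 50), gamma_high = c(50, 90))
    gain_env <- list()
    for (b in names(bands)) {
      g <- rep(1, n)
      for (k in seq_len(nrow(seg))) {
        if (seg$kind[k] %in% TASK_CODES) {
          idx <- (seg$start[k] + 1L):seg$end[k]
          g[idx] <- sqrt(config$class_gain[[seg$kind[k]]][[b]])
        }
      }
      gain_env[[b]] <- g
    }
    region <- intersect(config$region, labels)
    for (b in names(bands)) {
      k <- 1L
      while (k <= length(region)) {
        pair <- band_noise_pair(n, config$fs, bands[[b]][1], bands[[b]][2])
        for (j in 1:2) {
          if (k > length(region)) break
          i <- match(region[k], labels)
          X[, i] <- X[, i] + config$gamma_base_amp * gain_env[[b]] * pair[[j]]
          k <- k + 1L
        }
      }
    }
  }
  data <- t(X)
  rm(X)

  meta <- list(generator = "gaitatt-sim", seed = config$seed,
               stride_hz = config$stride_hz,
               class_gain = config$class_gain, region = config$region)
  sess <- eeg_session(data, fs = config$fs, montage = mont, segments = seg,
                      meta = meta)
  if (length(config$bad_channels) > 0) {
    sess <- corrupt_channels(sess, config$bad_channels)
  }
  sess
}

#' Generate a null session (no task-dependent structure)
#'
#' Identical to [generate_session()] except that every class gain and
#' broadband gain is 1, so per-task band powers differ only by sampling error.
#' The output metadata is marked `null` and carries no class-gain map.
#'
#' @param config A [sim_config()]; its gain fields are overridden.
#' @return An [eeg_session()].
#' @export
generate_null_session <- function(config = sim_config()) {
  config$class_gain <- lapply(default_class_gain(), function(g) {
    g[] <- 1; g
  })
  config$task_broadband_gain[] <- 1
  sess <- generate_session(config)
  sess$meta$class_gain <- NULL
  sess$meta$null <- TRUE
  sess
}

#' Corrupt channels with out-of-range signals
#'
#' Replaces the named channels with a deterministic drift-plus-oscillation
#' signal whose amplitude persistently exceeds the +/-50 uV EEG range (for
#' `amplitude` well above 50), leaving all other channels untouched.
#'
#' @param session An [eeg_session()].
#' @param bad Named numeric vector: electrode label -> amplitude in uV.
#' @return The modified session.
#' @export
corrupt_channels <- function(session, bad) {
  validate_session(session)
  if (length(bad) == 0) return(session)
  labels <- session$montage$names
  unknown <- setdiff(names(bad), labels)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  t <- seq_len(ncol(session$data)) / session$fs
  for (lab in names(bad)) {
    amp <- bad[[lab]]
    i <- match(lab, labels)
    session$data[i, ] <- amp * (0.7 * sin(2 * pi * 0.9 * t) +
                                  0.5 * sin(2 * pi * 0.07 * t))
  }
  session$meta$corrupted <- names(bad)
  session
}
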