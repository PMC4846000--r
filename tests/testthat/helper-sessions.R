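# Shared fixtures, built in code at test time.
#
# Full-size sessions (8 runs x 60 s tasks) are expensive, so most tests run on
# a scaled-down paradigm: same 8-run A,B,C,D layout and sampling rate, shorter
# tasks and breaks. Structural-count assertions that depend on the full layout
# live in test-acceptance.R and use the full default once.

small_cfg <- function(task_duration_s = 6, break_duration_s = 2, seed = 42L,
                      ...) {
  sim_config(task_duration_s = task_duration_s,
             break_duration_s = break_duration_s, seed = seed, ...)
}

# One small session + its features, computed once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture_session <- function() {
  if (is.null(.fixture_env$session)) {
    .fixture_env$session <- generate_session(small_cfg())
  }
  .fixture_env$session
}

fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    pp <- preprocess_session(fixture_session())
    .fixture_env$prep <- pp
    .fixture_env$features <- extract_features(pp$session)
  }
  .fixture_env$features
}

fixture_prep <- function() {
  fixture_features()
  .fixture_env$prep
}

# Tiny task-structured session from explicit data (fast path for unit tests
# that need full control over samples). `data` is 32 x n.
data_session <- function(data, fs = 1200, n_runs = 1L) {
  n <- ncol(data)
  task_n <- n %/% (4L * n_runs)
  stopifnot(task_n * 4L * n_runs == n)
  seg <- paradigm_segments_for_test(fs, n_runs, task_n)
  eeg_session(data, fs = fs, segments = seg)
}

paradigm_segments_for_test <- function(fs, n_runs, task_n) {
  kind <- character(0); run <- integer(0); start <- integer(0); end <- integer(0)
  at <- 0L
  for (r in seq_len(n_runs)) {
    for (k in c("A", "B", "C", "D")) {
      kind <- c(kind, k); run <- c(run, r)
      start <- c(start, at); end <- c(end, at + task_n)
      at <- at + task_n
    }
  }
  data.frame(kind = kind, run = run, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Periodogram band power oracle (independent of the package's Burg path).
periodogram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f < hi & f <= fs / 2])
}

# Gaussian feature clusters for classifier sanity tests: 4 classes, run ids.
gaussian_clusters <- function(n_per_class_run = 10, n_runs = 8, d = 32,
                              sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 4, d)
  for (c in 1:4) centers[c, seq_len(4)] <- sep * (c == 1:4)
  values <- NULL; labels <- character(0); runs <- integer(0)
  for (r in seq_len(n_runs)) {
    for (c in 1:4) {
      m <- matrix(stats::rnorm(n_per_class_run * d, sd = sd),
                  n_per_class_run, d)
      m <- sweep(m, 2, centers[c, ], `+`)
      values <- rbind(values, m)
      labels <- c(labels, rep(LETTERS[c], n_per_class_run))
      runs <- c(runs, rep(r, n_per_class_run))
    }
  }
  structure(list(values = values, labels = labels, runs = runs,
                 band = "synthetic"), class = "band_features")
}
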