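# Per-task segmentation, overlapped epoching, Burg maximum-entropy spectra
# and six-band power features.

#' Frequency bands
#'
#' The six canonical EEG bands used throughout: delta 1-4, theta 4-8,
#' alpha 8-12, beta 12-30, gamma_low 30-50, gamma_high 50-90 Hz. Band edges
#' are half-open `[low, high)`, so a shared edge belongs to the upper band.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
       gamma_low = c(30, 50), gamma_high = c(50, 90))
}

#' Remove breaks from a session
#'
#' Drops break segments and concatenates the task segments in order, so no
#' later epoch can straddle a break. Task segment annotations are re-based to
#' the concatenated recording.
#'
#' @param session An [eeg_session()] (or standardized session).
#' @return The session restricted to task segments.
#' @export
drop_breaks <- function(session) {
  validate_session(session)
  seg <- session$segments
  task <- seg[seg$kind %in% TASK_CODES, , drop = FALSE]
  if (nrow(task) == nrow(seg)) return(session)
  keep <- unlist(lapply(seq_len(nrow(task)), function(i) {
    (task$start[i] + 1L):task$end[i]
  }))
  lens <- task$end - task$start
  new_end <- cumsum(lens)
  task$start <- c(0L, new_end[-length(new_end)])
  task$end <- new_end
  rownames(task) <- NULL
  session$data <- session$data[, keep, drop = FALSE]
  session$segments <- task
  session
}

#' Cut task segments into overlapped epochs
#'
#' Each task segment is cut into `epoch_len`-sample epochs starting every
#' `step` samples from the segment start, one epoch per step slot
#' (`floor(segment_length / step)` epochs). Epochs whose window runs past the
#' segment end are right-padded by reflection about the boundary, which is
#' what makes a 60 s task yield 120 (not 119) epochs at 1 s / 0.5 s overlap.
#' No epoch ever crosses a task boundary.
#'
#' @param session A break-free session (see [drop_breaks()]); sessions with
#'   breaks are passed through [drop_breaks()] first.
#' @param epoch_len Epoch length in samples (default 1200 = 1 s at 1200 Hz).
#' @param step Step between epoch starts in samples (default 600).
#' @return An `epoch_set`: list with `data` (channels x samples), `fs`,
#'   `starts` (0-based epoch starts), `seg_end` (enclosing segment end per
#'   epoch), `labels` (task code per epoch), `runs`, `epoch_len`, `step`.
#' @export
epoch_tasks <- function(session, epoch_len = 1200L, step = 600L) {
  session <- drop_breaks(session)
  seg <- session$segments
  epoch_len <- as.integer(epoch_len)
  step <- as.integer(step)
  if (epoch_len > 2L * step) {
    stop("step must be at least half the epoch length (reflection padding)")
  }
  starts <- integer(0); seg_end <- integer(0)
  labels <- character(0); runs <- integer(0)
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    if (len < epoch_len) stop("segment shorter than one epoch")
    k <- len %/% step
    st <- seg$start[i] + step * (seq_len(k) - 1L)
    starts <- c(starts, st)
    seg_end <- c(seg_end, rep(seg$end[i], k))
    labels <- c(labels, rep(seg$kind[i], k))
    runs <- c(runs, rep(seg$run[i], k))
  }
  structure(
    list(data = session$data, fs = session$fs, starts = starts,
         seg_end = seg_end, labels = labels, runs = runs,
         epoch_len = epoch_len, step = step,
         montage = session$montage),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", length(x$starts), " epochs x ", nrow(x$data),
      " channels, len ", x$epoch_len, ", step ", x$step, "\n", sep = "")
  invisible(x)
}

#' Materialize one epoch of an epoch set
#'
#' @param es An `epoch_set`.
#' @param i Epoch index.
#' @return channels x epoch_len matrix (reflection padding applied).
#' @export
epoch_signal <- function(es, i) {
  g <- es$starts[i] + seq_len(es$epoch_len) - 1L
  over <- g >= es$seg_end[i]
  g[over] <- 2L * es$seg_end[i] - g[over] - 1L
  es$data[, g + 1L, drop = FALSE]
}

#' Burg maximum-entropy spectrum of one epoch
#'
#' Fits an AR model of the given order by Burg's recursion (minimizing the
#' summed forward and backward prediction error power) and evaluates the AR
#' power spectrum at integer frequencies 1..100 Hz. An all-zero epoch yields
#' the all-zero spectrum.
#'
#' @param x Numeric vector (one channel of one epoch) or channels x samples
#'   matrix (one spectrum per row).
#' @param order AR model order (default 16); epoch length must be >= 2*order.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector (or matrix) of power values at 1..100 Hz; class
#'   `burg_spectrum` with attribute `ar_order`.
#' @export
burg_spectrum <- function(x, order = 16L, fs = 1200) {
  freqs <- as.numeric(1:100)
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, function(r) .burg_psd(r, order, freqs, fs)))
    colnames(out) <- as.character(1:100)
  } else {
    out <- .burg_psd(as.numeric(x), as.integer(order), freqs, fs)
    names(out) <- as.character(1:100)
  }
  structure(out, ar_order = as.integer(order), class = "burg_spectrum")
}

#' Band power from a spectrum
#'
#' Sums the integer-Hz power bins in the half-open interval `[low, high)` of
#' the named band, per channel.
#'
#' @param spectrum Output of [burg_spectrum()] (vector or matrix with bins
#'   1..100 Hz).
#' @param band Band name (see [eeg_bands()]).
#' @return Scalar (vector input) or per-row vector of band powers.
#' @export
band_power <- function(spectrum, band) {
  bands <- eeg_bands()
  if (!band %in% names(bands)) stop("unknown band: ", band)
  lo <- bands[[band]][1]; hi <- bands[[band]][2]
  bins <- lo:(hi - 1L)
  if (is.matrix(spectrum)) rowSums(spectrum[, bins, drop = FALSE])
  else sum(spectrum[bins])
}

#' Extract six-band power features from a session
#'
#' Runs the full feature path: drop breaks, cut 1 s epochs with 0.5 s overlap
#' per task, fit a Burg AR spectrum (1..100 Hz, 1 Hz resolution) to every
#' epoch and channel, and sum power bins per band. The default session layout
#' yields 3840 epochs (960 per task) and 32 features per epoch and band.
#'
#' @param session A standardized session (see [standardize()]); any session
#'   is accepted since the features are relative either way.
#' @param order Burg AR order.
#' @param epoch_len,step Epoching parameters in samples.
#' @return Named list over the six bands; each element is a `band_features`
#'   object: list with `values` (epochs x 32 matrix), `labels` (task codes),
#'   `runs`, `band`.
#' @export
extract_features <- function(session, order = 16L, epoch_len = 1200L,
                             step = 600L) {
  es <- epoch_tasks(session, epoch_len, step)
  bands <- eeg_bands()
  lo <- vapply(bands, `[`, 0, 1L)
  hi <- vapply(bands, `[`, 0, 2L)
  nep <- length(es$starts)
  nch <- nrow(es$data)
  mats <- lapply(bands, function(b) matrix(0, nep, nch,
                                           dimnames = list(NULL, es$montage$names)))
  for (ch in seq_len(nch)) {
    bp <- .burg_band_channel(es$data[ch, ], es$starts, es$seg_end,
                             as.integer(epoch_len), as.integer(order),
                             es$fs, as.integer(lo), as.integer(hi))
    for (b in seq_along(bands)) mats[[b]][, ch] <- bp[, b]
  }
  out <- lapply(seq_along(bands), function(b) {
    structure(list(values = mats[[b]], labels = es$labels, runs = es$runs,
                   band = names(bands)[b], ar_order = as.integer(order)),
              class = "band_features")
  })
  names(out) <- names(bands)
  out
}

#' @export
print.band_features <- function(x, ...) {
  cat("<band_features> ", x$band, ": ", nrow(x$values), " epochs x ",
      ncol(x$values), " channels\n", sep = "")
  invisible(x)
}

#' Per-task averaged feature vectors
#'
#' Averages the per-epoch feature vectors within each (band, task) cell,
#' producing the 6 x 4 = 24 mean scalp maps used for spatial inspection.
#'
#' @param features Output of [extract_features()].
#' @return Data frame: one row per (band, task), channel columns.
#' @export
average_feature_vectors <- function(features) {
  rows <- list()
  for (b in names(features)) {
    bf <- features[[b]]
    for (task in TASK_CODES) {
      v <- colMeans(bf$values[bf$labels == task, , drop = FALSE])
      rows[[paste(b, task)]] <- data.frame(band = b, task = task, t(v),
                                           check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write features to CSV
#'
#' One row per (epoch, band): columns `epoch`, `run`, `task`, `band`, then the
#' 32 channel features.
#'
#' @param features Output of [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  tabs <- lapply(features, function(bf) {
    data.frame(epoch = seq_len(nrow(bf$values)), run = bf$runs,
               task = bf$labels, band = bf$band, bf$values,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read features back from CSV
#'
#' @param path CSV written by [write_features_csv()].
#' @return Named list of `band_features`, as from [extract_features()].
#' @export
read_features_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  chans <- setdiff(names(tab), c("epoch", "run", "task", "band"))
  out <- lapply(split(tab, tab$band), function(d) {
    structure(list(values = as.matrix(d[, chans]), labels = d$task,
                   runs = d$run, band = d$band[1]),
              class = "band_features")
  })
  out[intersect(names(eeg_bands()), names(out))]
}
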