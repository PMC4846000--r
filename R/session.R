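TASK_CODES <- c("A", "B", "C", "D")

#' Attention-task labels
#'
#' The four one-minute tasks of the dual-task treadmill paradigm and the
#' attention-to-gait level each is designed to induce: normal walking is the
#' standard level, mental arithmetic and soundless video are distractors
#' (low attention to gait), and stepping on irregularly placed marks forces a
#' high attention level.
#'
#' @return A data frame with columns `code`, `description`, `attention_level`.
#' @export
task_labels <- function() {
  data.frame(
    code = TASK_CODES,
    description = c("normal walking", "mathematical operations",
                    "video", "following marks"),
    attention_level = c("standard", "low", "low", "high"),
    stringsAsFactors = FALSE
  )
}

#' Construct an EEG session
#'
#' A session is a channels x samples matrix in microvolts plus its sampling
#' rate, montage, and an ordered segment table annotating tasks and breaks.
#' Segment intervals are 0-based half-open `[start, end)` sample indices; they
#' must tile the recording without gaps or overlaps, and every run must
#' contain the four tasks in the fixed order A, B, C, D.
#'
#' @param data Numeric matrix, channels x samples, microvolts. Rows must match
#'   the montage order.
#' @param fs Sampling rate in Hz.
#' @param montage A [standard_montage()] object.
#' @param segments Data frame with columns `kind` (one of "A","B","C","D",
#'   "break"), `run` (integer 1..n_runs, `NA` for breaks), `start`, `end`
#'   (0-based half-open sample indices).
#' @param subject_group `"healthy"` or `"patient"`.
#' @param meta Free-form provenance list.
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(data, fs, montage = standard_montage(), segments,
                        subject_group = c("healthy", "patient"),
                        meta = list()) {
  subject_group <- match.arg(subject_group)
  s <- structure(
    list(data = data, fs = fs, montage = montage,
         segments = as.data.frame(segments),
         subject_group = subject_group, meta = meta),
    class = "eeg_session"
  )
  validate_session(s)
}

validate_session <- function(s) {
  stopifnot(inherits(s, "eeg_session"))
  validate_montage(s$montage)
  if (!is.matrix(s$data) || !is.numeric(s$data)) {
    stop("session data must be a numeric matrix")
  }
  if (nrow(s$data) != length(s$montage$names)) {
    stop("structural error: session has ", nrow(s$data),
         " channels but montage has ", length(s$montage$names))
  }
  if (!is.numeric(s$fs) || length(s$fs) != 1L || s$fs <= 0) {
    stop("fs must be a positive scalar")
  }
  seg <- s$segments
  need <- c("kind", "run", "start", "end")
  if (!all(need %in% names(seg))) stop("segments need columns kind/run/start/end")
  if (!all(seg$kind %in% c(TASK_CODES, "break"))) stop("unknown segment kind")
  n <- ncol(s$data)
  if (nrow(seg) == 0L) stop("segments must tile the recording")
  if (seg$start[1] != 0L || seg$end[nrow(seg)] != n) {
    stop("ordering error: segments must tile [0, n_samples)")
  }
  if (any(seg$end <= seg$start)) stop("empty or inverted segment")
  if (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)])) {
    stop("ordering error: segments must be ordered, non-overlapping and gapless")
  }
  task <- seg[seg$kind %in% TASK_CODES, , drop = FALSE]
  if (nrow(task) > 0L) {
    if (anyNA(task$run)) stop("task segments must carry a run index")
    for (r in unique(task$run)) {
      kinds <- task$kind[task$run == r]
      if (!identical(kinds, TASK_CODES)) {
        stop("run ", r, " must contain exactly tasks A,B,C,D in order")
      }
    }
  }
  s
}

#' @export
print.eeg_session <- function(x, ...) {
  nt <- sum(x$segments$kind %in% TASK_CODES)
  cat("<eeg_session> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$fs, " Hz, ", nt, " task segments, group=", x$subject_group, "\n",
      sep = "")
  invisible(x)
}

#' Write a session to the internal on-disk format
#'
#' The internal format is a raw binary sample file (`<stem>.dat`, 64-bit
#' little-endian floats in microvolts, sample-major channel interleaving) plus
#' a JSON sidecar (`<stem>.json`) holding the sampling rate, channel labels,
#' segment table, subject group and metadata. Both files are written
#' deterministically, so two writes of the same session are byte-identical.
#'
#' @param session An [eeg_session()].
#' @param path Output stem; `.json` and `.dat` are appended.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  stem <- sub("\\.json$", "", path)
  sidecar <- list(
    format = "gaitatt-session-v1",
    fs = session$fs,
    channels = session$montage$names,
    n_samples = ncol(session$data),
    subject_group = session$subject_group,
    segments = session$segments,
    meta = session$meta
  )
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE,
                       null = "null")
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(session$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a session from disk
#'
#' @param path File stem (internal format) or EDF file path.
#' @param format `"internal"` or `"edf"`.
#' @param montage Montage used to check and order channels.
#' @param segments Optional segment table for EDF imports, which carry no
#'   task annotations of their own; defaults to a single untasked segment.
#' @return An [eeg_session()].
#' @export
read_session <- function(path, format = c("internal", "edf"),
                         montage = standard_montage(), segments = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    return(read_session_edf(path, montage = montage, segments = segments))
  }
  stem <- sub("\\.json$", "", path)
  if (!file.exists(paste0(stem, ".json"))) stop("no such session: ", path)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  chans <- side$channels
  if (length(chans) != length(montage$names)) {
    stop("structural error: file declares ", length(chans), " channels")
  }
  if (!all(chans %in% montage$names)) {
    stop("labeled-channel error: unknown channel label(s): ",
         paste(setdiff(chans, montage$names), collapse = ", "))
  }
  n <- side$n_samples
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = length(chans) * n, size = 8L,
               endian = "little")
  data <- matrix(x, nrow = length(chans))
  rownames(data) <- chans
  data <- data[montage$names, , drop = FALSE]  # restore montage order
  seg <- as.data.frame(side$segments)
  seg$run <- as.integer(seg$run)
  eeg_session(data, fs = side$fs, montage = montage, segments = seg,
              subject_group = side$subject_group,
              meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

# Segment table for the default paradigm layout: n_runs runs of four
# task_s-second tasks (A,B,C,D) separated by break_s-second breaks.
paradigm_segments <- function(fs, n_runs = 8L, task_s = 60, break_s = 60) {
  task_n <- as.integer(round(task_s * fs))
  break_n <- as.integer(round(break_s * fs))
  kind <- character(0); run <- integer(0); start <- integer(0); end <- integer(0)
  at <- 0L
  for (r in seq_len(n_runs)) {
    for (k in TASK_CODES) {
      kind <- c(kind, k); run <- c(run, r)
      start <- c(start, at); end <- c(end, at + task_n)
      at <- at + task_n
    }
    if (r < n_runs) {
      kind <- c(kind, "break"); run <- c(run, NA_integer_)
      start <- c(start, at); end <- c(end, at + break_n)
      at <- at + break_n
    }
  }
  data.frame(kind = kind, run = run, start = start, end = end,
             stringsAsFactors = FALSE)
}
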