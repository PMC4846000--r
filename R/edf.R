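# Minimal European Data Format (EDF) support.
#
# Only what the pipeline needs: a read-only importer for continuous 32-channel
# recordings (16-bit samples, physical dimensions V/mV/uV converted to uV on
# import), plus an unexported writer used by the test-suite to build small
# synthetic EDF fixtures at run time. No EDF+ annotations, no discontinuous
# records.

edf_read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

read_session_edf <- function(path, montage = standard_montage(),
                             segments = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  edf_read_ascii(con, 8L)                      # version
  edf_read_ascii(con, 80L); edf_read_ascii(con, 80L)
  edf_read_ascii(con, 8L); edf_read_ascii(con, 8L)
  edf_read_ascii(con, 8L)                      # header length
  edf_read_ascii(con, 44L)
  n_rec <- as.integer(edf_read_ascii(con, 8L))
  dur <- as.numeric(edf_read_ascii(con, 8L))
  ns <- as.integer(edf_read_ascii(con, 4L))
  if (ns != length(montage$names)) {
    stop("structural error: EDF declares ", ns, " channels, expected ",
         length(montage$names))
  }
  rd <- function(w) vapply(seq_len(ns), function(i) edf_read_ascii(con, w), "")
  labels <- rd(16L)
  rd(80L)                                      # transducer
  dims <- rd(8L)
  pmin <- as.numeric(rd(8L)); pmax <- as.numeric(rd(8L))
  dmin <- as.numeric(rd(8L)); dmax <- as.numeric(rd(8L))
  rd(80L)                                      # prefiltering
  spr <- as.integer(rd(8L))
  rd(32L)                                      # reserved

  labels <- toupper(sub("^EEG ", "", labels))
  unknown <- setdiff(labels, montage$names)
  if (length(unknown)) {
    stop("labeled-channel error: unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  }
  if (length(unique(spr)) != 1L) stop("heterogeneous sampling rates unsupported")
  fs <- spr[1] / dur
  scale <- (pmax - pmin) / (dmax - dmin)
  to_uv <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
           stop("unsupported physical dimension: ", d))
  }, 1)

  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) * scale[i] + pmin[i]
      data[i, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- phys * to_uv[i]
    }
  }
  rownames(data) <- labels
  data <- data[montage$names, , drop = FALSE]
  if (is.null(segments)) {
    segments <- data.frame(kind = "break", run = NA_integer_, start = 0L,
                           end = ncol(data), stringsAsFactors = FALSE)
  }
  eeg_session(data, fs = fs, montage = montage, segments = segments,
              meta = list(source = path, format = "edf"))
}

# Write a synthetic EDF file (testing only). Quantizes to 16 bits over the
# given physical range, so the round trip is approximate by design.
write_edf_synthetic <- function(data, fs, path, labels = rownames(data),
                                phys_range = c(-500, 500), dim = "uV") {
  ns <- nrow(data)
  spr <- as.integer(fs)                        # one-second records
  n_rec <- ncol(data) %/% spr
  stopifnot(n_rec >= 1L)
  pad <- function(x, w) {
    x <- substr(as.character(x), 1L, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_len <- 256L + 256L * ns
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8L); wr("X X X X", 80L); wr("Startdate X X X X", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L); wr(hdr_len, 8L); wr("", 44L)
  wr(n_rec, 8L); wr("1", 8L); wr(ns, 4L)
  for (l in labels) wr(l, 16L)
  for (i in seq_len(ns)) wr("synthetic", 80L)
  for (i in seq_len(ns)) wr(dim, 8L)
  for (i in seq_len(ns)) wr(phys_range[1], 8L)
  for (i in seq_len(ns)) wr(phys_range[2], 8L)
  for (i in seq_len(ns)) wr(-32768L, 8L)
  for (i in seq_len(ns)) wr(32767L, 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(spr, 8L)
  for (i in seq_len(ns)) wr("", 32L)
  scale <- 65535 / (phys_range[2] - phys_range[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- data[i, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - phys_range[1]) * scale) - 32768L)
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
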