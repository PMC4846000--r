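#' @useDynLib gaitatt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var rnorm runif rpois fft filter qnorm wilcox.test
#'   p.adjust predict quantile
NULL

# Electrode labels of the 32-site fronto-central/centro-parietal/occipital
# 10/10 montage, in amplifier channel order.
MONTAGE_LABELS <- c(
  "FZ",
  "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
  "C5", "C3", "C1", "CZ", "C2", "C4", "C6",
  "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
  "P5", "P3", "PZ", "P4", "P6",
  "PO7", "PO3", "POZ", "PO4", "PO8"
)

# Schematic 2-D scalp positions (unitless, head radius ~ 1, nose up).
# x: left negative / right positive; y: anterior positive.
MONTAGE_POSITIONS <- matrix(c(
   0.00,  0.50,                                              # FZ
  -0.60,  0.25, -0.40,  0.25, -0.20,  0.25,  0.00,  0.25,    # FC5 FC3 FC1 FCZ
   0.20,  0.25,  0.40,  0.25,  0.60,  0.25,                  # FC2 FC4 FC6
  -0.60,  0.00, -0.40,  0.00, -0.20,  0.00,  0.00,  0.00,    # C5 C3 C1 CZ
   0.20,  0.00,  0.40,  0.00,  0.60,  0.00,                  # C2 C4 C6
  -0.60, -0.25, -0.40, -0.25, -0.20, -0.25,  0.00, -0.25,    # CP5 CP3 CP1 CPZ
   0.20, -0.25,  0.40, -0.25,  0.60, -0.25,                  # CP2 CP4 CP6
  -0.60, -0.50, -0.40, -0.50,  0.00, -0.50,  0.40, -0.50,    # P5 P3 PZ P4
   0.60, -0.50,                                              # P6
  -0.55, -0.75, -0.30, -0.75,  0.00, -0.75,  0.30, -0.75,    # PO7 PO3 POZ PO4
   0.55, -0.75                                               # PO8
), ncol = 2, byrow = TRUE, dimnames = list(MONTAGE_LABELS, c("x", "y")))

#' Standard 32-electrode 10/10 montage
#'
#' Builds the montage used throughout the pipeline: the 32 fronto-central to
#' parieto-occipital electrode sites of the extended 10/10 system (FZ, FC5-FC6,
#' C5-C6, CP5-CP6, P5-P6, PO7-PO8 rows), with schematic 2-D scalp positions
#' and a neighbor relation derived from those positions.
#'
#' Two electrodes are neighbors when their distance does not exceed
#' `neighbor_factor` times the larger of their two nearest-neighbor distances.
#' Taking the larger of the two makes the relation symmetric while guaranteeing
#' that every electrode keeps at least its own nearest sites, so border
#' electrodes always have two or more neighbors.
#'
#' @param neighbor_factor Multiplier on the nearest-neighbor distance used to
#'   cut off the adjacency (default 1.3).
#' @return An object of class `montage`: a list with `names` (32 labels),
#'   `positions` (32 x 2 matrix) and `neighbors` (named list of character
#'   vectors).
#' @examples
#' m <- standard_montage()
#' m$neighbors$CZ
#' @export
standard_montage <- function(neighbor_factor = 1.3) {
  pos <- MONTAGE_POSITIONS
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  nb <- stats::setNames(vector("list", nrow(pos)), rownames(pos))
  for (i in seq_len(nrow(pos))) {
    cut <- neighbor_factor * pmax(nnd[i], nnd)
    nb[[i]] <- rownames(pos)[d[i, ] <= cut]
  }
  structure(
    list(names = rownames(pos), positions = pos, neighbors = nb,
         neighbor_factor = neighbor_factor),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$names), " electrodes: ",
      paste(utils::head(x$names, 6), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  if (anyDuplicated(m$names)) stop("montage labels must be unique")
  if (length(m$names) != nrow(m$positions)) {
    stop("montage positions must match labels")
  }
  for (e in m$names) {
    nbs <- m$neighbors[[e]]
    if (e %in% nbs) stop("neighbor relation must be irreflexive: ", e)
    if (length(nbs) < 2) stop("electrode with fewer than 2 neighbors: ", e)
    for (f in nbs) {
      if (!e %in% m$neighbors[[f]]) {
        stop("neighbor relation must be symmetric: ", e, "/", f)
      }
    }
  }
  invisible(m)
}

#' Export a montage as JSON
#'
#' @param montage A `montage` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage_json <- function(montage, path) {
  validate_montage(montage)
  obj <- list(
    names = montage$names,
    positions = as.data.frame(montage$positions),
    neighbors = montage$neighbors
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
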