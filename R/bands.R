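# Frequency-band selection by pairwise Bhattacharyya distance.

TASK_PAIRS <- c("AB", "AC", "AD", "BC", "BD", "CD")

#' Bhattacharyya distance between two feature sets
#'
#' Multivariate-Gaussian Bhattacharyya distance between the sample
#' distributions of two epoch x feature matrices:
#' \deqn{D = \tfrac18 (\mu_1-\mu_2)^T \bar\Sigma^{-1} (\mu_1-\mu_2)
#'   + \tfrac12 \ln\frac{\det \bar\Sigma}{\sqrt{\det\Sigma_1 \det\Sigma_2}},
#'   \quad \bar\Sigma = (\Sigma_1+\Sigma_2)/2 .}
#' Covariances are shrunk toward their diagonal
#' (\eqn{(1-\lambda)\Sigma + \lambda \,\mathrm{diag}(\Sigma)}) because
#' 32-dimensional covariances estimated from a few hundred epochs can be
#' ill-conditioned. Shrinkage leaves the two closed-form 1-D cases and the
#' zero distance between identical samples untouched.
#'
#' @param x1,x2 Numeric matrices, epochs x features (>= 2 epochs each).
#' @param shrinkage Shrinkage weight lambda toward the diagonal (default 0.1).
#' @param diagonal Use diagonal covariances only.
#' @return Non-negative distance; 0 for identical sample moments.
#' @export
bhattacharyya <- function(x1, x2, shrinkage = 0.1, diagonal = FALSE) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) < 2 || nrow(x2) < 2) stop("need at least 2 epochs per class")
  if (ncol(x1) != ncol(x2)) stop("feature dimensions differ")
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  reg <- function(x) {
    S <- stats::cov(x)
    if (diagonal) return(diag(diag(S), ncol(x)))
    (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(x))
  }
  S1 <- reg(x1); S2 <- reg(x2)
  Sbar <- (S1 + S2) / 2
  dm <- mu1 - mu2
  sol <- tryCatch(solve(Sbar, dm), error = function(e) {
    stop("numerical error: singular pooled covariance after regularization")
  })
  ld <- function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop("numerical error: non-positive-definite covariance")
    as.numeric(d$modulus)
  }
  as.numeric(sum(dm * sol) / 8 + 0.5 * (ld(Sbar) - 0.5 * (ld(S1) + ld(S2))))
}

#' Band x task-pair Bhattacharyya table
#'
#' Computes the Bhattacharyya distance for every pair of the four tasks
#' (AB, AC, AD, BC, BD, CD) in each of the six frequency bands.
#'
#' @param features Output of [extract_features()], or a pooled list of
#'   `band_features` (all four task labels must be present in every band).
#' @param ... Passed to [bhattacharyya()].
#' @return 6 x 6 numeric matrix (bands x pairs), class `bdist_table`.
#' @export
bdist_table <- function(features, ...) {
  out <- matrix(NA_real_, length(features), length(TASK_PAIRS),
                dimnames = list(names(features), TASK_PAIRS))
  for (b in names(features)) {
    bf <- features[[b]]
    if (!all(TASK_CODES %in% bf$labels)) {
      stop("missing task label(s) in band ", b)
    }
    for (p in TASK_PAIRS) {
      t1 <- substr(p, 1, 1); t2 <- substr(p, 2, 2)
      out[b, p] <- bhattacharyya(bf$values[bf$labels == t1, , drop = FALSE],
                                 bf$values[bf$labels == t2, , drop = FALSE],
                                 ...)
    }
  }
  class(out) <- c("bdist_table", class(out))
  out
}

#' Select separable frequency bands
#'
#' A band is selected when its Bhattacharyya distance meets the inclusive
#' `>= threshold` criterion on every designated task pair (the criterion that
#' maps to a ~0-2% two-class Bayes error at threshold 3.5).
#'
#' @param table A [bdist_table()].
#' @param threshold Selection threshold (default 3.5, inclusive).
#' @param pairs_of_interest Which pairs must pass (default: all six).
#' @return List with `selected` (band names), `pass` (logical bands x pairs
#'   matrix for the designated pairs).
#' @export
select_bands <- function(table, threshold = 3.5,
                         pairs_of_interest = colnames(table)) {
  pass <- unclass(table)[, pairs_of_interest, drop = FALSE] >= threshold
  list(selected = rownames(table)[rowSums(!pass) == 0], pass = pass)
}

#' Pool feature sets across sessions
#'
#' Row-binds per-band feature matrices from several sessions (e.g., all
#' healthy-subject sessions) before computing distances.
#'
#' @param feature_list List of [extract_features()] outputs.
#' @return A single feature map in the same format.
#' @export
pool_features <- function(feature_list) {
  bands <- names(feature_list[[1]])
  out <- lapply(bands, function(b) {
    structure(list(
      values = do.call(rbind, lapply(feature_list, function(f) f[[b]]$values)),
      labels = unlist(lapply(feature_list, function(f) f[[b]]$labels)),
      runs = unlist(lapply(feature_list, function(f) f[[b]]$runs)),
      band = b
    ), class = "band_features")
  })
  names(out) <- bands
  out
}
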