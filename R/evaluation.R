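# Finite-sample chance-level ranges (adjusted-Wald binomial interval) and
# rank-sum significance comparisons of classification results.

#' Ideal chance level
#'
#' Accuracy of an ideal random classifier on balanced classes: `100 / k` %.
#'
#' @param n_classes Number of balanced classes (>= 2).
#' @return Chance level in percent.
#' @export
ideal_chance <- function(n_classes) {
  if (n_classes < 2) stop("need at least 2 classes")
  100 / n_classes
}

#' Adjusted success-probability estimator
#'
#' The adjusted (add-two-successes, add-four-trials) estimator behind the
#' finite-sample chance interval: \eqn{\tilde p = (n \bar X + 2)/(n + 4)}.
#'
#' @param n Number of test epochs.
#' @param xbar Ideal random-classifier accuracy as a probability (e.g. 0.25
#'   for four balanced classes).
#' @return \eqn{\tilde p}.
#' @export
p_tilde <- function(n, xbar) {
  if (n < 0) stop("n must be >= 0")
  (n * xbar + 2) / (n + 4)
}

#' Finite-sample chance-level range
#'
#' Confidence interval around the accuracy of a random classifier evaluated
#' on `n` epochs (adjusted-Wald form):
#' \deqn{\tilde p \pm z_{1-\alpha/2}\sqrt{\tilde p(1-\tilde p)/(n+4)} .}
#' A single-fold classification result inside this range should be considered
#' indistinguishable from chance.
#'
#' @param n Number of test epochs (>= 1).
#' @param xbar Ideal random accuracy as a probability (default 0.25).
#' @param alpha Confidence parameter in (0, 1]; `alpha = 1` degenerates to a
#'   zero-width interval at \eqn{\tilde p}.
#' @return A `chance_range`: list with `lower`, `upper` (percent), `params`.
#' @export
chance_range <- function(n, xbar = 0.25, alpha = 0.05) {
  if (n < 1) stop("n must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("invalid alpha")
  if (xbar <= 0 || xbar >= 1) stop("xbar must be in (0, 1)")
  pt <- p_tilde(n, xbar)
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * sqrt(pt * (1 - pt) / (n + 4))
  structure(list(lower = 100 * (pt - hw), upper = 100 * (pt + hw),
                 params = list(n = n, xbar = xbar, alpha = alpha, z = z,
                               p_tilde = pt)),
            class = "chance_range")
}

#' @export
print.chance_range <- function(x, ...) {
  cat(sprintf("<chance_range> %.2f%% < rate < %.2f%% (n=%d, xbar=%.3g, alpha=%.3g)\n",
              x$lower, x$upper, x$params$n, x$params$xbar, x$params$alpha))
  invisible(x)
}

#' Compare success rates against the chance range
#'
#' For each classifier, pools its single-fold success rates and compares them
#' to an equally long vector of values drawn uniformly from the chance range,
#' using a two-sided Wilcoxon rank-sum test; p-values are Bonferroni-adjusted
#' across the classifiers compared.
#'
#' @param rates Named list: classifier -> numeric vector of fold success
#'   rates in percent (a single numeric vector is treated as one classifier).
#' @param range A [chance_range()].
#' @param seed Seed for the chance-vector draw (logged in the output).
#' @return Data frame with `classifier`, `n`, `mean_rate`, `p`, `p_adj`,
#'   `significant` (adjusted p < 0.05), `above_chance`.
#' @export
compare_to_chance <- function(rates, range, seed = 20160426L) {
  if (is.numeric(rates)) rates <- list(classifier = rates)
  if (any(lengths(rates) == 0)) stop("empty sample")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fam <- length(rates)
  rows <- lapply(names(rates), function(nm) {
    v <- rates[[nm]]
    chance <- stats::runif(length(v), range$lower, range$upper)
    p <- stats::wilcox.test(v, chance, exact = FALSE)$p.value
    data.frame(classifier = nm, n = length(v), mean_rate = mean(v), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * fam)
  out$significant <- out$p_adj < 0.05
  out$above_chance <- out$mean_rate > (range$lower + range$upper) / 2
  attr(out, "seed") <- seed
  out
}

#' Pairwise rank-sum comparisons of result groups
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups (e.g. the 10
#' classifier pairs of a 5-classifier family, or band/group contrasts), with
#' Bonferroni correction over the pairs in the table.
#'
#' @param groups Named list: group -> numeric vector of fold success rates
#'   (>= 2 values each).
#' @param bonferroni_family Family size for the correction; defaults to the
#'   number of pairs in the table.
#' @return List with `p` (symmetric raw p matrix), `p_adj`, `significant`
#'   (adjusted p < 0.05).
#' @export
pairwise_comparisons <- function(groups, bonferroni_family = NULL) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("degenerate group: < 2 fold values")
  nm <- names(groups)
  k <- length(nm)
  fam <- bonferroni_family %||% (k * (k - 1) / 2)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE)$p.value
      p[i, j] <- pv
      p[j, i] <- pv
    }
  }
  p_adj <- p
  p_adj[] <- pmin(1, p * fam)
  list(p = p, p_adj = p_adj, significant = p_adj < 0.05,
       bonferroni_family = fam)
}
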