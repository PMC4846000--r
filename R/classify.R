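# Run-wise 8-fold cross-validated multi-class decoding with the five
# classifiers of the study: RBF-kernel SVM (C = 512, kernel width 0.002),
# Gaussian naive Bayes, LDA, KNN (k = 30) and a decision tree.

CLASSIFIER_KINDS <- c("svm_rbf", "naive_bayes", "lda", "knn", "decision_tree")

#' Classifier specification
#'
#' @param kind One of `"svm_rbf"`, `"naive_bayes"`, `"lda"`, `"knn"`,
#'   `"decision_tree"`.
#' @param C SVM box constraint (default 512).
#' @param gamma_kernel RBF kernel width parameter (default 0.002).
#' @param k Number of neighbors for KNN (default 30).
#' @param min_split Minimum node size to attempt a split in the tree.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = CLASSIFIER_KINDS, C = 512,
                            gamma_kernel = 0.002, k = 30L, min_split = 2L) {
  kind <- match.arg(kind)
  if (C <= 0 || gamma_kernel <= 0 || k < 1 || min_split < 2) {
    stop("hyperparameters must be positive")
  }
  structure(list(kind = kind, C = C, gamma_kernel = gamma_kernel,
                 k = as.integer(k), min_split = as.integer(min_split)),
            class = "classifier_spec")
}

#' All five default classifier specifications
#' @return Named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function() {
  specs <- lapply(CLASSIFIER_KINDS, classifier_spec)
  names(specs) <- CLASSIFIER_KINDS
  specs
}

#' Run-wise cross-validation folds
#'
#' One fold per run: fold i tests on the epochs of run i and trains on the
#' other runs. The test folds partition the epochs.
#'
#' @param features A `band_features` object (epochs carry run indices).
#' @return List of `list(train, test)` index vectors, one per run.
#' @export
runwise_folds <- function(features) {
  runs <- features$runs
  ids <- sort(unique(runs))
  if (length(ids) < 2) stop("missing run structure: need >= 2 runs")
  lapply(ids, function(r) {
    list(train = which(runs != r), test = which(runs == r))
  })
}

# Gaussian naive Bayes (equal priors would match balanced tasks; empirical
# priors used, they coincide here).
nb_fit_predict <- function(xtr, ytr, xte) {
  classes <- sort(unique(ytr))
  eps <- 1e-12 * max(apply(xtr, 2, var), 1e-300)
  stats_by_class <- lapply(classes, function(c) {
    xc <- xtr[ytr == c, , drop = FALSE]
    list(mu = colMeans(xc), v = pmax(apply(xc, 2, var), eps),
         logprior = log(nrow(xc) / nrow(xtr)))
  })
  ll <- sapply(stats_by_class, function(s) {
    -0.5 * colSums((t(xte) - s$mu)^2 / s$v) -
      0.5 * sum(log(2 * pi * s$v)) + s$logprior
  })
  classes[max.col(ll, ties.method = "first")]
}

predict_fold <- function(spec, xtr, ytr, xte) {
  classes <- sort(unique(ytr))
  if (length(classes) < 2) stop("degenerate training fold: < 2 classes")
  yi <- match(ytr, classes) - 1L
  pred <- switch(
    spec$kind,
    svm_rbf = classes[.svm_ovo(xtr, yi, xte, spec$C, spec$gamma_kernel) + 1L],
    naive_bayes = nb_fit_predict(xtr, ytr, xte),
    lda = {
      fit <- MASS::lda(x = xtr, grouping = factor(ytr, levels = classes))
      as.character(stats::predict(fit, xte)$class)
    },
    knn = {
      if (spec$k > nrow(xtr)) stop("k exceeds the training-set size")
      classes[.knn_predict(xtr, yi, xte, spec$k) + 1L]
    },
    decision_tree = classes[.cart_fit_predict(xtr, yi, xte, spec$min_split) + 1L]
  )
  pred
}

#' Cross-validated evaluation of one classifier on one feature set
#'
#' @param features A `band_features` object.
#' @param spec A [classifier_spec()].
#' @param folds Folds from [runwise_folds()] (the default).
#' @param group Subject group tag carried into the result.
#' @return A `cv_result`: list with `rates` (per-fold % correct), `mean`,
#'   `sd`, `band`, `kind`, `group`.
#' @export
evaluate <- function(features, spec, folds = runwise_folds(features),
                     group = "healthy") {
  x <- features$values
  y <- features$labels
  rates <- vapply(folds, function(f) {
    pred <- predict_fold(spec, x[f$train, , drop = FALSE], y[f$train],
                         x[f$test, , drop = FALSE])
    100 * mean(pred == y[f$test])
  }, 0)
  structure(list(rates = rates, mean = mean(rates), sd = stats::sd(rates),
                 band = features$band, kind = spec$kind, group = group),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s [%s]: %.2f +/- %.2f %% (%d folds)\n",
              x$kind, x$band, x$group, x$mean, x$sd, length(x$rates)))
  invisible(x)
}

#' Evaluate a matrix of (session, band, classifier) combinations
#'
#' @param sessions List of per-session feature maps (outputs of
#'   [extract_features()]); each may carry a `group` attribute ("healthy" or
#'   "patient", default "healthy") and a `session` attribute (identifier).
#' @param specs List of [classifier_spec()] (default all five).
#' @param bands Band names to evaluate (default the two gamma bands).
#' @return Long data frame of single-fold results: `session`, `group`,
#'   `band`, `classifier`, `fold`, `rate`.
#' @export
run_matrix <- function(sessions, specs = default_classifiers(),
                       bands = c("gamma_low", "gamma_high")) {
  rows <- list()
  for (si in seq_along(sessions)) {
    feats <- sessions[[si]]
    grp <- attr(feats, "group") %||% "healthy"
    sid <- attr(feats, "session") %||% paste0("S", si)
    for (b in bands) {
      for (spec in specs) {
        cv <- evaluate(feats[[b]], spec, group = grp)
        rows[[length(rows) + 1L]] <- data.frame(
          session = sid, group = grp, band = b, classifier = spec$kind,
          fold = seq_along(cv$rates), rate = cv$rates,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group averages over pooled fold values
#'
#' Means and standard deviations per (group, band, classifier) computed over
#' all single-fold values pooled across sessions, not over session means.
#'
#' @param results Data frame from [run_matrix()].
#' @return Data frame with columns `group`, `band`, `classifier`, `mean`,
#'   `sd`, `n_folds`.
#' @export
group_summary <- function(results) {
  agg <- stats::aggregate(rate ~ group + band + classifier, data = results,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  out <- data.frame(agg[, c("group", "band", "classifier")],
                    mean = agg$rate[, "mean"], sd = agg$rate[, "sd"],
                    n_folds = agg$rate[, "n"])
  out
}
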