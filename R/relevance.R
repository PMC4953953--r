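#' Eigenvalue-based feature relevance ranking
#'
#' Standardizes the columns of the feature matrix, eigendecomposes the
#' feature correlation structure (via singular value decomposition of the
#' standardized matrix, so wide matrices never require a full feature-by-
#' feature eigenproblem), keeps the leading principal components reaching
#' `var_explained` of the total variance, and scores each feature by its
#' eigenvalue-weighted absolute loadings on those components:
#' \deqn{relevance_j = \sum_{i \le k} |v_{ij}| \lambda_i.}
#' Features with the highest overall correlation to the retained components
#' rank first. Constant columns get score 0.
#'
#' @param Xi Trials-by-features numeric matrix, at least 2 rows.
#' @param var_explained Fraction of variance the retained components must
#'   reach; default 0.9.
#' @return Object of class `relevance_ranking`: `relevance` (scores),
#'   `order` (feature indices by decreasing score), `n_components_kept`,
#'   `var_explained`.
#' @export
pca_relevance <- function(Xi, var_explained = 0.9) {
  Xi <- as.matrix(Xi)
  n <- nrow(Xi)
  if (n < 2) stop("need at least 2 trials")
  mu <- colMeans(Xi)
  sdv <- apply(Xi, 2, stats::sd)
  ok <- sdv > 0
  Z <- sweep(sweep(Xi[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")
  sv <- svd(Z)
  lambda <- sv$d^2 / (n - 1)
  cum <- cumsum(lambda) / sum(lambda)
  k <- which(cum >= var_explained)[1]
  V <- sv$v[, seq_len(k), drop = FALSE]
  score_ok <- as.numeric(abs(V) %*% lambda[seq_len(k)])
  relevance <- numeric(ncol(Xi))
  relevance[ok] <- score_ok
  names(relevance) <- colnames(Xi)
  structure(
    list(relevance = relevance,
         order = order(relevance, decreasing = TRUE),
         n_components_kept = k,
         var_explained = var_explained),
    class = "relevance_ranking"
  )
}

#' Select the most relevant features
#'
#' Returns the feature columns in ranking order, truncated either to the
#' first `k` or (default) to the smallest prefix holding `mass` of the total
#' relevance score.
#'
#' @param Xi Feature matrix.
#' @param ranking A `relevance_ranking` for `Xi`.
#' @param k Number of features to keep; overrides `mass` when given.
#' @param mass Fraction of total relevance the kept prefix must reach.
#' @return Matrix of selected columns (ranking order), with attribute
#'   `selected` (original column indices).
#' @export
select_features <- function(Xi, ranking, k = NULL, mass = 0.9) {
  ord <- ranking$order
  if (is.null(k)) {
    sc <- ranking$relevance[ord]
    tot <- sum(sc)
    if (tot <= 0) stop("empty selection: all relevance scores are zero")
    k <- which(cumsum(sc) / tot >= mass)[1]
  }
  if (k < 1 || k > ncol(Xi)) stop("k must be in 1..ncol(Xi)")
  sel <- ord[seq_len(k)]
  out <- Xi[, sel, drop = FALSE]
  attr(out, "selected") <- sel
  out
}

#' Binary emotion labels from 9-point ratings
#'
#' Thresholds self-assessment ratings at the scale midpoint: label `high`
#' iff rating > 5, otherwise `low` (a rating of exactly 5 is `low`).
#'
#' @param ratings Numeric vector in `[1, 9]`.
#' @param dimension Which affective dimension the ratings describe.
#' @return Object of class `label_set`: `ratings`, `labels` (factor
#'   low/high), `dimension`.
#' @export
make_labels <- function(ratings,
                        dimension = c("valence", "arousal", "dominance",
                                      "liking")) {
  dimension <- match.arg(dimension)
  if (any(!is.finite(ratings)) || any(ratings < 1) || any(ratings > 9)) {
    stop("ratings must lie in [1, 9]")
  }
  labels <- factor(ifelse(ratings > 5, "high", "low"),
                   levels = c("low", "high"))
  structure(list(ratings = ratings, labels = labels, dimension = dimension),
            class = "label_set")
}

#' Confusion counts, accuracy and F1 for binary low/high predictions
#'
#' Positive class is `high`. Accuracy = (TP + TN) / N and
#' F1 = 2 TP / (2 TP + FP + FN), both in percent.
#'
#' @param truth,pred Vectors of `"low"`/`"high"` values of equal length.
#' @return List with `confusion` (TP, FP, TN, FN), `accuracy`, `f1`.
#' @export
classification_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  conf <- c(TP = sum(pred == "high" & truth == "high"),
            FP = sum(pred == "high" & truth == "low"),
            TN = sum(pred == "low" & truth == "low"),
            FN = sum(pred == "low" & truth == "high"))
  list(confusion = conf,
       accuracy = unname(100 * (conf["TP"] + conf["TN"]) / length(truth)),
       f1 = unname(100 * 2 * conf["TP"] /
                     (2 * conf["TP"] + conf["FP"] + conf["FN"])))
}

#' Leave-one-out SVM evaluation
#'
#' For each trial in turn, the remaining trials alone are used to
#' standardize the features, rank them by [pca_relevance()], select the most
#' relevant subset, and train a soft-margin radial-basis SVM; the held-out
#' trial is then projected through the same standardization and selection
#' and predicted. No information from the held-out trial reaches any fitted
#' component. Aggregated over all folds, the function reports accuracy,
#' F1 for the positive class `high` (robust under class imbalance), the
#' confusion counts and the per-fold predictions.
#'
#' @param Xi Trials-by-features matrix (`N_tr >= 3`).
#' @param labels A `label_set` (or factor with levels low/high); both
#'   classes must be present.
#' @param var_explained Variance fraction for the per-fold relevance
#'   analysis (default 0.9).
#' @param mass Relevance-mass truncation rule for per-fold selection.
#' @param cost Soft-margin SVM cost (default 1).
#' @param gamma RBF kernel width; default `1 / n_selected_features` on the
#'   standardized scale.
#' @param method Free-form tag recorded in the result.
#' @return Object of class `evaluation_result`: `accuracy` and `f1` (in
#'   percent), `confusion`, `predictions`, `dimension`, `method`.
#' @export
loo_evaluate <- function(Xi, labels, var_explained = 0.9, mass = 0.9,
                         cost = 1, gamma = NULL, method = "features") {
  dimension <- if (inherits(labels, "label_set")) labels$dimension else NA
  y <- if (inherits(labels, "label_set")) labels$labels else
    factor(labels, levels = c("low", "high"))
  n <- nrow(Xi)
  if (n < 3) stop("need at least 3 trials")
  if (length(y) != n) stop("labels do not match trial count")
  if (nlevels(droplevels(y)) < 2) stop("degenerate labels: only one class")

  pred <- character(n)
  for (i in seq_len(n)) {
    tr_X <- Xi[-i, , drop = FALSE]
    tr_y <- droplevels(y[-i])
    if (nlevels(tr_y) < 2) {
      pred[i] <- as.character(tr_y[1])
      next
    }
    mu <- colMeans(tr_X)
    sdv <- apply(tr_X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Z <- sweep(sweep(tr_X, 2, mu), 2, sdv, "/")
    rk <- pca_relevance(Z, var_explained)
    Zs <- select_features(Z, rk, mass = mass)
    sel <- attr(Zs, "selected")
    g <- if (is.null(gamma)) 1 / ncol(Zs) else gamma
    fit <- e1071::svm(x = Zs, y = tr_y, kernel = "radial", cost = cost,
                      gamma = g, scale = FALSE)
    z_new <- (Xi[i, ] - mu) / sdv
    pred[i] <- as.character(stats::predict(fit,
                                           matrix(z_new[sel], nrow = 1)))
  }
  met <- classification_metrics(as.character(y), pred)
  structure(
    list(accuracy = met$accuracy, f1 = met$f1, confusion = met$confusion,
         predictions = factor(pred, levels = c("low", "high")),
         truth = y, dimension = dimension, method = method),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("LOO evaluation [%s%s]: accuracy %.2f%%, F1 %.2f%%\n",
              x$method,
              if (!is.na(x$dimension)) paste0(", ", x$dimension) else "",
              x$accuracy, x$f1))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  invisible(x)
}

#' One-sided paired t-test
#'
#' Classical paired t statistic on the differences `a - b`, with the
#' upper-tail alternative that the mean of `a` exceeds the mean of `b`.
#' When all differences are exactly zero the statistic is 0 and p = 0.5 by
#' symmetry; any other zero-variance difference vector is an error.
#'
#' @param a,b Equal-length numeric vectors (paired scores), length >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_onesided_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must have equal length >= 2")
  }
  d <- a - b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 0.5, df = n - 1, mean_diff = 0))
    }
    stop("zero-variance differences: paired t-test undefined")
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat, p = stats::pt(t_stat, df = n - 1, lower.tail = FALSE),
       df = n - 1, mean_diff = mean(d))
}
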