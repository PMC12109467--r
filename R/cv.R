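#' Enumerate exhaustive cross-validation splits
#'
#' Leave-two-out (LTOCV) enumerates all `choose(n, 2)` unordered validation
#' pairs in lexicographic order; leave-one-out (LOOCV) enumerates the `n`
#' validation singletons. Every split's training and validation indices are
#' disjoint and together cover all items.
#'
#' @param n_items Number of items (>= 3).
#' @param scheme `"ltocv"` or `"loocv"`.
#' @return List of splits, each `list(train = <indices>, validation = <indices>)`.
#' @examples
#' length(enumerate_splits(11, "ltocv")) # 55
#' @export
enumerate_splits <- function(n_items, scheme = c("ltocv", "loocv")) {
  scheme <- match.arg(scheme)
  if (n_items < 3) stop("need at least 3 items for exhaustive cross-validation")
  val_sets <- if (scheme == "ltocv") {
    utils::combn(n_items, 2, simplify = FALSE)
  } else {
    as.list(seq_len(n_items))
  }
  lapply(val_sets, function(v) list(train = setdiff(seq_len(n_items), v),
                                    validation = v))
}

#' ZeroR (training-majority) baseline accuracy
#'
#' For each exhaustive split, predicts the training set's majority outcome
#' for every validation item and pools the results. Majority ties are broken
#' toward the negative class `NO`. On the embedded cohort (8 NO / 3 YES)
#' every training majority is NO, giving 80/110 = 72.7% under LTOCV and
#' 8/11 = 72.7% under LOOCV.
#'
#' @param labels Character vector of `"YES"`/`"NO"` outcomes, one per item.
#' @param scheme `"ltocv"` or `"loocv"`.
#' @return Pooled baseline accuracy as a fraction in \[0, 1\].
#' @export
zeror_baseline <- function(labels, scheme = c("ltocv", "loocv")) {
  scheme <- match.arg(scheme)
  splits <- enumerate_splits(length(labels), scheme)
  correct <- 0L; total <- 0L
  for (sp in splits) {
    maj <- .majority_label(labels[sp$train])
    correct <- correct + sum(labels[sp$validation] == maj)
    total <- total + length(sp$validation)
  }
  correct / total
}

# majority label with ties toward the negative class
.majority_label <- function(labels) {
  n_yes <- sum(labels == "YES")
  if (n_yes > length(labels) - n_yes) "YES" else "NO"
}

#' Fit a principal component model on training rows
#'
#' Thin wrapper around [stats::prcomp()] fitting `n_components` components
#' on the training rows only, with per-variable centering and (by default)
#' unit-variance scaling computed from those rows. Scores can additionally
#' be whitened to unit training variance, which is how the cross-validation
#' engine consumes them (the two components then contribute equally to
#' K-nearest-neighbor distances). A zero-variance variable has its scale
#' reset to 1 with a warning rather than producing `NaN`s.
#'
#' @param x Numeric matrix/data frame of training rows.
#' @param n_components Number of components (default 2).
#' @param scale Unit-variance scaling of input variables (default `TRUE`).
#' @param whiten Rescale scores to unit training variance (default `TRUE`).
#' @return An object of class `pca_model` with a [predict()] method.
#' @export
fit_pca <- function(x, n_components = 2, scale = TRUE, whiten = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || any(colnames(x) == ""))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) <= n_components)
    stop("need more training rows than components")
  if (ncol(x) < n_components)
    stop("need at least ", n_components, " variables")
  sds <- apply(x, 2, stats::sd)
  if (scale && any(sds == 0)) {
    warning("zero-variance variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; scale set to 1")
  }
  scale_vec <- if (scale) ifelse(sds == 0, 1, sds) else FALSE
  pr <- stats::prcomp(x, center = TRUE, scale. = scale_vec, rank. = n_components)
  sdev <- pr$sdev[seq_len(n_components)]
  structure(list(prcomp = pr, n_components = n_components,
                 whiten = whiten, score_sd = ifelse(sdev == 0, 1, sdev)),
            class = "pca_model")
}

#' Project rows through a fitted PCA model
#'
#' @param object A `pca_model` from [fit_pca()].
#' @param newdata Rows to transform (matrix or data frame).
#' @param ... Unused.
#' @return Matrix of component scores (`n_components` columns).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- rownames(object$prcomp$rotation)
  z <- stats::predict(object$prcomp, newdata)[, seq_len(object$n_components), drop = FALSE]
  if (object$whiten) z <- sweep(z, 2, object$score_sd, "/")
  z
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- x$prcomp$sdev^2
  cat(sprintf("<pca_model: %d components, explained variance %s>\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * ev[seq_len(x$n_components)] / sum(ev)),
                    collapse = " + ")))
  invisible(x)
}

#' Deterministic K-nearest-neighbor prediction
#'
#' Euclidean-distance KNN with fully specified tie rules so that runs are
#' reproducible: distance ties are broken by training row order (stable
#' sort), and vote ties (possible for even `k`) are broken either toward the
#' training-majority class (`tie = "majority"`, the reproduction default;
#' majority ties fall back to `NO`) or by the single nearest neighbor's
#' label (`tie = "nearest"`). Features can be rescaled using training
#' statistics before distances are computed: min-max to \[0, 1\]
#' (`"minmax"`), z-scoring (`"zscore"`), or used as given (`"none"`).
#'
#' @param train_x Training feature matrix/data frame.
#' @param train_y Training labels (`"YES"`/`"NO"`).
#' @param query_x Query rows.
#' @param k Number of neighbors (1 <= k <= nrow(train_x)).
#' @param rescale Feature rescaling rule fitted on the training rows.
#' @param tie Vote tie rule, `"majority"` or `"nearest"`.
#' @return Character vector of predicted labels.
#' @examples
#' tr <- data.frame(x = c(0, 1, 2, 10, 11))
#' y <- c("NO", "NO", "NO", "YES", "YES")
#' knn_predict(tr, y, data.frame(x = 9), k = 3, rescale = "none") # "YES"
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 1,
                        rescale = c("minmax", "zscore", "none"),
                        tie = c("majority", "nearest")) {
  rescale <- match.arg(rescale)
  tie <- match.arg(tie)
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  if (nrow(train_x) == 0) stop("empty training set")
  if (k < 1 || k > nrow(train_x)) stop("k must be in [1, nrow(train_x)]")
  sc <- .fit_rescale(train_x, rescale)
  trZ <- .apply_rescale(train_x, sc)
  qZ <- .apply_rescale(query_x, sc)
  maj <- .majority_label(train_y)
  apply(qZ, 1, function(q) {
    d <- sqrt(colSums((t(trZ) - q)^2))
    ord <- order(d)                       # stable: distance ties by row order
    nb <- train_y[ord[seq_len(k)]]
    n_yes <- sum(nb == "YES")
    if (2 * n_yes == k) {
      if (tie == "majority") maj else nb[1]
    } else if (2 * n_yes > k) "YES" else "NO"
  })
}

.fit_rescale <- function(x, rescale) {
  switch(rescale,
    none = list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))),
    zscore = {
      s <- apply(x, 2, stats::sd)
      list(center = colMeans(x), scale = ifelse(s == 0, 1, s))
    },
    minmax = {
      lo <- apply(x, 2, min); hi <- apply(x, 2, max)
      list(center = lo, scale = ifelse(hi == lo, 1, hi - lo))
    })
}

.apply_rescale <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)
}

#' Classification metrics from a pooled confusion matrix
#'
#' Standard binary metrics with thrombosis `YES` as the positive class.
#' Precision and recall are `NA` when their denominator is zero; F1 is `NA`
#' whenever precision or recall is.
#'
#' @param cm Named numeric vector or list with `tp`, `fp`, `fn`, `tn`.
#' @return List with `accuracy`, `precision`, `recall`, `f1` (fractions).
#' @export
compute_metrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' Percentage rounded half away from zero
#'
#' Accuracy tables report percentages to 1 decimal place computed from the
#' exact integer counts; rounding is half away from zero (so 87.25 prints
#' as 87.3), never banker's rounding.
#'
#' @param fraction Value in \[0, 1\] (vectorized).
#' @param digits Decimal places, default 1.
#' @return Percentage.
#' @export
as_percent <- function(fraction, digits = 1) {
  m <- 10^digits
  sign(fraction) * floor(abs(fraction) * 100 * m + 0.5) / m
}
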