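#' Leave-one-trial-out SVM evaluation for one subject
#'
#' Every trial is held out once: the classifier trains on all segments of the
#' other trials and predicts the held-out trial's segments, so no segment of
#' a test trial can leak into training through within-trial correlation.
#' Features are z-scored with training-fold statistics only (constant
#' training features keep unit scale), then fed to a C-classification SVM
#' with RBF kernel at the classical LIBSVM defaults (cost 1, kernel width
#' `gamma = 1/n_features`).
#'
#' @param features A wide feature table from [feature_table()] (or
#'   [baseline_feature_table()]) restricted to one subject.
#' @param dimension `"valence"` or `"arousal"`.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` means
#'   `1/n_features`.
#' @param keep_fold_fits If `TRUE`, the returned report carries a
#'   `fold_fits` list (per held-out trial: training scaler mean/sd and the
#'   fitted SVM coefficients, rho and support indices) so leakage-freedom
#'   can be asserted: perturbing a held-out trial's features must leave its
#'   own fold's fit bit-identical.
#' @return An object of class `"loto_report"`: list with `per_fold` (tibble:
#'   `trial`, `n_test`, `n_correct`), `accuracy` (percent), `confusion`
#'   (2x2 matrix, predicted high/low x true high/low), `f1` (high class),
#'   `dimension`, `n_features`, `feature_cols` (and `fold_fits` when
#'   requested).
#' @examples
#' \donttest{
#' ds <- make_two_class_dataset(synthetic_spec(
#'   n_trials = 8, trial_sec = 10, n_channels = 2,
#'   informative_channels = 1:2, seed = 1))[[1]]
#' ft <- feature_table(ds, imf_levels = 1)
#' glance(loto_evaluate(ft, "valence"))
#' }
#' @export
loto_evaluate <- function(features, dimension = c("valence", "arousal"),
                          cost = 1, gamma = NULL, keep_fold_fits = FALSE) {
  dimension <- match.arg(dimension)
  if (length(unique(features$subject_id)) != 1) {
    abort_invalid_input("`features` must hold exactly one subject; see evaluate_subjects()")
  }
  trials <- unique(features$trial)
  if (length(trials) < 2) abort_invalid_input("need >= 2 trials for leave-one-trial-out")
  y <- features[[paste0(dimension, "_label")]]
  if (length(unique(y)) < 2) {
    abort_invalid_input("subject has a single class in this dimension")
  }
  meta_cols <- c("subject_id", "trial", "segment", "valence_rating",
                 "arousal_rating", "valence_label", "arousal_label")
  feat_cols <- setdiff(names(features), meta_cols)
  X <- as.matrix(features[feat_cols])
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(predicted = c("high", "low"),
                                      truth = c("high", "low")))
  fold_fits <- list()
  per_fold <- purrr::map_dfr(trials, function(t_out) {
    test <- features$trial == t_out
    if (length(unique(y[!test])) < 2) {
      # training fold degenerates to one class; count the fold as unpredictable
      return(tibble::tibble(trial = t_out, n_test = sum(test), n_correct = 0L))
    }
    mu <- colMeans(X[!test, , drop = FALSE])
    sds <- apply(X[!test, , drop = FALSE], 2, stats::sd)
    sds[sds < 1e-12] <- 1
    Ztr <- sweep(sweep(X[!test, , drop = FALSE], 2, mu), 2, sds, "/")
    Zte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sds, "/")
    fit <- e1071::svm(Ztr, y[!test], type = "C-classification",
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    pred <- predict(fit, Zte)
    if (keep_fold_fits) {
      fold_fits[[as.character(t_out)]] <<- list(
        mu = mu, sds = sds, rho = fit$rho, coefs = fit$coefs,
        index = fit$index)
    }
    for (p in c("high", "low")) for (tr in c("high", "low")) {
      confusion[p, tr] <<- confusion[p, tr] + sum(pred == p & y[test] == tr)
    }
    tibble::tibble(trial = t_out, n_test = sum(test),
                   n_correct = sum(pred == y[test]))
  })
  total <- sum(per_fold$n_test)
  structure(
    list(per_fold = per_fold,
         accuracy = 100 * sum(per_fold$n_correct) / total,
         confusion = confusion,
         f1 = f1_score(confusion),
         dimension = dimension,
         n_features = ncol(X),
         feature_cols = feat_cols,
         fold_fits = if (keep_fold_fits) fold_fits,
         subject_id = features$subject_id[1]),
    class = "loto_report"
  )
}

#' @export
print.loto_report <- function(x, ...) {
  cat(sprintf("<loto_report '%s' (%s): %.2f%% accuracy, F1 %.4f, %d folds, %d features>\n",
              x$subject_id, x$dimension, x$accuracy, x$f1,
              nrow(x$per_fold), x$n_features))
  invisible(x)
}

#' @describeIn loto_evaluate Per-fold tibble (`trial`, `n_test`, `n_correct`,
#'   `fold_accuracy` in percent).
#' @param x A `"loto_report"`.
#' @param ... Unused.
#' @method tidy loto_report
#' @export
tidy.loto_report <- function(x, ...) {
  dplyr::mutate(x$per_fold, fold_accuracy = 100 * .data$n_correct / .data$n_test)
}

#' @describeIn loto_evaluate One-row summary tibble (`subject_id`,
#'   `dimension`, `accuracy`, `f1`, confusion cells `tp`, `fp`, `fn`, `tn`,
#'   `n_folds`, `n_features`).
#' @method glance loto_report
#' @export
glance.loto_report <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(subject_id = x$subject_id, dimension = x$dimension,
                 accuracy = x$accuracy, f1 = x$f1,
                 tp = cm["high", "high"], fp = cm["high", "low"],
                 fn = cm["low", "high"], tn = cm["low", "low"],
                 n_folds = nrow(x$per_fold), n_features = x$n_features)
}

#' @describeIn loto_evaluate Per-fold accuracy plot.
#' @param object A `"loto_report"`.
#' @method autoplot loto_report
#' @export
autoplot.loto_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$fold_accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
    ggplot2::labs(x = "held-out trial", y = "fold accuracy (%)")
}

#' Evaluate many subjects and aggregate
#'
#' Runs [loto_evaluate()] per subject. Subjects whose ratings give a single
#' class in the requested dimension cannot be cross-validated and are
#' excluded from the averages with a message. Mean accuracy is the mean of
#' per-subject accuracies (each itself a mean over that subject's folds);
#' the confusion matrices and F1 are pooled over all included subjects.
#'
#' @inheritParams loto_evaluate
#' @return A tibble, one row per subject (columns as [glance()] of a
#'   `"loto_report"`, plus `included`), with attributes `mean_accuracy`,
#'   `sd_accuracy`, `pooled_confusion`, `pooled_f1`.
#' @export
evaluate_subjects <- function(features, dimension = c("valence", "arousal"),
                              cost = 1, gamma = NULL) {
  dimension <- match.arg(dimension)
  out <- purrr::map_dfr(split(features, features$subject_id), function(ft) {
    rep <- tryCatch(loto_evaluate(ft, dimension, cost = cost, gamma = gamma),
                    emdeeg_error_invalid_input = function(e) NULL)
    if (is.null(rep)) {
      message("subject ", ft$subject_id[1],
              " has one class in ", dimension, "; excluded")
      return(tibble::tibble(subject_id = ft$subject_id[1],
                            dimension = dimension, accuracy = NA_real_,
                            f1 = NA_real_, tp = NA_real_, fp = NA_real_,
                            fn = NA_real_, tn = NA_real_,
                            n_folds = NA_integer_, n_features = NA_integer_,
                            included = FALSE))
    }
    dplyr::mutate(glance(rep), included = TRUE)
  })
  inc <- out[out$included, ]
  pooled <- matrix(c(sum(inc$tp), sum(inc$fn), sum(inc$fp), sum(inc$tn)), 2, 2,
                   dimnames = list(predicted = c("high", "low"),
                                   truth = c("high", "low")))
  attr(out, "mean_accuracy") <- mean(inc$accuracy)
  attr(out, "sd_accuracy") <- stats::sd(inc$accuracy)
  attr(out, "pooled_confusion") <- pooled
  attr(out, "pooled_f1") <- f1_score(pooled)
  out
}

#' F1 score of the high class from a 2x2 confusion matrix
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall
#' for the `"high"` class; defined as 0 when precision + recall is 0.
#'
#' @param confusion 2x2 numeric matrix with dimnames
#'   `list(predicted = c("high","low"), truth = c("high","low"))`, or an
#'   unnamed 2x2 matrix in that orientation.
#' @return A number in `[0, 1]`.
#' @examples
#' cm <- matrix(c(6664, 2024, 2723, 3949), 2, 2) # predicted x truth
#' f1_score(cm) # 0.7374
#' @export
f1_score <- function(confusion) {
  if (!is.matrix(confusion) || !all(dim(confusion) == 2) ||
      any(confusion < 0) || sum(confusion) <= 0) {
    abort_invalid_input("`confusion` must be a nonnegative 2x2 matrix with positive total")
  }
  dn <- dimnames(confusion)
  if (!is.null(dn) && !is.null(dn[[1]])) {
    confusion <- confusion[c("high", "low"), c("high", "low")]
  }
  tp <- confusion[1, 1]; fp <- confusion[1, 2]; fn <- confusion[2, 1]
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Paired two-sided t-test between per-subject accuracies
#'
#' Compares two configurations evaluated on the same subjects. The verdict
#' is `"similar"` when `p > alpha` (the null hypothesis being that the two
#' configurations perform alike). Identical vectors give `p = 1`; a constant
#' nonzero difference has zero variance and no finite t statistic, which is
#' reported as an error rather than a fabricated p value.
#'
#' @param accuracies_a,accuracies_b Numeric vectors of per-subject
#'   accuracies (percent), equal length >= 3, paired by subject.
#' @param alpha Significance level. Default 0.05.
#' @return A one-row tibble: `statistic`, `p_value`, `similar` (logical).
#' @export
paired_ttest <- function(accuracies_a, accuracies_b, alpha = 0.05) {
  check_numeric_finite(accuracies_a, "accuracies_a")
  check_numeric_finite(accuracies_b, "accuracies_b")
  if (length(accuracies_a) != length(accuracies_b) || length(accuracies_a) < 3) {
    abort_invalid_input("need equal-length paired vectors with >= 3 subjects")
  }
  d <- accuracies_a - accuracies_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(statistic = 0, p_value = 1, similar = TRUE))
    }
    abort_degenerate_signal("constant nonzero paired differences: t statistic undefined")
  }
  tt <- stats::t.test(accuracies_a, accuracies_b, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 similar = tt$p.value > alpha)
}
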