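#' Two-class Fisher distance
#'
#' The classical two-class separability ratio
#' `(mean_a - mean_b)^2 / (var_a + var_b)` with unbiased (n-1) sample
#' variances: squared between-class scatter over summed within-class scatter.
#' It is invariant to a common affine shift and to a common nonzero scaling
#' of both classes. When the summed variance is below `1e-12` (degenerate,
#' e.g. constant features) the denominator is capped at `1e-12` and a warning
#' flags the score, keeping rankings total rather than producing infinities.
#'
#' @param class_a,class_b Numeric vectors, each with >= 2 finite values.
#' @return A single nonnegative number.
#' @examples
#' fisher_distance(c(0, 1), c(2, 3)) # 4
#' @export
fisher_distance <- function(class_a, class_b) {
  check_numeric_finite(class_a, "class_a")
  check_numeric_finite(class_b, "class_b")
  if (length(class_a) < 2 || length(class_b) < 2) {
    abort_invalid_input("each class needs >= 2 values")
  }
  num <- (mean(class_a) - mean(class_b))^2
  denom <- stats::var(class_a) + stats::var(class_b)
  if (denom < 1e-12) {
    warning("degenerate within-class variance; Fisher distance capped")
    denom <- 1e-12
  }
  num / denom
}

#' Rank channels by Fisher distance of a feature between the two classes
#'
#' For each channel, the Fisher distance of the named feature between the
#' low and high classes of `dimension` is computed from a labelled feature
#' table (see [feature_table()]). With several subjects in the table, scores
#' are computed per subject, channels are ranked within each subject, and
#' channels are ordered by their mean rank across subjects (mean score is
#' also reported); with one subject this reduces to ordering by score. Ties
#' break by the table's channel order, so the ranking is deterministic.
#' `feature = "all"` sums the three features' Fisher scores per channel
#' before ranking.
#'
#' @param features A wide feature table from [feature_table()].
#' @param dimension `"valence"` or `"arousal"`.
#' @param feature `"Dt"`, `"Dp"`, `"logEnorm"`, or `"all"`.
#' @param imf_level IMF level whose features are scored. Default 1.
#' @param top_k Optionally keep only the first `top_k` rows.
#' @return A tibble with columns `channel`, `feature`, `score` (mean across
#'   subjects), `mean_rank`, `rank`, ordered best first.
#' @export
rank_channels <- function(features, dimension = c("valence", "arousal"),
                          feature = c("Dt", "Dp", "logEnorm", "all"),
                          imf_level = 1L, top_k = NULL) {
  dimension <- match.arg(dimension)
  feature <- match.arg(feature)
  label_col <- paste0(dimension, "_label")
  labs <- features[[label_col]]
  if (length(unique(labs[!is.na(labs)])) < 2) {
    abort_invalid_input("both classes must be present to rank channels")
  }
  feats <- if (feature == "all") .feature_names else feature
  long <- features |>
    tidyr::pivot_longer(
      cols = dplyr::matches(paste0("_imf", imf_level, "_(",
                                   paste(.feature_names, collapse = "|"), ")$")),
      names_to = c("channel", "imf", "feat"), names_sep = "_",
      values_to = "value"
    ) |>
    dplyr::filter(.data$feat %in% feats)
  ch_order <- unique(long$channel)
  per_subject <- long |>
    dplyr::group_by(.data$subject_id, .data$channel, .data$feat) |>
    dplyr::summarise(
      score = fisher_distance(.data$value[.data[[label_col]] == "low"],
                              .data$value[.data[[label_col]] == "high"]),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$subject_id, .data$channel) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      channel = factor(.data$channel, levels = ch_order),
      subj_rank = rank(-.data$score, ties.method = "first")
    ) |>
    dplyr::ungroup()
  out <- per_subject |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(score = mean(.data$score),
                     mean_rank = mean(.data$subj_rank), .groups = "drop") |>
    dplyr::arrange(.data$mean_rank, .data$channel) |>
    dplyr::mutate(feature = feature, rank = dplyr::row_number(),
                  channel = as.character(.data$channel)) |>
    dplyr::select("channel", "feature", "score", "mean_rank", "rank")
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Plot Fisher-distance channel rankings
#'
#' @param ranking A tibble from [rank_channels()].
#' @return A ggplot bar chart, channels ordered by rank.
#' @export
plot_channel_ranking <- function(ranking) {
  ranking$channel <- factor(ranking$channel, levels = rev(ranking$channel))
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$score, y = .data$channel)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Fisher distance", y = NULL)
}
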