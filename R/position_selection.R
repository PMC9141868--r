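#' Keep predictive (position, residue) features
#'
#' A feature survives when its scaled importance exceeds `importance_min`
#' and its model's cross-validated best-class AUC exceeds `auc_min` (both
#' strict). Defaults reproduce the published gates (importance > 10,
#' AUC > 0.7).
#'
#' @param results An `or_importance_set` from [run_all_pairs()], or a tidy
#'   importance tibble with columns `dataset_id`, `chemical_id`, `position`,
#'   `residue`, `importance`, `model_auc`.
#' @param importance_min,auc_min Gate thresholds.
#' @return A tibble of kept features, one row per
#'   (dataset, chemical, position, residue).
#' @export
filter_features <- function(results, importance_min = 10, auc_min = 0.7) {
  tab <- if (inherits(results, "or_importance_set")) tidy(results) else as_tibble(results)
  tab |>
    filter(.data$importance > importance_min, .data$model_auc > auc_min)
}

#' Rank alignment positions by how often they are predictive
#'
#' `times_predictive` of a position is the number of kept
#' (residue, chemical) features at that position within a dataset: the same
#' position counts once per predictive residue per chemical. Ties are broken
#' by the maximum importance observed at the position, then by ascending
#' position index, so rankings are deterministic.
#'
#' @param features Kept-feature tibble from [filter_features()].
#' @param dataset Optional single dataset id to restrict to.
#' @return A tibble (`dataset_id`, `position`, `times_predictive`,
#'   `max_importance`) sorted within dataset by the ranking order.
#' @export
rank_positions <- function(features, dataset = NULL) {
  if (!is.null(dataset)) features <- features[features$dataset_id %in% dataset, ]
  if (nrow(features) == 0) {
    warn("no kept features; empty ranking")
    return(tibble(
      dataset_id = character(), position = integer(),
      times_predictive = integer(), max_importance = double()
    ))
  }
  features |>
    group_by(.data$dataset_id, .data$position) |>
    summarise(
      times_predictive = n(),
      max_importance = max(.data$importance),
      .groups = "drop"
    ) |>
    arrange(
      .data$dataset_id, desc(.data$times_predictive),
      desc(.data$max_importance), .data$position
    )
}

#' Union of each dataset's top-k predictive positions
#'
#' @param rankings A ranking tibble from [rank_positions()] (any number of
#'   datasets), or a list of such tibbles.
#' @param k Positions to take per dataset (default 10).
#' @return Sorted integer vector of distinct alignment positions.
#' @export
union_top_positions <- function(rankings, k = 10) {
  if (is.list(rankings) && !is.data.frame(rankings)) rankings <- list_rbind(rankings)
  if (nrow(rankings) == 0) abort("empty rankings")
  tops <- rankings |>
    group_by(.data$dataset_id) |>
    slice_head(n = k) |>
    ungroup()
  short <- tops |> count(.data$dataset_id) |> filter(.data$n < k)
  if (nrow(short) > 0) {
    inform(paste0(
      "rankings shorter than k for: ",
      paste(short$dataset_id, collapse = ", "), "; taking all"
    ))
  }
  sort(unique(tops$position))
}
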