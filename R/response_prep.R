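#' Select training chemicals by data availability
#'
#' Counts tested (non-missing) protein-chemical cells per chemical over the
#' union of all datasets and keeps chemicals with strictly more than
#' `min_values` values, most-tested first. On the three published insect
#' panels this rule selects the 8 most profiled of 672 chemicals.
#'
#' @param responses Long response tibble (`dataset_id`, `protein_id`,
#'   `chemical_id`, `value`) as returned by [read_responses()].
#' @param min_values Minimum tested-value count (strict `>`).
#' @return A tibble (`chemical_id`, `n_values`), sorted by `n_values`
#'   descending; possibly zero rows.
#' @export
select_chemicals <- function(responses, min_values = 100) {
  responses |>
    filter(!is.na(.data$value)) |>
    count(.data$chemical_id, name = "n_values") |>
    filter(.data$n_values > min_values) |>
    arrange(desc(.data$n_values), .data$chemical_id)
}

#' Binarize chemical responses at the 75th percentile
#'
#' Within each (dataset, chemical), responses strictly greater than the 75th
#' percentile of that chemical's tested values become 1 (responder), all
#' other tested values 0; untested cells stay untested. Binarization is
#' never pooled across datasets, so heterogeneous measurement units cannot
#' leak between panels. Ties at the threshold are 0 by the strict
#' inequality.
#'
#' @param responses Long response tibble.
#' @param method Percentile estimator: `"interpolate"` (linear interpolation
#'   between order statistics, [stats::quantile()] type 7) or `"nearest"`
#'   (nearest-rank, type 1).
#' @return The input tibble with an added integer column `bin`.
#' @export
binarize_responses <- function(responses, method = c("interpolate", "nearest")) {
  method <- match.arg(method)
  qtype <- if (method == "interpolate") 7 else 1
  responses |>
    group_by(.data$dataset_id, .data$chemical_id) |>
    mutate(bin = {
      v <- .data$value
      ok <- !is.na(v)
      if (!any(ok)) {
        warn(sprintf(
          "chemical %s in dataset %s has no tested values; skipped",
          .data$chemical_id[1], .data$dataset_id[1]
        ))
        rep(NA_integer_, length(v))
      } else {
        thr <- quantile(v[ok], 0.75, type = qtype, names = FALSE)
        as.integer(v > thr)
      }
    }) |>
    ungroup()
}
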