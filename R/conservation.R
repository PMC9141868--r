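#' Per-column conservation scores within clusters
#'
#' The conservation score of an alignment column within a cluster is the
#' frequency of its modal residue among the cluster's members: 1 means fully
#' conserved, values near 0 mean highly variable. Gaps and `"X"` are not
#' residues: by default they are excluded from both the modal count and the
#' denominator, and a column where no member carries a residue receives no
#' score. Setting `gap_as_state = TRUE` instead treats `"-"` as an ordinary
#' 21st state (`"X"` is always excluded).
#'
#' @param family An [or_family()].
#' @param clusters Tibble (`seq_id`, `cluster_id`).
#' @param cluster Optional cluster id(s) to restrict to.
#' @param min_size Minimum cluster size to score (default 5).
#' @param gap_as_state Count the gap character as a residue state.
#' @return A tibble (`cluster_id`, `position`, `conservation`, `n_counted`);
#'   `conservation` is `NA` where `n_counted` is 0.
#' @export
position_conservation <- function(family, clusters, cluster = NULL,
                                  min_size = 5, gap_as_state = FALSE) {
  sizes <- count(clusters, .data$cluster_id)
  keep <- sizes$cluster_id[sizes$n >= min_size]
  if (!is.null(cluster)) keep <- intersect(keep, cluster)
  if (length(keep) == 0) {
    return(tibble(
      cluster_id = character(), position = integer(),
      conservation = double(), n_counted = integer()
    ))
  }
  m <- seq_matrix(family)
  excluded <- if (gap_as_state) "X" else c("X", "-")
  out <- map(keep, function(cid) {
    ids <- clusters$seq_id[clusters$cluster_id == cid]
    sub <- m[ids, , drop = FALSE]
    scores <- apply(sub, 2, function(col) {
      col <- col[!col %in% excluded]
      if (length(col) == 0) return(c(NA_real_, 0))
      tab <- tabulate(factor(col, levels = unique(col)))
      c(max(tab) / length(col), length(col))
    })
    tibble(
      cluster_id = cid, position = seq_len(ncol(sub)),
      conservation = scores[1, ], n_counted = as.integer(scores[2, ])
    )
  })
  list_rbind(out)
}

#' Predictive versus background conservation per cluster
#'
#' For each cluster with at least `min_size` members, computes the
#' background conservation `c_bg` (mean per-column score over all scored
#' columns), the predictive conservation `c_pred` (mean over the supplied
#' predictive positions) and their ratio `c_pred / c_bg`. A ratio above 1
#' indicates a binding site more conserved than the rest of the protein,
#' the signature of receptors tuned to a narrow set of ligands; below 1, a
#' binding site more variable than background.
#'
#' @inheritParams position_conservation
#' @param predictive_positions Non-empty integer vector of alignment
#'   columns (e.g. from [union_top_positions()]).
#' @return A tibble of class `or_conservation` (`cluster_id`, `n_members`,
#'   `c_bg`, `c_pred`, `ratio`), one row per qualifying cluster.
#' @export
cluster_conservation <- function(family, clusters, predictive_positions,
                                 min_size = 5, gap_as_state = FALSE) {
  if (length(predictive_positions) == 0) abort("empty predictive position set")
  predictive_positions <- as.integer(predictive_positions)
  if (any(predictive_positions < 1) || any(predictive_positions > n_columns(family))) {
    abort("predictive positions outside alignment bounds")
  }
  scores <- position_conservation(family, clusters,
    min_size = min_size, gap_as_state = gap_as_state
  )
  sizes <- count(clusters, .data$cluster_id, name = "n_members")
  out <- scores |>
    group_by(.data$cluster_id) |>
    summarise(
      c_bg = mean(.data$conservation, na.rm = TRUE),
      c_pred = mean(.data$conservation[.data$position %in% predictive_positions],
        na.rm = TRUE
      ),
      .groups = "drop"
    ) |>
    mutate(ratio = .data$c_pred / .data$c_bg) |>
    left_join(sizes, by = "cluster_id") |>
    select("cluster_id", "n_members", "c_bg", "c_pred", "ratio")
  class(out) <- unique(c("or_conservation", class(out)))
  out
}
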