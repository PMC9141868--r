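#' Build the machine-learning design table from an alignment
#'
#' One row per sequence, one column per alignment position (`pos1`,
#' `pos2`, ...), each cell the residue character at that position. A
#' position is a machine-learning *variable*; a residue at a position is a
#' *feature*. The gap character `"-"` is a first-class category: indel
#' presence can itself be predictive.
#'
#' @param family An [or_family()].
#' @param subset Optional character vector of seq_ids (default: all).
#' @return A tibble of class `or_features` with a `seq_id` column followed
#'   by one character column per position; the `retained_positions`
#'   attribute holds the 1-based positions the columns correspond to.
#' @export
build_feature_table <- function(family, subset = NULL) {
  if (is.null(subset)) subset <- family$seq_id
  if (length(subset) == 0) abort("empty sequence subset")
  unknown <- setdiff(subset, family$seq_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown seq_ids in subset: ", paste(head(unknown, 5), collapse = ", ")))
  }
  m <- seq_matrix(family)[subset, , drop = FALSE]
  colnames(m) <- paste0("pos", seq_len(ncol(m)))
  out <- tibble(seq_id = subset, as_tibble(m))
  attr(out, "retained_positions") <- seq_len(ncol(m))
  class(out) <- unique(c("or_features", class(out)))
  out
}

#' @rdname build_feature_table
#' @param x An `or_features` table.
#' @export
retained_positions <- function(x) attr(x, "retained_positions")

#' Drop near-zero-variance alignment columns
#'
#' Removes positions that carry (almost) no information for model training:
#' a column is dropped when it is constant, or when the frequency ratio of
#' its most common to second most common residue exceeds `freq_cut` *and*
#' its number of distinct residues is below `unique_cut` percent of the rows
#' (the conventional 95/5 rule, `freq_cut = 19`). Delegates to
#' [caret::nearZeroVar()].
#'
#' @param table An `or_features` table from [build_feature_table()].
#' @param freq_cut,unique_cut Thresholds as in [caret::nearZeroVar()].
#' @return The filtered `or_features` table with `retained_positions`
#'   updated. Idempotent, and independent of row order.
#' @export
filter_near_zero_variance <- function(table, freq_cut = 19, unique_cut = 10) {
  pos <- retained_positions(table)
  cells <- as.data.frame(table[, -1, drop = FALSE])
  drop <- caret::nearZeroVar(cells, freqCut = freq_cut, uniqueCut = unique_cut)
  if (length(drop) == ncol(cells)) {
    abort("all alignment columns were dropped as near-zero variance; lower freq_cut")
  }
  if (length(drop) > 0) {
    inform(sprintf("dropped %d near-zero-variance position(s)", length(drop)))
    table <- table[, c(1L, 1L + setdiff(seq_along(pos), drop)), drop = FALSE]
    pos <- pos[-drop]
  }
  attr(table, "retained_positions") <- pos
  class(table) <- unique(c("or_features", class(table)))
  table
}

# One-hot encode an or_features table into a numeric matrix whose columns are
# named p<position>_<residue> (gap "-" becomes "gap"). "X" (unknown residue)
# gets no indicator column: an X row is simply zero across that position.
#
# Indicators observed in fewer than min_support sequences (or absent in fewer
# than min_support) are dropped: a residue seen once or twice cannot support a
# generalizable split and such rare indicators mostly inject impurity-
# importance noise. The support floor is capped at n/4 so tiny tables are
# never emptied.
encode_features <- function(table, min_support = 5L) {
  pos <- retained_positions(table)
  n <- nrow(table)
  eff <- max(1L, min(as.integer(min_support), n %/% 4L))
  mats <- vector("list", length(pos))
  for (j in seq_along(pos)) {
    col <- table[[j + 1L]]
    lev <- sort(setdiff(unique(col), "X"))
    m <- matrix(0L, nrow = n, ncol = length(lev))
    for (k in seq_along(lev)) m[, k] <- as.integer(col == lev[k])
    colnames(m) <- paste0("p", pos[j], "_", if_else(lev == "-", "gap", lev))
    mats[[j]] <- m
  }
  out <- do.call(cbind, mats)
  rownames(out) <- table$seq_id
  keep <- colSums(out) >= eff & colSums(out) <= n - eff
  if (!any(keep)) return(out)
  out[, keep, drop = FALSE]
}

# Inverse of encode_features' naming: "p12_A" -> (12, "A"); "p12_gap" -> (12, "-")
decode_feature_names <- function(nms) {
  m <- stringr::str_match(nms, "^p(\\d+)_(.+)$")
  tibble(
    position = as.integer(m[, 2]),
    residue = if_else(m[, 3] == "gap", "-", m[, 3])
  )
}
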