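#' Map alignment columns to a reference sequence's residue numbers
#'
#' Column `p` maps to the number of non-gap reference characters at columns
#' `<= p` when the reference row is non-gap at `p`; columns where the
#' reference is gapped are unmapped (`NA`). Residue numbering is 1-based on
#' the ungapped reference.
#'
#' @param family An [or_family()].
#' @param reference_seq_id seq_id of the reference (linking) sequence.
#' @return A tibble (`column`, `ref_index`), strictly increasing over
#'   mapped rows.
#' @export
column_to_reference <- function(family, reference_seq_id) {
  i <- match(reference_seq_id, family$seq_id)
  if (is.na(i)) abort(sprintf("reference id '%s' absent from the alignment", reference_seq_id))
  chars <- strsplit(family$aligned_seq[i], "", fixed = TRUE)[[1]]
  non_gap <- chars != "-"
  tibble(
    column = seq_along(chars),
    ref_index = if_else(non_gap, cumsum(non_gap), NA_integer_)
  )
}

#' Residue correspondence between a reference and a template sequence
#'
#' Globally aligns the two (ungapped) protein sequences with
#' [Biostrings::pairwiseAlignment()] (affine gaps) and returns the
#' residue-to-residue correspondence; template indices are shifted by
#' `numbering_offset` to match an external numbering frame such as a solved
#' structure's. A percent identity below `min_identity` triggers a warning
#' that the mapping is unreliable.
#'
#' @param reference_seq,template_seq Protein sequences (plain strings; any
#'   gap characters are stripped).
#' @param numbering_offset Added to template residue indices.
#' @param substitution_matrix,gap_opening,gap_extension Alignment
#'   parameters, logged in the result's attributes.
#' @param min_identity Identity floor (fraction) below which to warn.
#' @return A tibble (`ref_index`, `template_index`) over aligned residue
#'   pairs; both columns strictly increasing.
#' @export
reference_to_template <- function(reference_seq, template_seq,
                                  numbering_offset = 0L,
                                  substitution_matrix = "BLOSUM62",
                                  gap_opening = 10, gap_extension = 0.5,
                                  min_identity = 0.2) {
  ref <- gsub("-", "", toupper(reference_seq), fixed = TRUE)
  tmpl <- gsub("-", "", toupper(template_seq), fixed = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(tmpl),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pid <- Biostrings::pid(aln) / 100
  if (pid < min_identity) {
    warn(sprintf(
      "reference-template identity %.1f%% below %.0f%%; mapping may be unreliable",
      pid * 100, min_identity * 100
    ))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ri <- cumsum(p != "-")
  ti <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  out <- tibble(
    ref_index = ri[both],
    template_index = ti[both] + as.integer(numbering_offset)
  )
  attr(out, "parameters") <- list(
    substitution_matrix = substitution_matrix, gap_opening = gap_opening,
    gap_extension = gap_extension, percent_identity = pid * 100,
    numbering_offset = numbering_offset
  )
  out
}

#' Full alignment-column to template-residue map
#'
#' Composes [column_to_reference()] with [reference_to_template()] into a
#' single table: alignment column, reference residue index, template
#' residue index; `NA` where unmapped.
#'
#' @inheritParams column_to_reference
#' @param template_seq Template protein sequence (e.g. the only solved
#'   structure of the family), or `NULL` to map to the reference only.
#' @param ... Passed to [reference_to_template()].
#' @return A tibble of class `or_position_map` (`column`, `ref_index`,
#'   `template_index`).
#' @export
position_map <- function(family, reference_seq_id, template_seq = NULL, ...) {
  c2r <- column_to_reference(family, reference_seq_id)
  if (is.null(template_seq)) {
    out <- mutate(c2r, template_index = NA_integer_)
  } else {
    i <- match(reference_seq_id, family$seq_id)
    r2t <- reference_to_template(family$aligned_seq[i], template_seq, ...)
    out <- left_join(c2r, r2t, by = "ref_index")
  }
  class(out) <- unique(c("or_position_map", class(out)))
  out
}

#' Annotation table for a set of alignment positions
#'
#' Formats a set of positions (for instance the top predictive positions)
#' as a publication-style table: alignment column, reference residue number
#' and template residue number, with `"-"` for unmapped coordinates, plus a
#' free-form label per position.
#'
#' @param positions Integer vector of alignment columns.
#' @param map An [position_map()] result.
#' @param labels Optional character vector parallel to `positions` (e.g.
#'   `"top10"`, `"experimental"`); recycled if length 1.
#' @return A tibble (`column`, `ref_residue`, `template_residue`, `label`)
#'   with character residue columns using `"-"` for unmapped.
#' @export
annotate_positions <- function(positions, map, labels = "top10") {
  if (length(positions) == 0) {
    return(tibble(
      column = integer(), ref_residue = character(),
      template_residue = character(), label = character()
    ))
  }
  labels <- rep_len(labels, length(positions))
  idx <- match(positions, map$column)
  fmt <- function(v) if_else(is.na(v), "-", as.character(v))
  tibble(
    column = as.integer(positions),
    ref_residue = fmt(map$ref_index[idx]),
    template_residue = fmt(map$template_index[idx]),
    label = labels
  )
}
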