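#' Aligned protein family objects
#'
#' An `or_family` is a tibble with one row per aligned sequence and columns
#' `seq_id`, `species_id` and `aligned_seq`. All `aligned_seq` strings have
#' identical length (the alignment width, stored in the `n_columns`
#' attribute); alignment columns are numbered 1-based throughout the package.
#' Only the 20 amino-acid one-letter codes, `"X"` (unknown residue, ignored
#' by all counting operations) and the gap character `"-"` may occur.
#'
#' @param seq_id,species_id,aligned_seq Character vectors of equal length.
#' @return A tibble of class `or_family`.
#' @examples
#' fam <- or_family(c("Sp1_a", "Sp2_b"), c("Sp1", "Sp2"), c("AC-G", "AAAG"))
#' n_columns(fam)
#' @export
or_family <- function(seq_id, species_id, aligned_seq) {
  out <- tibble(
    seq_id = as.character(seq_id),
    species_id = as.character(species_id),
    aligned_seq = toupper(as.character(aligned_seq))
  )
  validate_or_family(out)
}

validate_or_family <- function(x) {
  if (nrow(x) == 0) abort("an aligned family needs at least one sequence")
  if (anyDuplicated(x$seq_id)) {
    abort(paste0(
      "duplicated seq_id: ",
      paste(unique(x$seq_id[duplicated(x$seq_id)]), collapse = ", ")
    ))
  }
  widths <- nchar(x$aligned_seq)
  if (length(unique(widths)) > 1L) {
    ref <- max(widths)
    bad <- x$seq_id[widths != ref]
    abort(paste0(
      "alignment error: sequences differ in length; offending ids: ",
      paste(bad, collapse = ", ")
    ))
  }
  bad_char <- stringr::str_locate(x$aligned_seq,
                                  paste0("[^", paste(AA_LETTERS, collapse = ""), "X\\-]"))[, 1]
  if (any(!is.na(bad_char))) {
    i <- which(!is.na(bad_char))[1]
    abort(sprintf(
      "validation error: illegal character '%s' in %s at column %d",
      substr(x$aligned_seq[i], bad_char[i], bad_char[i]), x$seq_id[i], bad_char[i]
    ))
  }
  attr(x, "n_columns") <- widths[1]
  class(x) <- unique(c("or_family", class(x)))
  x
}

#' @rdname or_family
#' @param x An `or_family`.
#' @export
n_columns <- function(x) {
  attr(x, "n_columns") %||% nchar(x$aligned_seq[1])
}

#' Residue matrix view of an aligned family
#'
#' @param family An [or_family()].
#' @return A character matrix, one row per sequence (rownames are `seq_id`),
#'   one column per alignment position.
#' @export
seq_matrix <- function(family) {
  m <- do.call(rbind, strsplit(family$aligned_seq, "", fixed = TRUE))
  rownames(m) <- family$seq_id
  m
}

#' Read an aligned FASTA file into an `or_family`
#'
#' The species of each sequence is taken, in order of precedence, from a
#' sidecar `species_map` (seq_id -> species_id), or from the header via
#' `species_parser` (default: the prefix before the first underscore).
#' Real chemoreceptor datasets have heterogeneous naming, hence the override.
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param species_parser Function mapping a seq_id to a species_id.
#' @param species_map Optional data frame with columns `seq_id`, `species_id`.
#' @return An [or_family()].
#' @export
read_aligned_fasta <- function(path,
                               species_parser = function(id) sub("_.*$", "", id),
                               species_map = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  if (!is.null(species_map)) {
    sp <- setNames(as.character(species_map$species_id), species_map$seq_id)
    species <- unname(sp[ids])
    missing <- is.na(species)
    species[missing] <- vapply(ids[missing], species_parser, character(1))
  } else {
    species <- vapply(ids, species_parser, character(1))
  }
  or_family(ids, species, seqs)
}

#' @rdname read_aligned_fasta
#' @param family An [or_family()] to write.
#' @export
write_aligned_fasta <- function(family, path) {
  lines <- as.vector(rbind(paste0(">", family$seq_id), family$aligned_seq))
  writeLines(lines, path)
  invisible(path)
}

#' Species taxonomy with sociality flags
#'
#' A nested taxonomy is stored as two tibbles: `species` (`species_id`,
#' `social`) and `taxa` in long form (`taxon_code`, `parent_code`,
#' `species_id`), one row per (taxon, member species). The membership sets
#' must form a tree: every child taxon's members are a subset of its
#' parent's, and the root taxon (with empty/NA parent) contains all species.
#'
#' @param taxa Tibble with columns `taxon_code`, `parent_code`, `species_id`.
#' @param social Tibble with columns `species_id`, `social` (logical).
#' @return A list of class `or_taxonomy` with elements `species` and `taxa`.
#' @export
or_taxonomy <- function(taxa, social) {
  taxa <- as_tibble(taxa)[, c("taxon_code", "parent_code", "species_id")]
  taxa$parent_code[taxa$parent_code %in% c("", "-")] <- NA_character_
  species <- as_tibble(social)
  species$social <- as.logical(species$social)
  obj <- structure(list(species = species, taxa = taxa), class = "or_taxonomy")
  validate_or_taxonomy(obj)
}

validate_or_taxonomy <- function(tax) {
  members <- split(tax$taxa$species_id, tax$taxa$taxon_code)
  if (any(lengths(members) == 0)) abort("taxonomy error: empty taxon member set")
  parent_of <- tax$taxa |>
    distinct(.data$taxon_code, .data$parent_code) |>
    (\(d) setNames(d$parent_code, d$taxon_code))()
  roots <- names(parent_of)[is.na(parent_of)]
  if (length(roots) != 1) {
    abort("taxonomy error: expected exactly one root taxon (empty parent_code)")
  }
  for (tx in names(parent_of)) {
    p <- parent_of[[tx]]
    if (is.na(p)) next
    if (!p %in% names(members)) {
      abort(sprintf("taxonomy error: parent taxon '%s' of '%s' is undefined", p, tx))
    }
    extra <- setdiff(members[[tx]], members[[p]])
    if (length(extra) > 0) {
      abort(sprintf(
        "taxonomy error: taxon '%s' has species not in its parent '%s': %s",
        tx, p, paste(extra, collapse = ", ")
      ))
    }
  }
  all_sp <- unique(tax$species$species_id)
  missing_root <- setdiff(all_sp, members[[roots]])
  if (length(missing_root) > 0) {
    abort(sprintf(
      "taxonomy error: root taxon '%s' is missing species: %s",
      roots, paste(missing_root, collapse = ", ")
    ))
  }
  tax
}

#' Species belonging to one taxon
#' @param taxonomy An [or_taxonomy()].
#' @param taxon_code Single taxon code.
#' @return Character vector of species ids.
#' @export
taxon_species <- function(taxonomy, taxon_code) {
  unique(taxonomy$taxa$species_id[taxonomy$taxa$taxon_code == taxon_code])
}

#' Read the tabular pipeline inputs
#'
#' `read_clusters()` reads a TSV with columns `seq_id`, `cluster_id`;
#' `read_taxonomy()` a TSV with columns `taxon_code`, `parent_code`,
#' `species_id`, `social`; `read_responses()` one or more CSV/TSV response
#' panels (first column `protein_id`, remaining columns one per chemical;
#' empty cells mean "not tested", never zero). `read_tables()` bundles the
#' three and cross-validates everything against the alignment.
#'
#' @param path,cluster_path,taxonomy_path File paths.
#' @param response_paths Named character vector of response-panel paths; the
#'   names are used as dataset ids.
#' @param family Optional [or_family()] for referential checks.
#' @return `read_clusters()`: tibble (`seq_id`, `cluster_id`);
#'   `read_taxonomy()`: an [or_taxonomy()]; `read_responses()`: a long tibble
#'   (`dataset_id`, `protein_id`, `chemical_id`, `value`) with one row per
#'   tested protein-chemical pair; `read_tables()`: a list with elements
#'   `clusters`, `taxonomy`, `responses`.
#' @export
read_clusters <- function(path, family = NULL) {
  cl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  cl <- as_tibble(cl)[, c("seq_id", "cluster_id")]
  if (anyDuplicated(cl$seq_id)) {
    abort("referential error: a sequence is assigned to more than one cluster")
  }
  if (!is.null(family)) {
    unknown <- setdiff(cl$seq_id, family$seq_id)
    if (length(unknown) > 0) {
      abort(paste0(
        "referential error: cluster table ids absent from the alignment: ",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
  }
  cl
}

#' @rdname read_clusters
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  social <- tx |>
    distinct(.data$species_id, social = toupper(.data$social) %in% c("TRUE", "T", "1", "YES")) |>
    distinct(.data$species_id, .keep_all = TRUE)
  or_taxonomy(tx[, c("taxon_code", "parent_code", "species_id")], social)
}

#' @rdname read_clusters
#' @export
read_responses <- function(response_paths, family = NULL) {
  if (is.null(names(response_paths)) || any(names(response_paths) == "")) {
    abort("response_paths must be a named vector; names are dataset ids")
  }
  out <- imap(response_paths, function(p, id) {
    delim <- if (grepl("\\.tsv$", p)) "\t" else ","
    wide <- readr::read_delim(p, delim = delim, col_types = readr::cols(
      .default = "d", protein_id = "c"
    ), na = c("", "NA"))
    long <- tidyr::pivot_longer(wide, -"protein_id",
      names_to = "chemical_id", values_to = "value"
    )
    long <- long[!is.na(long$value), ]
    tibble(dataset_id = id, long)
  }) |> list_rbind()
  if (!is.null(family)) {
    unknown <- setdiff(out$protein_id, family$seq_id)
    if (length(unknown) > 0) {
      abort(paste0(
        "referential error: response proteins absent from the alignment: ",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
  }
  out
}

#' @rdname read_clusters
#' @export
read_tables <- function(cluster_path, taxonomy_path, response_paths, family = NULL) {
  taxonomy <- read_taxonomy(taxonomy_path)
  if (!is.null(family)) {
    unknown_sp <- setdiff(family$species_id, taxonomy$species$species_id)
    if (length(unknown_sp) > 0) {
      abort(paste0(
        "referential error: alignment species absent from the taxonomy: ",
        paste(unknown_sp, collapse = ", ")
      ))
    }
  }
  list(
    clusters = read_clusters(cluster_path, family),
    taxonomy = taxonomy,
    responses = read_responses(response_paths, family)
  )
}

#' Write the tabular pipeline inputs
#'
#' Inverses of [read_clusters()], [read_taxonomy()] and [read_responses()]:
#' a write followed by the matching read reproduces the object.
#'
#' @param clusters,taxonomy,responses Objects as returned by the readers.
#' @param path Output file path; for `write_responses()` a directory, one
#'   `responses_<dataset>.csv` per dataset.
#' @return The path(s) written, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(clusters, path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
write_taxonomy <- function(taxonomy, path) {
  tab <- taxonomy$taxa |>
    left_join(taxonomy$species, by = "species_id") |>
    mutate(parent_code = if_else(is.na(.data$parent_code), "-", .data$parent_code))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
write_responses <- function(responses, path) {
  paths <- responses |>
    split(responses$dataset_id) |>
    imap(function(d, id) {
      wide <- tidyr::pivot_wider(d[, c("protein_id", "chemical_id", "value")],
        names_from = "chemical_id", values_from = "value"
      )
      f <- file.path(path, paste0("responses_", id, ".csv"))
      readr::write_csv(wide, f, na = "")
      f
    })
  invisible(unlist(paths))
}

#' Drop flagged pseudogenes and fragments
#'
#' Sequences flagged `pseudogene` or `fragment` are removed; unflagged
#' sequences default to `ok`. Curation is declarative only: the package never
#' infers pseudogene status from the sequence itself.
#'
#' @param family An [or_family()].
#' @param flags Data frame with columns `seq_id` and `flag` (one of
#'   `"pseudogene"`, `"fragment"`, `"ok"`), covering any subset of sequences.
#' @return The curated [or_family()]. Idempotent.
#' @export
apply_curation_flags <- function(family, flags = NULL) {
  if (is.null(flags) || nrow(flags) == 0) return(family)
  flags <- as_tibble(flags)
  bad_flag <- setdiff(flags$flag, c("pseudogene", "fragment", "ok"))
  if (length(bad_flag) > 0) {
    abort(paste0("unknown curation flag: ", paste(bad_flag, collapse = ", ")))
  }
  unknown <- setdiff(flags$seq_id, family$seq_id)
  if (length(unknown) > 0) {
    warn(paste0(
      "curation flags for unknown ids ignored: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  drop <- flags$seq_id[flags$flag %in% c("pseudogene", "fragment")]
  keep <- !(family$seq_id %in% drop)
  if (!any(keep)) abort("curation removed every sequence in the family")
  n_removed <- sum(!keep)
  if (n_removed > 0) inform(sprintf("curation removed %d sequence(s)", n_removed))
  validate_or_family(family[keep, ])
}
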