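# Independent oracles used by the equivalence tests. All are deliberately
# brute-force and share no code with the package internals.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n, m) group assignments (no ties assumed). Uses the symmetry of the
# rank-sum distribution: p = P(|U - mn/2| >= |u_obs - mn/2|).
oracle_wilcoxon_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  n <- length(b)
  centre <- m * n / 2
  picks <- utils::combn(length(pooled), m)
  us <- apply(picks, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# 75th percentile by explicit linear interpolation between order statistics.
oracle_q75 <- function(x) {
  x <- sort(x)
  h <- (length(x) - 1) * 0.75
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# Modal-residue conservation by explicit tallies over a character matrix
# (rows = sequences of one cluster), excluding gaps and X.
oracle_conservation <- function(rows) {
  chars <- strsplit(rows, "")
  n_col <- length(chars[[1]])
  vapply(seq_len(n_col), function(p) {
    col <- vapply(chars, `[[`, character(1), p)
    col <- col[!(col %in% c("-", "X"))]
    if (length(col) == 0) return(NA_real_)
    best <- 0
    for (res in unique(col)) best <- max(best, sum(col == res))
    best / length(col)
  }, numeric(1))
}

# Tiny fixture builders -------------------------------------------------

tiny_family <- function(seqs, species = NULL) {
  ids <- names(seqs)
  if (is.null(species)) species <- sub("_.*$", "", ids)
  or_family(ids, species, unname(seqs))
}

tiny_taxonomy <- function(species, social) {
  rows <- dplyr::bind_rows(
    tibble::tibble(taxon_code = "A", parent_code = NA_character_, species_id = species),
    tibble::tibble(
      taxon_code = paste0("A", seq_along(species)),
      parent_code = "A", species_id = species
    )
  )
  if (any(social)) {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(taxon_code = "S", parent_code = "A", species_id = species[social])
    )
  }
  or_taxonomy(rows, tibble::tibble(species_id = species, social = social))
}

# A small deterministic response tibble in the package's long layout.
tiny_responses <- function(dataset_id, values) {
  # values: named list chemical -> named numeric vector (proteins)
  purrr::imap(values, function(v, chem) {
    tibble::tibble(
      dataset_id = dataset_id, protein_id = names(v),
      chemical_id = chem, value = unname(v)
    )
  }) |> purrr::list_rbind()
}
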