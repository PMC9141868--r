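#' Taxon-specific expansion scores per cluster
#'
#' For each cluster with at least `min_size` members and each taxon, the
#' enrichment is `log2(n_seqs / n_species)`: the number of cluster members
#' from the taxon's species over the number of species in the taxon.
#' Positive values flag lineage-specific expansions (more sequences than
#' species); negative values under-representation; a taxon contributing no
#' sequence is reported as absent (`NA`), never as `-Inf`.
#'
#' @param family An [or_family()].
#' @param clusters Tibble (`seq_id`, `cluster_id`).
#' @param taxonomy An [or_taxonomy()].
#' @param min_size Minimum cluster size (default 5).
#' @return A tibble of class `or_enrichment` (`cluster_id`, `taxon_code`,
#'   `n_seqs`, `n_species`, `enrichment`).
#' @export
taxon_enrichment <- function(family, clusters, taxonomy, min_size = 5) {
  sizes <- count(clusters, .data$cluster_id)
  keep <- sizes$cluster_id[sizes$n >= min_size]
  members <- clusters |>
    filter(.data$cluster_id %in% keep) |>
    left_join(family[, c("seq_id", "species_id")], by = "seq_id")
  taxa <- taxonomy$taxa |>
    group_by(.data$taxon_code) |>
    summarise(n_species = n_distinct(.data$species_id), .groups = "drop")
  counts <- taxonomy$taxa |>
    inner_join(members, by = "species_id", relationship = "many-to-many") |>
    count(.data$cluster_id, .data$taxon_code, name = "n_seqs")
  out <- tidyr::expand_grid(
    cluster_id = sort(keep),
    taxon_code = taxa$taxon_code
  ) |>
    left_join(counts, by = c("cluster_id", "taxon_code")) |>
    mutate(n_seqs = if_else(is.na(.data$n_seqs), 0L, as.integer(.data$n_seqs))) |>
    left_join(taxa, by = "taxon_code") |>
    mutate(enrichment = if_else(
      .data$n_seqs > 0, log2(.data$n_seqs / .data$n_species), NA_real_
    ))
  class(out) <- unique(c("or_enrichment", class(out)))
  out
}

#' Annotate clusters with expansion, sociality and conservation
#'
#' Per cluster: member count, number of species represented, the expansion
#' ratio (members per represented species), the fraction of members from
#' social species, and, when a conservation table is supplied, the
#' predictive/background conservation ratio.
#'
#' @inheritParams taxon_enrichment
#' @param conservation Optional [cluster_conservation()] result to join; a
#'   cluster without a profile is annotated with `ratio = NA` and excluded
#'   from the rank tests.
#' @return A tibble of class `or_annotation` (`cluster_id`, `n_members`,
#'   `n_species_present`, `expansion`, `social_fraction`, `ratio`).
#' @export
annotate_clusters <- function(family, clusters, taxonomy,
                              conservation = NULL, min_size = 5) {
  members <- clusters |>
    left_join(family[, c("seq_id", "species_id")], by = "seq_id") |>
    left_join(taxonomy$species, by = "species_id")
  out <- members |>
    group_by(.data$cluster_id) |>
    summarise(
      n_members = n(),
      n_species_present = n_distinct(.data$species_id),
      social_fraction = mean(.data$social),
      .groups = "drop"
    ) |>
    mutate(expansion = .data$n_members / .data$n_species_present) |>
    filter(.data$n_members >= min_size)
  if (!is.null(conservation)) {
    out <- left_join(out, conservation[, c("cluster_id", "ratio")], by = "cluster_id")
  } else {
    out$ratio <- NA_real_
  }
  out <- select(
    out, "cluster_id", "n_members", "n_species_present",
    "expansion", "social_fraction", "ratio"
  )
  class(out) <- unique(c("or_annotation", class(out)))
  out
}

#' Median-split rank test on conservation ratios
#'
#' Splits annotated clusters at the median of a criterion -- the social-OR
#' fraction, the expansion ratio, or both at once -- and compares the
#' conservation ratios of the two groups with a two-sided Wilcoxon rank-sum
#' test. "Above the median" is strict, so clusters sitting exactly at the
#' median fall in the low group. With `criterion = "both"` the high group
#' must exceed both medians.
#'
#' @param annotations An [annotate_clusters()] result with non-`NA` `ratio`
#'   for the clusters to test.
#' @param criterion `"social"`, `"expansion"` or `"both"`.
#' @return A one-row tibble: criterion, the median threshold(s), group
#'   sizes, group means and the Wilcoxon p-value.
#' @export
median_split_test <- function(annotations, criterion = c("social", "expansion", "both")) {
  criterion <- match.arg(criterion)
  ann <- annotations[!is.na(annotations$ratio), ]
  med_social <- median(ann$social_fraction)
  med_exp <- median(ann$expansion)
  high <- switch(criterion,
    social = ann$social_fraction > med_social,
    expansion = ann$expansion > med_exp,
    both = ann$social_fraction > med_social & ann$expansion > med_exp
  )
  if (sum(high) < 2 || sum(!high) < 2) {
    abort(sprintf("degenerate split for criterion '%s': a group has < 2 clusters", criterion))
  }
  wt <- wilcox.test(ann$ratio[high], ann$ratio[!high], alternative = "two.sided")
  tibble(
    criterion = criterion,
    median_social = med_social, median_expansion = med_exp,
    n_high = sum(high), n_low = sum(!high),
    mean_high = mean(ann$ratio[high]), mean_low = mean(ann$ratio[!high]),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}

#' Clusters specifically expanded in one species
#'
#' A cluster counts as specifically expanded in species `x` when at least
#' `fraction` of its members come from `x` (default: all of them) and it
#' has at least `min_size` members.
#'
#' @inheritParams taxon_enrichment
#' @param species Single species id.
#' @param fraction Minimum fraction of members from the species.
#' @return Character vector of cluster ids.
#' @export
species_specific_clusters <- function(family, clusters, species,
                                      fraction = 1, min_size = 5) {
  clusters |>
    left_join(family[, c("seq_id", "species_id")], by = "seq_id") |>
    group_by(.data$cluster_id) |>
    summarise(
      n = n(), frac = mean(.data$species_id == species), .groups = "drop"
    ) |>
    filter(.data$n >= min_size, .data$frac >= fraction) |>
    pull("cluster_id")
}

#' Compare conservation ratios between two species' private expansions
#'
#' Contrasts the predictive/background conservation ratios of the clusters
#' specifically expanded in `species_a` versus those specifically expanded
#' in `species_b` (two-sided Wilcoxon rank-sum). Used to ask whether, e.g.,
#' a solitary beetle's private receptor radiations are less conserved at
#' the binding site than a social ant's.
#'
#' @inheritParams species_specific_clusters
#' @param conservation A [cluster_conservation()] result.
#' @param species_a,species_b Species ids to contrast.
#' @return A one-row tibble with cluster counts, group mean ratios and the
#'   Wilcoxon p-value.
#' @export
species_specific_comparison <- function(family, clusters, conservation,
                                        species_a, species_b,
                                        fraction = 1, min_size = 5) {
  ca <- species_specific_clusters(family, clusters, species_a, fraction, min_size)
  cb <- species_specific_clusters(family, clusters, species_b, fraction, min_size)
  ra <- conservation$ratio[conservation$cluster_id %in% ca]
  rb <- conservation$ratio[conservation$cluster_id %in% cb]
  if (length(ra) < 2 || length(rb) < 2) {
    abort(sprintf(
      "too few specifically-expanded clusters (%s: %d, %s: %d)",
      species_a, length(ra), species_b, length(rb)
    ))
  }
  wt <- wilcox.test(ra, rb, alternative = "two.sided")
  tibble(
    species_a = species_a, species_b = species_b,
    n_a = length(ra), n_b = length(rb),
    mean_a = mean(ra), mean_b = mean(rb),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}
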