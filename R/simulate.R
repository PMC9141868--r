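#' Configuration for the synthetic family generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a clustered, pre-aligned protein family over a nested species
#' taxonomy, with planted "binding" columns that are (a) conserved within
#' clusters at a different rate than the background and (b) causally linked
#' to a noisy continuous chemical response.
#'
#' Each cluster draws a consensus sequence from `background_freqs`; each
#' member copies the consensus at a column with probability `theta_bind`
#' (columns in `binding_positions`) or `theta_bg` (elsewhere) and otherwise
#' draws from the background; gaps are then inserted i.i.d. per cell at
#' `gap_rate`. Gene counts per (species, cluster) follow a zero-inflated
#' geometric law: zero with probability `p_absent`, otherwise `1 + rgeom()`
#' with mean chosen so the overall mean is `mean_genes`.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_species,n_social Number of species and how many of them are
#'   social (the social species form one clade of the generated taxonomy).
#' @param n_clusters Number of ortholog clusters.
#' @param mean_genes Mean number of genes per (species, cluster).
#' @param p_absent Probability a species has no member in a cluster.
#' @param n_columns Alignment width.
#' @param background_freqs Length-20 residue frequency vector (normalised
#'   internally); default uniform.
#' @param theta_bg,theta_bind Per-column probability that a member copies the
#'   cluster consensus, at background and at planted binding columns.
#' @param binding_positions Integer vector of planted columns, or `NULL` to
#'   draw `n_binding` columns at random.
#' @param n_binding Number of planted columns when `binding_positions` is `NULL`.
#' @param gap_rate Per-cell gap insertion probability.
#' @param n_chemicals Number of chemicals in a simulated response panel.
#' @param n_active Planted positions engaged by each chemical: every
#'   chemical's response depends on a random subset of `n_active` of the
#'   planted columns, emulating that different odorants contact different
#'   binding-pocket residues.
#' @param responsive_target Target frequency of the responsive residue set
#'   at an engaged column. The set is the frequency-ranked subset of
#'   residues observed at the column whose cumulative frequency is closest
#'   to this target, so that a planted effect splits the family near the
#'   binarization quantile (default 0.25, matching the upper-quartile
#'   labeling rule).
#' @param beta,sigma Response effect size per engaged position carrying a
#'   responsive residue, and the Gaussian noise s.d. (`beta/sigma` is the
#'   planted signal-to-noise).
#' @param missing_frac Fraction of protein-chemical cells left untested.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 12L,
                       n_social = 6L,
                       n_clusters = 20L,
                       mean_genes = 2,
                       p_absent = 0.4,
                       n_columns = 100L,
                       background_freqs = NULL,
                       theta_bg = 0.5,
                       theta_bind = 0.85,
                       binding_positions = NULL,
                       n_binding = 5L,
                       gap_rate = 0.05,
                       n_chemicals = 8L,
                       n_active = 2L,
                       responsive_target = 0.25,
                       beta = 1,
                       sigma = 0.3,
                       missing_frac = 0.2) {
  if (is.null(background_freqs)) background_freqs <- rep(1 / 20, 20)
  if (length(background_freqs) != 20 || any(background_freqs < 0)) {
    abort("background_freqs must be 20 non-negative frequencies")
  }
  background_freqs <- background_freqs / sum(background_freqs)
  if (theta_bg < 0 || theta_bg > 1 || theta_bind < 0 || theta_bind > 1) {
    abort("theta_bg and theta_bind must lie in [0, 1]")
  }
  if (is.null(binding_positions)) {
    if (n_binding > n_columns) {
      abort("config error: more planted binding positions than alignment columns")
    }
  } else {
    binding_positions <- as.integer(binding_positions)
    if (any(binding_positions < 1) || any(binding_positions > n_columns)) {
      abort("config error: binding_positions outside 1..n_columns")
    }
  }
  if (n_social > n_species) abort("n_social cannot exceed n_species")
  structure(
    list(
      seed = as.integer(seed), n_species = as.integer(n_species),
      n_social = as.integer(n_social), n_clusters = as.integer(n_clusters),
      mean_genes = mean_genes, p_absent = p_absent,
      n_columns = as.integer(n_columns), background_freqs = background_freqs,
      theta_bg = theta_bg, theta_bind = theta_bind,
      binding_positions = binding_positions, n_binding = as.integer(n_binding),
      gap_rate = gap_rate, n_chemicals = as.integer(n_chemicals),
      n_active = as.integer(n_active), responsive_target = responsive_target,
      beta = beta, sigma = sigma, missing_frac = missing_frac
    ),
    class = "sim_config"
  )
}

# Two-clade taxonomy over the configured species: root "A" splits into the
# social clade "B" and the solitary clade "C", each with per-species leaves.
sim_taxonomy <- function(config) {
  sp <- sprintf("Sp%02d", seq_len(config$n_species))
  social <- seq_len(config$n_species) <= config$n_social
  rows <- list(tibble(taxon_code = "A", parent_code = NA_character_, species_id = sp))
  if (config$n_social > 0) {
    rows <- c(rows, list(
      tibble(taxon_code = "B", parent_code = "A", species_id = sp[social]),
      tibble(
        taxon_code = sprintf("B%d", seq_len(sum(social))),
        parent_code = "B", species_id = sp[social]
      )
    ))
  }
  if (config$n_social < config$n_species) {
    rows <- c(rows, list(
      tibble(taxon_code = "C", parent_code = "A", species_id = sp[!social]),
      tibble(
        taxon_code = sprintf("C%d", seq_len(sum(!social))),
        parent_code = "C", species_id = sp[!social]
      )
    ))
  }
  or_taxonomy(list_rbind(rows), tibble(species_id = sp, social = social))
}

#' Simulate a clustered aligned family
#'
#' @param config A [sim_config()].
#' @return A list with elements `family` ([or_family()]), `clusters`
#'   (tibble `seq_id`, `cluster_id`), `taxonomy` ([or_taxonomy()]),
#'   `binding_positions` (the planted columns actually used) and
#'   `consensus` (per-cluster consensus strings). Deterministic given
#'   `config$seed`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    taxonomy <- sim_taxonomy(config)
    binding <- config$binding_positions
    if (is.null(binding)) {
      binding <- sort(sample.int(config$n_columns, config$n_binding))
    }
    theta <- rep(config$theta_bg, config$n_columns)
    theta[binding] <- config$theta_bind
    # geometric mean chosen so E[genes] = mean_genes given P(absent) = p_absent
    mean_extra <- max(config$mean_genes / (1 - config$p_absent) - 1, 0)

    consensus <- replicate(config$n_clusters, paste(
      sample(AA_LETTERS, config$n_columns, replace = TRUE, prob = config$background_freqs),
      collapse = ""
    ))
    names(consensus) <- sprintf("C%d", seq_len(config$n_clusters) - 1L)

    rows <- list()
    for (ci in seq_len(config$n_clusters)) {
      cid <- names(consensus)[ci]
      cons <- strsplit(consensus[[ci]], "")[[1]]
      for (sp in taxonomy$species$species_id) {
        n_genes <- if (runif(1) < config$p_absent) 0L else
          1L + stats::rgeom(1, prob = 1 / (1 + mean_extra))
        if (n_genes == 0L) next
        for (g in seq_len(n_genes)) {
          copy <- runif(config$n_columns) < theta
          res <- ifelse(copy, cons,
            sample(AA_LETTERS, config$n_columns, replace = TRUE,
                   prob = config$background_freqs))
          res[runif(config$n_columns) < config$gap_rate] <- "-"
          rows[[length(rows) + 1L]] <- tibble(
            seq_id = sprintf("%s_%s_g%d", sp, cid, g),
            species_id = sp, cluster_id = cid,
            aligned_seq = paste(res, collapse = "")
          )
        }
      }
    }
    tab <- list_rbind(rows)
    list(
      family = or_family(tab$seq_id, tab$species_id, tab$aligned_seq),
      clusters = tab[, c("seq_id", "cluster_id")],
      taxonomy = taxonomy,
      binding_positions = binding,
      consensus = consensus
    )
  })
}

# Frequency-ranked residue subset at a column whose cumulative frequency is
# closest to the target (greedy, deterministic given the composition).
target_residue_set <- function(freqs, target) {
  freqs <- sort(freqs, decreasing = TRUE)
  chosen <- character()
  cum <- 0
  for (r in names(freqs)) {
    if (abs(cum + freqs[[r]] - target) < abs(cum - target)) {
      chosen <- c(chosen, r)
      cum <- cum + freqs[[r]]
    }
  }
  if (length(chosen) == 0) chosen <- names(freqs)[1]
  chosen
}

# Responsive residue sets: each chemical engages n_active planted positions;
# at each engaged position the responsive set is the observed-residue subset
# with cumulative frequency closest to responsive_target, so the planted
# effect divides the family roughly at the labeling quantile.
sim_responsive_sets <- function(family, config, binding_positions) {
  m <- seq_matrix(family)
  withr::with_seed(config$seed + 1000L, {
    out <- list()
    for (ch in seq_len(config$n_chemicals)) {
      active <- sample(binding_positions, min(config$n_active, length(binding_positions)))
      for (p in sort(active)) {
        col <- m[, p]
        col <- col[!col %in% c("-", "X")]
        fr <- table(col) / length(col)
        out[[length(out) + 1L]] <- tibble(
          chemical_id = sprintf("chem%02d", ch),
          position = p,
          residue = target_residue_set(setNames(as.numeric(fr), names(fr)),
                                       config$responsive_target)
        )
      }
    }
    list_rbind(out)
  })
}

#' Simulate a chemical-response panel for a family
#'
#' Each protein's continuous response to a chemical is `beta` times the
#' number of engaged planted positions at which its residue belongs to that
#' chemical's responsive set, plus `N(0, sigma)` noise; a `missing_frac`
#' fraction of cells is then dropped ("not tested").
#'
#' @param sim Result of [simulate_family()] (or a list with `family` and
#'   `binding_positions`).
#' @param config The [sim_config()] used to generate it.
#' @param dataset_id Dataset label for the panel.
#' @param proteins Optional subset of seq_ids to profile (default: all).
#' @param responsive_sets Optional tibble (`chemical_id`, `position`,
#'   `residue`); default: drawn deterministically from `config$seed`.
#' @return A long response tibble (`dataset_id`, `protein_id`,
#'   `chemical_id`, `value`) of tested cells only.
#' @export
simulate_responses <- function(sim, config, dataset_id = "ds1",
                               proteins = NULL, responsive_sets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  family <- sim$family
  binding <- sim$binding_positions
  if (is.null(responsive_sets)) {
    responsive_sets <- sim_responsive_sets(family, config, binding)
  }
  if (is.null(proteins)) proteins <- family$seq_id
  m <- seq_matrix(family)[proteins, , drop = FALSE]
  chems <- unique(responsive_sets$chemical_id)
  withr::with_seed(config$seed + 2000L + sum(utf8ToInt(dataset_id)), {
    grid <- tidyr::expand_grid(protein_id = proteins, chemical_id = chems)
    signal <- map2_dbl_(grid$protein_id, grid$chemical_id, function(pid, ch) {
      sets <- responsive_sets[responsive_sets$chemical_id == ch, ]
      sum(m[pid, sets$position] == sets$residue) * config$beta
    })
    grid$value <- signal + rnorm(nrow(grid), sd = config$sigma)
    keep <- runif(nrow(grid)) >= config$missing_frac
    tibble(dataset_id = dataset_id, grid[keep, ])
  })
}

# purrr::map2_dbl with less overhead for tight loops
map2_dbl_ <- function(x, y, f) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- f(x[[i]], y[[i]])
  out
}

#' Simulate a full study: family plus several response datasets
#'
#' Emulates the shape of the published inputs: one master family and
#' several response panels, each profiling the receptors of a single
#' (randomly chosen) species, as electrophysiology panels do.
#'
#' @param config A [sim_config()].
#' @param n_datasets Number of response panels.
#' @return The [simulate_family()] list plus an element `responses`
#'   (row-bound long response tibble over all datasets).
#' @export
simulate_study <- function(config, n_datasets = 3L) {
  sim <- simulate_family(config)
  focal <- withr::with_seed(
    config$seed + 3000L,
    sample(unique(sim$family$species_id), n_datasets)
  )
  sim$responses <- list_rbind(imap(setNames(focal, paste0("ds", seq_len(n_datasets))),
    function(sp, id) {
      prot <- sim$family$seq_id[sim$family$species_id == sp]
      simulate_responses(sim, config, dataset_id = id, proteins = prot)
    }
  ))
  sim
}
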