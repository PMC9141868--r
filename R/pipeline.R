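#' Pipeline configuration
#'
#' Collects every path, threshold and model setting the end-to-end pipeline
#' uses. Either `sim` (a [sim_config()], to generate synthetic inputs) or
#' the four input paths must be supplied.
#'
#' @param out_dir Output directory for all artifacts and the manifest.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param sim Optional [sim_config()]; when present the `simulate` stage
#'   writes the input files itself.
#' @param alignment,clusters,taxonomy Input file paths (ignored when
#'   simulating).
#' @param responses Named character vector of response CSV paths (names =
#'   dataset ids; ignored when simulating).
#' @param min_values,importance_min,auc_min,top_k,min_cluster_size,freq_cut,unique_cut
#'   Analysis thresholds (defaults: 100, 10, 0.7, 10, 5, 19, 10).
#' @param model A [model_spec()]; its seed is overridden by the derived
#'   stage seed.
#' @param reference_seq_id,template_seq,numbering_offset Optional structure
#'   mapping inputs (see [position_map()]).
#' @return A list of class `or_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            alignment = NULL, clusters = NULL,
                            taxonomy = NULL, responses = NULL,
                            min_values = 100, importance_min = 10,
                            auc_min = 0.7, top_k = 10, min_cluster_size = 5,
                            freq_cut = 19, unique_cut = 10,
                            model = model_spec(),
                            reference_seq_id = NULL, template_seq = NULL,
                            numbering_offset = 0L) {
  stopifnot(min_values > 0, importance_min > 0, auc_min > 0, top_k > 0,
            min_cluster_size > 0, freq_cut > 0, unique_cut > 0)
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), sim = sim,
      alignment = alignment, clusters = clusters, taxonomy = taxonomy,
      responses = responses,
      min_values = min_values, importance_min = importance_min,
      auc_min = auc_min, top_k = top_k, min_cluster_size = min_cluster_size,
      freq_cut = freq_cut, unique_cut = unique_cut, model = model,
      reference_seq_id = reference_seq_id, template_seq = template_seq,
      numbering_offset = numbering_offset
    ),
    class = "or_pipeline_config"
  )
}

PIPELINE_STAGES <- c("simulate", "prep", "train", "select", "conserve", "evolve", "map")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order -- simulate (or load inputs),
#' binarize and select chemicals, train the per-(dataset, chemical)
#' importance models, select predictive positions, score cluster
#' conservation, run the cluster-evolution tests, and map positions to a
#' reference/template numbering -- writing each stage's artifacts as TSV/CSV
#' under `config$out_dir`. A stage not requested in this run reads its
#' inputs from the artifacts already in `out_dir`. A `manifest.json` records
#' the seed, thresholds, package version and MD5 checksum of every artifact,
#' so identical configurations yield identical manifests.
#'
#' @param config An [pipeline_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `simulate, prep, train, select, conserve, evolve, map` (default: all
#'   applicable).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "or_pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (is.null(config$sim)) stages <- setdiff(stages, "simulate")
  if (is.null(config$reference_seq_id)) stages <- setdiff(stages, "map")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  state <- new.env(parent = emptyenv())
  written <- character()
  note <- function(f) written <<- union(written, f)

  run_stage <- function(name, body) {
    tryCatch(body(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # Lazily obtain an upstream object: from this run, else from out_dir, else
  # from the configured input paths.
  need <- local({
    loaders <- list(
      family = function() {
        p <- if (file.exists(out("family.fasta"))) out("family.fasta") else config$alignment
        if (is.null(p) || !file.exists(p)) {
          abort("config error: no alignment available (field 'alignment' or simulate stage)")
        }
        read_aligned_fasta(p)
      },
      clusters = function() {
        p <- if (file.exists(out("clusters.tsv"))) out("clusters.tsv") else config$clusters
        if (is.null(p) || !file.exists(p)) abort("config error: missing field 'clusters'")
        read_clusters(p, need("family"))
      },
      taxonomy = function() {
        p <- if (file.exists(out("taxonomy.tsv"))) out("taxonomy.tsv") else config$taxonomy
        if (is.null(p) || !file.exists(p)) abort("config error: missing field 'taxonomy'")
        read_taxonomy(p)
      },
      responses = function() {
        local_files <- list.files(config$out_dir, "^responses_.*\\.csv$", full.names = TRUE)
        if (length(local_files) > 0) {
          paths <- setNames(local_files, sub("^responses_(.*)\\.csv$", "\\1", basename(local_files)))
        } else {
          paths <- config$responses
        }
        if (is.null(paths)) abort("config error: missing field 'responses'")
        read_responses(paths, need("family"))
      },
      binarized = function() {
        p <- out("binarized.tsv")
        if (!file.exists(p)) abort("config error: prep stage artifacts missing; run 'prep' first")
        readr::read_tsv(p, col_types = readr::cols(
          dataset_id = "c", protein_id = "c", chemical_id = "c",
          value = "d", bin = "i"
        ))
      },
      importances = function() {
        p <- out("importances.tsv")
        if (!file.exists(p)) abort("config error: train stage artifacts missing; run 'train' first")
        readr::read_tsv(p, col_types = readr::cols(
          dataset_id = "c", chemical_id = "c", position = "i",
          residue = "c", importance = "d", model_auc = "d"
        ))
      },
      top_positions = function() {
        p <- out("top_positions.tsv")
        if (!file.exists(p)) abort("config error: select stage artifacts missing; run 'select' first")
        readr::read_tsv(p, col_types = "i")$position
      },
      conservation = function() {
        p <- out("conservation.tsv")
        if (!file.exists(p)) abort("config error: conserve stage artifacts missing; run 'conserve' first")
        readr::read_tsv(p, col_types = readr::cols(
          cluster_id = "c", n_members = "i", c_bg = "d", c_pred = "d", ratio = "d"
        ))
      }
    )
    function(name) {
      if (!is.null(state[[name]])) return(state[[name]])
      state[[name]] <- loaders[[name]]()
      state[[name]]
    }
  })

  if ("simulate" %in% stages) run_stage("simulate", function() {
    cfg <- config$sim
    cfg$seed <- config$seed
    sim <- simulate_study(cfg)
    state$family <- sim$family
    state$clusters <- sim$clusters
    state$taxonomy <- sim$taxonomy
    state$responses <- sim$responses
    state$binding_positions <- sim$binding_positions
    write_aligned_fasta(sim$family, out("family.fasta")); note(out("family.fasta"))
    write_clusters(sim$clusters, out("clusters.tsv")); note(out("clusters.tsv"))
    write_taxonomy(sim$taxonomy, out("taxonomy.tsv")); note(out("taxonomy.tsv"))
    for (f in write_responses(sim$responses, config$out_dir)) note(f)
    readr::write_tsv(
      tibble(position = sim$binding_positions), out("binding_positions.tsv")
    )
    note(out("binding_positions.tsv"))
  })

  if ("prep" %in% stages) run_stage("prep", function() {
    responses <- need("responses")
    sel <- select_chemicals(responses, config$min_values)
    bin <- binarize_responses(filter(responses, .data$chemical_id %in% sel$chemical_id))
    state$chemicals <- sel
    state$binarized <- bin
    readr::write_tsv(sel, out("chemicals.tsv")); note(out("chemicals.tsv"))
    readr::write_tsv(bin, out("binarized.tsv")); note(out("binarized.tsv"))
  })

  if ("train" %in% stages) run_stage("train", function() {
    spec <- config$model
    spec$seed <- config$seed + 10L
    fits <- run_all_pairs(need("family"), need("binarized"), spec,
      freq_cut = config$freq_cut, unique_cut = config$unique_cut
    )
    state$fits <- fits
    state$importances <- tidy(fits)
    readr::write_tsv(glance(fits), out("model_metrics.tsv")); note(out("model_metrics.tsv"))
    readr::write_tsv(state$importances, out("importances.tsv")); note(out("importances.tsv"))
  })

  if ("select" %in% stages) run_stage("select", function() {
    kept <- filter_features(need("importances"),
      importance_min = config$importance_min, auc_min = config$auc_min
    )
    ranking <- rank_positions(kept)
    top <- union_top_positions(ranking, k = config$top_k)
    state$top_positions <- top
    readr::write_tsv(kept, out("kept_features.tsv")); note(out("kept_features.tsv"))
    readr::write_tsv(ranking, out("position_ranking.tsv")); note(out("position_ranking.tsv"))
    readr::write_tsv(tibble(position = top), out("top_positions.tsv")); note(out("top_positions.tsv"))
  })

  if ("conserve" %in% stages) run_stage("conserve", function() {
    cons <- cluster_conservation(need("family"), need("clusters"),
      need("top_positions"),
      min_size = config$min_cluster_size
    )
    state$conservation <- cons
    readr::write_tsv(cons, out("conservation.tsv")); note(out("conservation.tsv"))
  })

  if ("evolve" %in% stages) run_stage("evolve", function() {
    enr <- taxon_enrichment(need("family"), need("clusters"), need("taxonomy"),
      min_size = config$min_cluster_size
    )
    ann <- annotate_clusters(need("family"), need("clusters"), need("taxonomy"),
      conservation = need("conservation"), min_size = config$min_cluster_size
    )
    tests <- list_rbind(map(
      c("social", "expansion", "both"),
      function(cr) tryCatch(median_split_test(ann, cr), error = function(e) NULL)
    ))
    state$annotations <- ann
    readr::write_tsv(enr, out("enrichment.tsv")); note(out("enrichment.tsv"))
    readr::write_tsv(ann, out("annotations.tsv")); note(out("annotations.tsv"))
    readr::write_tsv(tests, out("split_tests.tsv")); note(out("split_tests.tsv"))
  })

  if ("map" %in% stages) run_stage("map", function() {
    pm <- position_map(need("family"), config$reference_seq_id,
      template_seq = config$template_seq,
      numbering_offset = config$numbering_offset
    )
    annot <- annotate_positions(need("top_positions"), pm, labels = "top10")
    readr::write_tsv(pm, out("position_map.tsv")); note(out("position_map.tsv"))
    readr::write_tsv(annot, out("position_annotation.tsv")); note(out("position_annotation.tsv"))
  })

  manifest <- list(
    package = "orfam",
    version = as.character(utils::packageVersion("orfam")),
    seed = config$seed,
    stages = stages,
    thresholds = config[c(
      "min_values", "importance_min", "auc_min", "top_k",
      "min_cluster_size", "freq_cut", "unique_cut"
    )],
    model = unclass(config$model),
    files = as.list(tools::md5sum(sort(written)))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
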