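#' Random-forest model specification
#'
#' One classifier is trained per (dataset, chemical) pair: a random forest
#' of `n_trees` trees over the one-hot encoded residue features, with `mtry`
#' selected from a grid by repeated k-fold cross-validation on the
#' cross-validated AUC.
#'
#' @param n_trees Trees per forest.
#' @param mtry Candidate values for the number of predictors tried per
#'   split; values exceeding the number of encoded predictors are clipped.
#' @param cv_folds,cv_repeats Cross-validation folds and repeats
#'   (default 10 x 10 = 100 resamples).
#' @param seed Integer seed making the fit fully deterministic.
#' @return A list of class `or_model_spec`.
#' @export
model_spec <- function(n_trees = 500L, mtry = c(20L, 50L, 100L),
                       cv_folds = 10L, cv_repeats = 10L, seed = 1L) {
  stopifnot(n_trees >= 1, all(mtry >= 1), cv_folds >= 2, cv_repeats >= 1)
  structure(
    list(
      n_trees = as.integer(n_trees), mtry = as.integer(sort(unique(mtry))),
      cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
      seed = as.integer(seed)
    ),
    class = "or_model_spec"
  )
}

# Per-resample summary: AUC of the positive-class probability with fixed
# direction (cases score higher), plus sensitivity/precision/F1 of the hard
# predictions. The best-class convention is applied once, after averaging.
or_summary <- function(data, lev, model = NULL) {
  pos <- lev[2]
  roc_val <- if (length(unique(data$obs)) < 2) NA_real_ else {
    tryCatch(
      as.numeric(pROC::auc(pROC::roc(
        response = data$obs, predictor = data[[pos]],
        levels = lev, direction = "<", quiet = TRUE
      ))),
      error = function(e) NA_real_
    )
  }
  tp <- sum(data$pred == pos & data$obs == pos)
  fp <- sum(data$pred == pos & data$obs != pos)
  fn <- sum(data$pred != pos & data$obs == pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0) {
    2 * sens * prec / (sens + prec)
  } else {
    NA_real_
  }
  c(ROC = roc_val, Sens = sens, Precision = prec, F1 = f1)
}

#' Train one (dataset, chemical) importance model
#'
#' Restricts the design table to labeled sequences, re-filters near-zero
#' variance columns within that training subset, one-hot encodes residues so
#' that importances exist per (position, residue) feature, and fits a
#' cross-validated random forest via [caret::train()]. Feature importances
#' (mean decrease in impurity of the final forest) are min-max scaled to
#' `[0, 100]`; the reported AUC follows the best-class convention
#' `max(AUC, 1 - AUC)` applied to the resample mean.
#'
#' @param table An `or_features` table from [build_feature_table()].
#' @param labels Binary labels: either a tibble with columns `seq_id` and
#'   `bin`, or a named 0/1 vector. `NA` labels are dropped.
#' @param spec A [model_spec()].
#' @param dataset_id,chemical_id Metadata carried into the result.
#' @param filter_nzv Re-filter near-zero-variance columns on the training
#'   subset (default `TRUE`).
#' @param freq_cut,unique_cut Passed to [filter_near_zero_variance()].
#' @param min_support Minimum number of sequences an encoded
#'   (position, residue) indicator must be present in (and absent from) to
#'   enter the model; rare indicators cannot generalize and only add
#'   importance noise. Capped at a quarter of the training rows.
#' @return An object of class `or_importance` (see [tidy()] and
#'   [glance()] methods), or `NULL` with a warning when the labels contain a
#'   single class.
#' @export
train_pair <- function(table, labels, spec = model_spec(),
                       dataset_id = "ds", chemical_id = "chem",
                       filter_nzv = TRUE, freq_cut = 19, unique_cut = 10,
                       min_support = 5L) {
  lab <- as_label_vector(labels)
  lab <- lab[!is.na(lab)]
  lab <- lab[names(lab) %in% table$seq_id]
  if (length(unique(lab)) < 2) {
    warn(sprintf("pair (%s, %s): single-class labels; skipped", dataset_id, chemical_id))
    return(NULL)
  }
  sub <- table[match(names(lab), table$seq_id), , drop = FALSE]
  attr(sub, "retained_positions") <- retained_positions(table)
  class(sub) <- class(table)
  if (filter_nzv) {
    sub <- suppressMessages(
      filter_near_zero_variance(sub, freq_cut = freq_cut, unique_cut = unique_cut)
    )
  }
  x <- encode_features(sub, min_support = min_support)
  y <- factor(if_else(lab == 1, "resp", "nonresp"), levels = c("nonresp", "resp"))

  k <- spec$cv_folds
  if (length(y) < k) {
    warn(sprintf(
      "pair (%s, %s): %d labeled rows < %d folds; reducing folds",
      dataset_id, chemical_id, length(y), k
    ))
    k <- max(2L, length(y) %/% 2L)
  }
  grid <- unique(pmin(spec$mtry, ncol(x)))
  if (any(spec$mtry > ncol(x))) {
    warn(sprintf(
      "pair (%s, %s): mtry grid clipped to %d encoded predictors",
      dataset_id, chemical_id, ncol(x)
    ))
  }

  n_resample <- k * spec$cv_repeats
  fit <- withr::with_seed(spec$seed, {
    seeds <- c(
      lapply(seq_len(n_resample), function(i) sample.int(.Machine$integer.max, length(grid))),
      list(sample.int(.Machine$integer.max, 1))
    )
    ctrl <- caret::trainControl(
      method = if (spec$cv_repeats > 1) "repeatedcv" else "cv",
      number = k, repeats = spec$cv_repeats,
      classProbs = TRUE, summaryFunction = or_summary, seeds = seeds
    )
    caret::train(
      x = x, y = y, method = "rf", metric = "ROC",
      ntree = spec$n_trees, tuneGrid = data.frame(mtry = grid),
      trControl = ctrl
    )
  })

  best <- fit$results[fit$results$mtry == fit$bestTune$mtry, , drop = FALSE][1, ]
  auc_raw <- best$ROC
  vi <- caret::varImp(fit, scale = TRUE)$importance
  imp <- vi[[1]]
  imp[!is.finite(imp)] <- 0
  importances <- decode_feature_names(rownames(vi))
  importances$importance <- imp
  importances <- arrange(importances, desc(.data$importance), .data$position, .data$residue)

  structure(
    list(
      dataset_id = dataset_id, chemical_id = chemical_id,
      auc = max(auc_raw, 1 - auc_raw), auc_raw = auc_raw,
      f1 = best$F1, sensitivity = best$Sens, precision = best$Precision,
      mtry = fit$bestTune$mtry, n_train = length(y),
      importances = importances, spec = spec
    ),
    class = "or_importance"
  )
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    setNames(as.integer(labels$bin), labels$seq_id)
  } else if (!is.null(names(labels))) {
    setNames(as.integer(labels), names(labels))
  } else {
    abort("labels must be a (seq_id, bin) data frame or a named 0/1 vector")
  }
}

#' @export
print.or_importance <- function(x, ...) {
  cat(sprintf(
    "<or_importance> %s / %s: n = %d, AUC = %.3f, F1 = %.3f, mtry = %d\n",
    x$dataset_id, x$chemical_id, x$n_train, x$auc, x$f1, x$mtry
  ))
  invisible(x)
}

#' @rdname train_pair
#' @param x An `or_importance` object.
#' @param ... Unused.
#' @export
tidy.or_importance <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id, chemical_id = x$chemical_id,
    x$importances, model_auc = x$auc
  )
}

#' @rdname train_pair
#' @export
glance.or_importance <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id, chemical_id = x$chemical_id,
    auc = x$auc, f1 = x$f1, sensitivity = x$sensitivity,
    precision = x$precision, mtry = x$mtry, n_train = x$n_train
  )
}

#' Train importance models for every (dataset, chemical) pair
#'
#' For each dataset the design table is built over the proteins tested in
#' that dataset; for each selected chemical, only proteins with a binarized
#' response to that chemical enter training. Pairs whose labels contain a
#' single class are skipped with a warning and counted.
#'
#' @param family An [or_family()].
#' @param binarized Long response tibble with a `bin` column, from
#'   [binarize_responses()].
#' @param spec A [model_spec()].
#' @param chemicals Optional chemical ids to model (default: all present;
#'   typically `select_chemicals()$chemical_id`).
#' @inheritParams train_pair
#' @return A list of `or_importance` objects, class `or_importance_set`.
#' @export
run_all_pairs <- function(family, binarized, spec = model_spec(),
                          chemicals = NULL, filter_nzv = TRUE,
                          freq_cut = 19, unique_cut = 10, min_support = 5L) {
  if (!"bin" %in% names(binarized)) {
    abort("binarized must contain a 'bin' column; run binarize_responses() first")
  }
  if (is.null(chemicals)) chemicals <- unique(binarized$chemical_id)
  results <- list()
  n_skipped <- 0L
  for (ds in unique(binarized$dataset_id)) {
    d <- binarized[binarized$dataset_id == ds & binarized$chemical_id %in% chemicals, ]
    prot <- intersect(unique(d$protein_id), family$seq_id)
    if (length(prot) == 0) next
    table <- build_feature_table(family, prot)
    for (ch in intersect(chemicals, unique(d$chemical_id))) {
      lab <- d[d$chemical_id == ch & !is.na(d$bin), c("protein_id", "chemical_id", "bin")]
      res <- withCallingHandlers(
        train_pair(table, setNames(lab$bin, lab$protein_id), spec,
          dataset_id = ds, chemical_id = ch,
          filter_nzv = filter_nzv, freq_cut = freq_cut, unique_cut = unique_cut,
          min_support = min_support
        ),
        warning = function(w) {
          if (grepl("single-class", conditionMessage(w))) {
            n_skipped <<- n_skipped + 1L
          }
          warn(conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      if (!is.null(res)) results[[paste(ds, ch, sep = "/")]] <- res
    }
  }
  if (n_skipped > 0) inform(sprintf("skipped %d single-class pair(s)", n_skipped))
  structure(results, class = "or_importance_set")
}

#' @rdname run_all_pairs
#' @param x An `or_importance_set`.
#' @param ... Unused.
#' @export
tidy.or_importance_set <- function(x, ...) list_rbind(map(unclass(x), tidy))

#' @rdname run_all_pairs
#' @export
glance.or_importance_set <- function(x, ...) list_rbind(map(unclass(x), glance))

#' @export
print.or_importance_set <- function(x, ...) {
  cat(sprintf("<or_importance_set> %d model(s)\n", length(x)))
  if (length(x) > 0) print(glance(x))
  invisible(x)
}
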