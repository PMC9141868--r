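# A tiny family with one perfectly separating column: position 3 is W in
# responders and L in non-responders; everything else is shared noise.
separable_fixture <- function(n_pos = 8, n_neg = 24) {
  withr::with_seed(99, {
    base <- sample(c("A", "C", "D", "E"), 20, TRUE)
    mk <- function(marker) {
      s <- base
      s[3] <- marker
      s[sample(setdiff(1:20, 3), 4)] <- sample(c("A", "C", "D", "E"), 4, TRUE)
      paste(s, collapse = "")
    }
    seqs <- c(
      vapply(seq_len(n_pos), function(i) mk("W"), character(1)),
      vapply(seq_len(n_neg), function(i) mk("L"), character(1))
    )
    names(seqs) <- sprintf("Sp%d_g%d", rep(1:4, length.out = length(seqs)), seq_along(seqs))
    fam <- tiny_family(seqs)
    labels <- setNames(rep(c(1L, 0L), c(n_pos, n_neg)), names(seqs))
    list(fam = fam, labels = labels)
  })
}

fast_spec <- function(seed = 1) {
  model_spec(n_trees = 200, mtry = c(5, 20), cv_folds = 4, cv_repeats = 2, seed = seed)
}

test_that("a perfectly separating position gives AUC 1 and top importance", {
  fx <- separable_fixture()
  ft <- build_feature_table(fx$fam)
  res <- suppressWarnings(
    train_pair(ft, fx$labels, fast_spec(), dataset_id = "d", chemical_id = "c")
  )
  expect_equal(res$auc, 1)
  expect_equal(res$n_train, 32)
  top <- res$importances[1, ]
  expect_equal(top$position, 3L)
  expect_true(top$residue %in% c("W", "L"))
  expect_equal(top$importance, 100)
  expect_true(all(res$importances$importance >= 0 & res$importances$importance <= 100))
})

test_that("training is deterministic in the seed", {
  fx <- separable_fixture()
  ft <- build_feature_table(fx$fam)
  a <- suppressWarnings(train_pair(ft, fx$labels, fast_spec(7)))
  b <- suppressWarnings(train_pair(ft, fx$labels, fast_spec(7)))
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a), glance(b))
})

test_that("permuted labels keep the best-class AUC near chance", {
  fx <- separable_fixture(10, 30)
  ft <- build_feature_table(fx$fam)
  aucs <- vapply(1:5, function(s) {
    perm <- withr::with_seed(1000 + s, sample(fx$labels))
    names(perm) <- names(fx$labels)
    suppressWarnings(train_pair(ft, perm, fast_spec(s)))$auc
  }, numeric(1))
  expect_true(all(aucs >= 0.5)) # best-class convention floor
  expect_true(all(aucs <= 0.72))
  expect_lt(mean(aucs), 0.65)
})

test_that("degenerate labels are skipped or handled with reduced folds", {
  fx <- separable_fixture()
  ft <- build_feature_table(fx$fam)
  one_class <- setNames(rep(1L, 12), names(fx$labels)[1:12])
  expect_warning(res <- train_pair(ft, one_class, fast_spec()), "single-class")
  expect_null(res)
  few <- fx$labels[c(1:3, 9:11)]
  expect_warning(
    res2 <- train_pair(ft, few, model_spec(
      n_trees = 100, mtry = 5, cv_folds = 10, cv_repeats = 1, seed = 1
    )),
    "reducing folds"
  )
  expect_s3_class(res2$importances, "tbl_df")
  # mtry beyond the number of encoded predictors is clipped with a warning
  expect_warning(
    train_pair(ft, fx$labels, model_spec(
      n_trees = 50, mtry = 10000, cv_folds = 3, cv_repeats = 1, seed = 1
    )),
    "clipped"
  )
})

test_that("run_all_pairs trains one model per labelled pair and skips the rest", {
  fx <- separable_fixture()
  bin <- dplyr::bind_rows(
    tibble::tibble(
      dataset_id = "ds1", protein_id = names(fx$labels),
      chemical_id = "chemA", value = rnorm(32), bin = unname(fx$labels)
    ),
    tibble::tibble(
      dataset_id = "ds1", protein_id = names(fx$labels),
      chemical_id = "chemB", value = rnorm(32), bin = 0L # single class: skipped
    ),
    tibble::tibble(
      dataset_id = "ds2", protein_id = names(fx$labels)[1:16],
      chemical_id = "chemA", value = rnorm(16),
      bin = rep(c(0L, 1L), 8)
    )
  )
  expect_message(
    suppressWarnings(fits <- run_all_pairs(fx$fam, bin, fast_spec())),
    "skipped 1"
  )
  g <- glance(fits)
  expect_equal(nrow(g), 2)
  expect_setequal(paste(g$dataset_id, g$chemical_id), c("ds1 chemA", "ds2 chemA"))
  td <- tidy(fits)
  expect_true(all(c("dataset_id", "chemical_id", "position", "residue",
                    "importance", "model_auc") %in% names(td)))
  expect_error(run_all_pairs(fx$fam, bin[, -5], fast_spec()), "binarize")
})

test_that("importance scaling is min-max to 0..100 per model", {
  fx <- separable_fixture()
  ft <- build_feature_table(fx$fam)
  res <- suppressWarnings(train_pair(ft, fx$labels, fast_spec()))
  imp <- res$importances$importance
  expect_equal(max(imp), 100)
  expect_equal(min(imp), 0)
})
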