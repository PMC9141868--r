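fake_features <- function(...) {
  # rows: list(dataset, chemical, position, residue, importance, auc)
  rows <- list(...)
  purrr::map(rows, function(r) {
    tibble::tibble(
      dataset_id = r[[1]], chemical_id = r[[2]], position = as.integer(r[[3]]),
      residue = r[[4]], importance = as.numeric(r[[5]]), model_auc = as.numeric(r[[6]])
    )
  }) |> purrr::list_rbind()
}

test_that("feature gates are strict on both importance and AUC", {
  feats <- fake_features(
    list("ds1", "methyl_salicylate", 1472, "K", 14.4, 0.8), # kept
    list("ds1", "methyl_salicylate", 9, "A", 9.9, 0.99), # importance gate
    list("ds1", "methyl_salicylate", 9, "C", 50, 0.65), # AUC gate
    list("ds1", "methyl_salicylate", 9, "D", 10, 0.8) # boundary: strict >
  )
  kept <- filter_features(feats, importance_min = 10, auc_min = 0.7)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$position, 1472L)
})

test_that("times-predictive counts (residue, chemical) feature instances", {
  feats <- fake_features(
    list("ds1", "methyl_salicylate", 1472, "T", 31.5, 0.8),
    list("ds1", "methyl_salicylate", 1472, "P", 30.1, 0.8),
    list("ds1", "methyl_salicylate", 1472, "K", 14.4, 0.8),
    list("ds1", "geranyl_acetate", 1472, "L", 41.0, 0.8),
    list("ds1", "geranyl_acetate", 1472, "F", 27.3, 0.8),
    list("ds1", "geranyl_acetate", 1472, "A", 26.8, 0.8),
    list("ds1", "geranyl_acetate", 9, "W", 99, 0.9)
  )
  rk <- rank_positions(filter_features(feats))
  expect_equal(rk$times_predictive[rk$position == 1472], 6)
  expect_equal(rk$times_predictive[rk$position == 9], 1)
  # counts sum to the number of kept features
  expect_equal(sum(rk$times_predictive), nrow(filter_features(feats)))
})

test_that("ranking ties break by max importance then position", {
  feats <- fake_features(
    list("ds1", "c1", 30, "A", 80, 0.9), list("ds1", "c1", 30, "C", 20, 0.9),
    list("ds1", "c1", 10, "A", 40, 0.9), list("ds1", "c1", 10, "C", 39, 0.9),
    list("ds1", "c1", 20, "A", 40, 0.9), list("ds1", "c1", 20, "C", 38, 0.9)
  )
  rk <- rank_positions(filter_features(feats))
  # all tied at 2; 30 first (importance 80), then 10 and 20 (both max 40, index order)
  expect_equal(rk$position, c(30L, 10L, 20L))
  expect_warning(rank_positions(fake_features()[0, ]), "empty")
})

test_that("top-position unions have the right bounds and handle short rankings", {
  one_ranking <- function(ds, positions) {
    tibble::tibble(
      dataset_id = ds, position = as.integer(positions),
      times_predictive = rev(seq_along(positions)),
      max_importance = 50
    )
  }
  same <- dplyr::bind_rows(
    one_ranking("ds1", 1:10), one_ranking("ds2", 1:10), one_ranking("ds3", 1:10)
  )
  expect_equal(length(union_top_positions(same, k = 10)), 10)
  disjoint <- dplyr::bind_rows(
    one_ranking("ds1", 1:10), one_ranking("ds2", 11:20), one_ranking("ds3", 21:30)
  )
  expect_equal(length(union_top_positions(disjoint, k = 10)), 30)
  short <- dplyr::bind_rows(one_ranking("ds1", 1:3), one_ranking("ds2", 2:4))
  expect_message(u <- union_top_positions(short, k = 10), "shorter")
  expect_equal(u, 1:4)
  # property: k <= |union| <= 3k for three full rankings
  withr::with_seed(31, {
    for (i in 1:10) {
      rks <- dplyr::bind_rows(purrr::map(c("a", "b", "c"), function(ds) {
        one_ranking(ds, sample(1:40, 12))
      }))
      u <- union_top_positions(rks, k = 10)
      expect_gte(length(u), 10)
      expect_lte(length(u), 30)
    }
  })
})
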