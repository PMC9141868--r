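test_that("column conservation is the modal-residue frequency", {
  fam <- tiny_family(c(
    Sp1_a = "WAAD", Sp2_b = "WACE", Sp3_c = "WADF", Sp4_d = "FAEG", Sp5_e = "WAAH"
  ))
  cl <- tibble::tibble(seq_id = fam$seq_id, cluster_id = "C0")
  sc <- position_conservation(fam, cl, min_size = 5)
  expect_equal(sc$conservation[sc$position == 1], 4 / 5) # W,W,W,F,W
  expect_equal(sc$conservation[sc$position == 2], 1) # fully conserved
  expect_equal(sc$conservation[sc$position == 4], 1 / 5) # all distinct
})

test_that("gaps and X are excluded from count and denominator by default", {
  fam <- tiny_family(c(
    Sp1_a = "W-", Sp2_b = "W-", Sp3_c = "WX", Sp4_d = "F-", Sp5_e = "--"
  ))
  cl <- tibble::tibble(seq_id = fam$seq_id, cluster_id = "C0")
  sc <- position_conservation(fam, cl, min_size = 5)
  expect_equal(sc$conservation[sc$position == 1], 3 / 4) # W,W,W,F; the gap row ignored
  expect_true(is.na(sc$conservation[sc$position == 2])) # no residue at all
  expect_equal(sc$n_counted, c(4L, 0L))
  # gap-as-state alternative: column 2 is -,-,X,-,- and X stays excluded,
  # so the gap is modal among all 4 counted states
  sc2 <- position_conservation(fam, cl, min_size = 5, gap_as_state = TRUE)
  expect_equal(sc2$conservation[sc2$position == 2], 1)
  expect_equal(sc2$conservation[sc2$position == 1], 3 / 5) # W,W,W,F,- with the gap counted
})

test_that("clusters below the minimum size are not scored", {
  fam <- tiny_family(c(Sp1_a = "AA", Sp2_b = "AA", Sp3_c = "CC"))
  cl <- tibble::tibble(seq_id = fam$seq_id, cluster_id = c("C0", "C0", "C1"))
  sc <- position_conservation(fam, cl, min_size = 2)
  expect_setequal(unique(sc$cluster_id), "C0")
})

test_that("conservation matches the brute-force oracle on random families", {
  withr::with_seed(88, {
    for (i in 1:10) {
      n_seq <- sample(5:10, 1)
      n_col <- sample(3:10, 1)
      rows <- vapply(seq_len(n_seq), function(j) {
        paste(sample(c(strsplit("ACDEFGHIKL", "")[[1]], "-", "X"), n_col, TRUE),
          collapse = ""
        )
      }, character(1))
      fam <- tiny_family(setNames(rows, paste0("Sp", seq_len(n_seq), "_g")))
      cl <- tibble::tibble(seq_id = fam$seq_id, cluster_id = "C0")
      got <- position_conservation(fam, cl, min_size = 5)$conservation
      expect_identical(got, oracle_conservation(rows))
    }
  })
})

test_that("member order never changes any score", {
  withr::with_seed(12, {
    rows <- vapply(1:8, function(j) {
      paste(sample(c("A", "C", "D", "-"), 12, TRUE), collapse = "")
    }, character(1))
    fam <- tiny_family(setNames(rows, paste0("Sp", 1:8, "_g")))
    cl <- tibble::tibble(seq_id = fam$seq_id, cluster_id = "C0")
    base <- position_conservation(fam, cl)
    perm <- sample(8)
    fam2 <- fam[perm, ]
    attr(fam2, "n_columns") <- n_columns(fam)
    got <- position_conservation(fam2, cl[perm, ], min_size = 5)
    expect_equal(got, base)
  })
})

test_that("the conservation ratio behaves as arithmetic dictates", {
  fam <- tiny_family(c(
    Sp1_a = "WWAD", Sp2_b = "WWCE", Sp3_c = "WWDF", Sp4_d = "WWEG", Sp5_e = "WWAH"
  ))
  cl <- tibble::tibble(seq_id = fam$seq_id, cluster_id = "C0")
  # predictive set = all columns: ratio exactly 1
  all_cols <- cluster_conservation(fam, cl, 1:4)
  expect_equal(all_cols$ratio, 1)
  # predictive columns fully conserved (1.0) against background mean
  # (1 + 1 + 0.6 + 0.6 + 0.8)/5 = 0.8 -> ratio 1.25
  fam2 <- tiny_family(c(
    Sp1_a = "WAADC", Sp2_b = "WAADC", Sp3_c = "WAADC", Sp4_d = "WAFGC", Sp5_e = "WAFGA"
  ))
  cl2 <- tibble::tibble(seq_id = fam2$seq_id, cluster_id = "C0")
  prof <- cluster_conservation(fam2, cl2, c(1, 2))
  expect_equal(prof$c_pred, 1)
  expect_equal(prof$c_bg, 0.8)
  expect_equal(prof$ratio, 1.25)
  # guard rails
  expect_error(cluster_conservation(fam, cl, integer(0)), "empty")
  expect_error(cluster_conservation(fam, cl, 99), "bounds")
})

test_that("generated theta_bind > theta_bg clusters have ratios above 1 on average", {
  cfg <- sim_config(
    seed = 21, n_species = 8, n_social = 4, n_clusters = 10, n_columns = 60,
    theta_bg = 0.4, theta_bind = 0.9, n_binding = 6, mean_genes = 3, p_absent = 0.2
  )
  sim <- simulate_family(cfg)
  prof <- cluster_conservation(sim$family, sim$clusters, sim$binding_positions)
  expect_gt(mean(prof$ratio), 1)
})
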