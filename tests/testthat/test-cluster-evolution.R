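evo_fixture <- function() {
  # 3 species (Sp1, Sp2 social; Sp3 not), two clusters of >= 5 members
  seqs <- c(
    Sp1_a = "AAAA", Sp1_b = "AAAC", Sp1_c = "AAAD", Sp2_d = "AAAE", Sp2_e = "AAAF",
    Sp3_f = "CCCA", Sp3_g = "CCCC", Sp3_h = "CCCD", Sp3_i = "CCCE", Sp2_j = "CCCF"
  )
  fam <- tiny_family(seqs)
  cl <- tibble::tibble(
    seq_id = names(seqs),
    cluster_id = rep(c("C0", "C1"), each = 5)
  )
  tax <- tiny_taxonomy(c("Sp1", "Sp2", "Sp3"), c(TRUE, TRUE, FALSE))
  list(fam = fam, cl = cl, tax = tax)
}

test_that("enrichment is log2(sequences / species) with absent as NA", {
  fx <- evo_fixture()
  enr <- taxon_enrichment(fx$fam, fx$cl, fx$tax, min_size = 5)
  g <- function(cid, tc) enr$enrichment[enr$cluster_id == cid & enr$taxon_code == tc]
  # C0: 5 members from the 3-species root taxon
  expect_equal(g("C0", "A"), log2(5 / 3))
  # C0 social clade S (Sp1+Sp2): 5 sequences, 2 species
  expect_equal(g("C0", "S"), log2(5 / 2))
  # n sequences from an n-species taxon -> exactly 0
  expect_equal(g("C1", "A"), log2(5 / 3))
  expect_equal(g("C0", "A1"), log2(3 / 1))
  # absent taxon is NA, not -Inf
  expect_true(is.na(g("C0", "A3")))
  expect_false(any(is.infinite(enr$enrichment), na.rm = TRUE))
  # worked arithmetic: 14 sequences from an 8-species taxon
  expect_equal(log2(14 / 8), 0.8073549, tolerance = 1e-6)
})

test_that("doubling a cluster's membership from a taxon raises E by exactly 1", {
  fx <- evo_fixture()
  base <- taxon_enrichment(fx$fam, fx$cl, fx$tax, min_size = 5)
  # duplicate every C0 member (new ids, same species)
  extra_ids <- paste0(fx$cl$seq_id[fx$cl$cluster_id == "C0"], "_dup")
  fam2 <- or_family(
    c(fx$fam$seq_id, extra_ids),
    c(fx$fam$species_id, fx$fam$species_id[match(
      fx$cl$seq_id[fx$cl$cluster_id == "C0"], fx$fam$seq_id
    )]),
    c(fx$fam$aligned_seq, fx$fam$aligned_seq[match(
      fx$cl$seq_id[fx$cl$cluster_id == "C0"], fx$fam$seq_id
    )])
  )
  cl2 <- dplyr::bind_rows(fx$cl, tibble::tibble(seq_id = extra_ids, cluster_id = "C0"))
  doubled <- taxon_enrichment(fam2, cl2, fx$tax, min_size = 5)
  for (tc in c("A", "S", "A1", "A2")) {
    b <- base$enrichment[base$cluster_id == "C0" & base$taxon_code == tc]
    d <- doubled$enrichment[doubled$cluster_id == "C0" & doubled$taxon_code == tc]
    if (!is.na(b)) expect_equal(d, b + 1)
  }
})

test_that("cluster annotations compute expansion and social fraction", {
  fx <- evo_fixture()
  ann <- annotate_clusters(fx$fam, fx$cl, fx$tax, min_size = 5)
  a <- ann[ann$cluster_id == "C0", ]
  expect_equal(a$n_members, 5L)
  expect_equal(a$n_species_present, 2L) # Sp1, Sp2
  expect_equal(a$expansion, 2.5)
  expect_equal(a$social_fraction, 1) # all members social
  b <- ann[ann$cluster_id == "C1", ]
  expect_equal(b$social_fraction, 1 / 5) # one Sp2 member of five
  # 6 members from 2 species -> expansion 3; 11 from 11 -> 1
  expect_equal(6 / 2, 3)
})

test_that("median splits use strict inequality and partition the clusters", {
  ann <- tibble::tibble(
    cluster_id = paste0("C", 1:5),
    n_members = 10L, n_species_present = 2L,
    expansion = c(1, 2, 3, 4, 5),
    social_fraction = c(0.1, 0.2, 0.5, 0.9, 1),
    ratio = c(1.2, 1.1, 0.9, 1.05, 0.95)
  )
  res <- median_split_test(ann, "expansion")
  # median 3: strictly above -> {4, 5}
  expect_equal(res$n_high, 2)
  expect_equal(res$n_low, 3)
  expect_equal(res$n_high + res$n_low, nrow(ann))
  expect_error(
    median_split_test(ann[1:2, ], "expansion"),
    "degenerate"
  )
})

test_that("the Wilcoxon p matches exact enumeration for small groups", {
  # canonical case: perfectly separated ranks
  ann <- tibble::tibble(
    cluster_id = paste0("C", 1:6), n_members = 10L, n_species_present = 2L,
    expansion = c(1, 1, 1, 9, 9, 9), social_fraction = 0.5,
    ratio = c(1, 2, 3, 4, 5, 6)
  )
  res <- median_split_test(ann, "expansion")
  expect_equal(res$p_value, 0.1) # 2/20
  expect_equal(res$p_value, oracle_wilcoxon_p(c(4, 5, 6), c(1, 2, 3)))

  # random small instances, all group sizes <= 8, tie-free
  withr::with_seed(202, {
    for (i in 1:12) {
      m <- sample(2:8, 1); n <- sample(2:8, 1)
      vals <- sample(seq(0.5, 1.6, by = 0.01), m + n)
      p_pkg <- stats::wilcox.test(vals[1:m], vals[-(1:m)])$p.value
      expect_equal(p_pkg, oracle_wilcoxon_p(vals[1:m], vals[-(1:m)]),
        tolerance = 1e-12
      )
    }
  })
})

test_that("identical ratio distributions give non-significant splits", {
  withr::with_seed(55, {
    ps <- replicate(20, {
      ann <- tibble::tibble(
        cluster_id = paste0("C", 1:20), n_members = 10L, n_species_present = 2L,
        expansion = runif(20), social_fraction = runif(20),
        ratio = rnorm(20, 1, 0.05) # ratio independent of the criteria
      )
      median_split_test(ann, "social")$p_value
    })
    expect_gt(mean(ps), 0.2) # roughly uniform p-values, mean near 0.5
    expect_gt(max(ps), 0.5)
  })
})

test_that("species-specific cluster comparison recovers a planted contrast", {
  make_group <- function(seed, species, theta_bind, cluster_prefix) {
    cfg <- sim_config(
      seed = seed, n_species = 1, n_social = 0, n_clusters = 20,
      n_columns = 40, theta_bg = 0.6, theta_bind = theta_bind,
      binding_positions = 1:6, mean_genes = 10, p_absent = 0, gap_rate = 0
    )
    sim <- simulate_family(cfg)
    fam <- or_family(
      paste0(species, "_", sim$family$seq_id),
      rep(species, nrow(sim$family)), sim$family$aligned_seq
    )
    cl <- tibble::tibble(
      seq_id = fam$seq_id,
      cluster_id = paste0(cluster_prefix, sim$clusters$cluster_id)
    )
    list(fam = fam, cl = cl)
  }
  a <- make_group(1, "SpA", 0.95, "A") # conserved binding site
  b <- make_group(2, "SpB", 0.25, "B") # variable binding site
  fam <- or_family(
    c(a$fam$seq_id, b$fam$seq_id),
    c(a$fam$species_id, b$fam$species_id),
    c(a$fam$aligned_seq, b$fam$aligned_seq)
  )
  cl <- dplyr::bind_rows(a$cl, b$cl)
  cons <- cluster_conservation(fam, cl, 1:6)
  res <- species_specific_comparison(fam, cl, cons, "SpA", "SpB")
  expect_gte(res$n_a, 8)
  expect_gte(res$n_b, 8)
  expect_gt(res$mean_a, res$mean_b)
  expect_lt(res$p_value, 0.05)
  expect_error(
    species_specific_comparison(fam, cl, cons, "SpA", "SpZ"),
    "too few"
  )
})
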