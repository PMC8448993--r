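# A small hand-built two-generation table: two phenotyped parents (P1 x P2),
# one single-parent offspring (K3), and a sibship of three (K1, K2, K4).
family_fixture <- function() {
  tab <- pedigree_table(rbind(
    ped_df("P1", cohort_id = "G1", sex = "M", phenotype = 320),
    ped_df("P2", cohort_id = "G1", sex = "F", phenotype = 300),
    ped_df("P3", cohort_id = "G1", sex = "M", phenotype = 310),
    ped_df("K1", cohort_id = "G2", sex = "F", father_id = "P1",
           mother_id = "P2", sibship_id = "S1", phenotype = 315),
    ped_df("K2", cohort_id = "G2", sex = "M", father_id = "P1",
           mother_id = "P2", sibship_id = "S1", phenotype = 290),
    ped_df("K4", cohort_id = "G2", sex = "F", father_id = "P1",
           mother_id = "P2", sibship_id = "S1", phenotype = 305),
    ped_df("K3", cohort_id = "G2", sex = "M", father_id = "P3",
           sibship_id = "S2", phenotype = 312),
    ped_df("K5", cohort_id = "G2", sex = "M", father_id = "PX",
           mother_id = "PY", sibship_id = "S3", phenotype = 311)))
  adj <- compute_adjusted(tab, models = list(constant_model("G1", 300),
                                             constant_model("G2", 300)))
  list(tab = tab, adj = adj)
}

test_that("offspring-parent pairs: one pair per phenotyped parent", {
  fx <- family_fixture()
  op <- build_op_pairs(fx$adj, fx$tab)
  # 3 two-parent offspring -> 6 pairs, K3 -> 1 pair, K5's parents are
  # unphenotyped -> 0 pairs
  expect_equal(nrow(op), 7)
  expect_equal(sum(op$dependent_id == "K1"), 2)
  expect_equal(sum(op$dependent_id == "K5"), 0)
  expect_equal(attr(op, "n_unpaired"), 1)
  expect_true(all(op$weight == 1))
  # pairs carry the adjusted values of the right individuals
  k3 <- op[op$dependent_id == "K3", ]
  expect_equal(k3$x, 10)  # P3: 310 - 300
  expect_equal(k3$y, 12)
  # both pairs of one offspring share a resampling cluster
  expect_equal(length(unique(op$cluster_id[op$dependent_id == "K1"])), 1)
  expect_equal(op$cluster_id[op$dependent_id == "K1"][1],
               op$cluster_id[op$dependent_id == "K2"][1])
})

test_that("full-sib pairs use k(k-1) ordered pairs with weight 1/(k-1)", {
  fx <- family_fixture()
  fs <- build_fs_pairs(fx$adj, fx$tab)
  # sibship of 3 -> 6 pairs; singletons S2, S3 contribute nothing
  expect_equal(nrow(fs), 6)
  expect_true(all(fs$weight == 0.5))
  expect_true(all(fs$cluster_id == "S1"))
  expect_equal(attr(fs, "n_sibs"), 3)
  expect_equal(attr(fs, "n_sibships"), 1)
  # each sibling appears exactly k-1 times on each side
  expect_true(all(table(fs$dependent_id) == 2))
  expect_true(all(table(fs$independent_id) == 2))
  expect_true(all(fs$dependent_id != fs$independent_id))
})

test_that("sibship weighting invariants hold on generated pedigrees", {
  tab <- generate_pedigree(sim_params(n_families = 300, seed = 14))
  adj <- compute_adjusted(tab)
  fs <- build_fs_pairs(adj, tab)
  per <- split(fs, fs$cluster_id)
  for (g in per) {
    k <- length(unique(g$dependent_id))
    expect_equal(nrow(g), k * (k - 1))
    expect_equal(sum(g$weight), k)  # total dependent-side weight k
    expect_equal(unique(g$weight), 1 / (k - 1))
  }
  # a sibship-of-two pedigree: 2 pairs each of weight 1
  p2 <- sim_params(n_families = 20, sibship_size_dist = c(0, 1), seed = 15)
  tab2 <- generate_pedigree(p2)
  fs2 <- build_fs_pairs(compute_adjusted(tab2), tab2)
  expect_equal(nrow(fs2), 40)
  expect_true(all(fs2$weight == 1))
})

test_that("ordered FS pairs equal the doubled unordered pair list", {
  tab <- generate_pedigree(sim_params(n_families = 150, seed = 16))
  adj <- compute_adjusted(tab)
  fs <- build_fs_pairs(adj, tab)
  # unweighted slope from ordered pairs vs explicit double of i<j pairs
  key <- ifelse(fs$dependent_id < fs$independent_id,
                paste(fs$dependent_id, fs$independent_id),
                paste(fs$independent_id, fs$dependent_id))
  expect_true(all(table(key) == 2))
  b_ordered <- stats::cov(fs$x, fs$y) / stats::var(fs$x)
  un <- fs[fs$dependent_id < fs$independent_id, ]
  dbl <- rbind(un, data.frame(dependent_id = un$independent_id,
                              independent_id = un$dependent_id,
                              y = un$x, x = un$y, weight = un$weight,
                              cluster_id = un$cluster_id))
  b_doubled <- stats::cov(dbl$x, dbl$y) / stats::var(dbl$x)
  expect_equal(b_ordered, b_doubled, tolerance = 1e-12)
})

test_that("pair construction is deterministic regardless of input order", {
  tab <- generate_pedigree(sim_params(n_families = 100, seed = 17))
  adj <- compute_adjusted(tab)
  shuffled <- adj[sample(nrow(adj)), ]
  attributes(shuffled) <- c(attributes(shuffled),
                            attributes(adj)["models"])
  class(shuffled) <- class(adj)
  expect_equal(as.data.frame(build_op_pairs(adj, tab)),
               as.data.frame(build_op_pairs(shuffled, tab)))
  expect_equal(as.data.frame(build_fs_pairs(adj, tab)),
               as.data.frame(build_fs_pairs(shuffled, tab)))
})

test_that("spouse correlation behaves at its logical extremes", {
  n <- 40
  vals <- rnorm(n)
  tab <- pedigree_table(rbind(
    ped_df(sprintf("F%02d", 1:n), cohort_id = "G1", sex = "M",
           phenotype = 300 + vals),
    ped_df(sprintf("M%02d", 1:n), cohort_id = "G1", sex = "F",
           phenotype = 300 + vals),
    ped_df(sprintf("K%02d", 1:n), cohort_id = "G2",
           father_id = sprintf("F%02d", 1:n),
           mother_id = sprintf("M%02d", 1:n), phenotype = 300)))
  adj <- compute_adjusted(tab, models = list(constant_model("G1", 300),
                                             constant_model("G2", 300)))
  res <- spouse_correlation(adj, tab)
  expect_equal(res$r, 1)
  expect_equal(res$n_couples, n)

  set.seed(3)
  tab2 <- pedigree_table(rbind(
    ped_df(sprintf("F%03d", 1:400), cohort_id = "G1", sex = "M",
           phenotype = 300 + rnorm(400)),
    ped_df(sprintf("M%03d", 1:400), cohort_id = "G1", sex = "F",
           phenotype = 300 + rnorm(400)),
    ped_df(sprintf("K%03d", 1:400), cohort_id = "G2",
           father_id = sprintf("F%03d", 1:400),
           mother_id = sprintf("M%03d", 1:400), phenotype = 300)))
  adj2 <- compute_adjusted(tab2, models = list(constant_model("G1", 300),
                                               constant_model("G2", 300)))
  expect_lt(abs(spouse_correlation(adj2, tab2)$r), 0.12)

  few <- adj2[adj2$individual_id %in% c("F001", "M001", "K001"), ]
  class(few) <- class(adj2)
  expect_error(spouse_correlation(few, tab2), "insufficient")
})
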