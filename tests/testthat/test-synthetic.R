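test_that("simulated cladograms have the promised shape and determinism", {
  tr <- simulate_cladogram(34, seed = 1)
  expect_equal(length(tr$tip.label), 34L)
  expect_equal(tr$Nnode, 33L)                    # rooted binary: n - 1
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))
  expect_identical(ape::write.tree(simulate_cladogram(34, seed = 1)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_cladogram(34, seed = 2)),
                         ape::write.tree(tr)))
  tr3 <- simulate_cladogram(3, seed = 1)
  expect_equal(tr3$Nnode, 2L)
  expect_error(simulate_cladogram(2), "n_taxa")
})

test_that("simulated matrices match the configured composition", {
  tr <- simulate_cladogram(34, seed = 4)
  m <- simulate_matrix(tr, sim_config(seed = 9))
  sm <- summarize_matrix(m)
  expect_equal(c(sm$n_taxa, sm$n_char), c(34L, 51L))
  expect_equal(c(sm$binary, sm$ordered, sm$unordered), c(28L, 19L, 4L))
  # missing fraction within one percentage point of the configured value
  expect_lt(abs(sm$missing_fraction - 0.1), 0.01 + 3 * sqrt(0.09 / (34 * 51)))
  # determinism under the same seed
  m2 <- simulate_matrix(tr, sim_config(seed = 9))
  expect_identical(m$cells, m2$cells)
})

test_that("recorded true changes bound the parsimony steps from above", {
  for (seed in 1:5) {
    tr <- simulate_cladogram(10, seed = seed)
    m <- simulate_matrix(tr, sim_config(n_taxa = 10, n_binary = 15,
                                        n_ordered = 8, n_unordered = 4,
                                        rate = 0.4, missing_fraction = 0,
                                        polymorphism_fraction = 0,
                                        seed = seed + 50))
    sc <- score_tree(tr, m)
    expect_true(all(sc$chars$s <= attr(m, "true_changes")))
  }
})

test_that("rate zero gives constant characters and CI = 1", {
  tr <- simulate_cladogram(8, seed = 3)
  m <- simulate_matrix(tr, sim_config(n_taxa = 8, n_binary = 10,
                                      n_ordered = 5, n_unordered = 2,
                                      rate = 0, missing_fraction = 0,
                                      polymorphism_fraction = 0, seed = 8))
  sc <- score_tree(tr, m)
  expect_equal(sc$length, 0)
  expect_equal(sc$ci, 1)
  expect_equal(sum(attr(m, "true_changes")), 0L)
})

test_that("ordered characters stay inside their declared alphabet", {
  tr <- simulate_cladogram(12, seed = 6)
  m <- simulate_matrix(tr, sim_config(n_taxa = 12, n_binary = 0,
                                      n_ordered = 20, n_unordered = 0,
                                      max_states = 4, rate = 2,
                                      missing_fraction = 0,
                                      polymorphism_fraction = 0.1, seed = 7))
  states <- unlist(lapply(m$cells[!is.na(m$cells)],
                          cladistica:::cell_states))
  expect_true(all(states >= 0 & states <= 3))
})

test_that("a small recovery experiment runs, is seeded, and scores honestly", {
  cfg <- sim_config(n_taxa = 8, n_binary = 25, n_ordered = 10,
                    n_unordered = 5, rate = 0.05, missing_fraction = 0,
                    polymorphism_fraction = 0, seed = 2)
  r1 <- recovery_experiment(cfg, n_reps = 6)
  r2 <- recovery_experiment(cfg, n_reps = 6)
  expect_identical(r1$details, r2$details)
  expect_gte(r1$recovery, 0); expect_lte(r1$recovery, 1)
  expect_gte(r1$mean_rf, 0); expect_lte(r1$mean_rf, 1)
})

test_that("shuffled-tip negative control collapses recovery", {
  # permuting tip labels destroys the signal: the true tree should almost
  # never remain optimal for a matrix evolved on a shuffled relabelling
  hits <- 0L
  for (i in 1:6) {
    tr <- simulate_cladogram(10, seed = 300 + i)
    m <- simulate_matrix(tr, sim_config(n_taxa = 10, n_binary = 40,
                                        n_ordered = 8, n_unordered = 2,
                                        rate = 0.3, missing_fraction = 0,
                                        polymorphism_fraction = 0,
                                        seed = 400 + i))
    shuffled <- tr
    shuffled$tip.label <- cladistica:::with_seed(500 + i,
                                                 sample(tr$tip.label))
    bb <- branch_and_bound(m, search_config())
    if (score_tree(shuffled, m)$length <= bb$objective + 1e-9) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("rf_distance agrees with an independent implementation", {
  for (i in 1:10) {
    a <- rand_tree(8, seed = 1700 + i)
    b <- rand_tree(8, seed = 1800 + i)
    expect_equal(rf_distance(a, b),
                 as.numeric(phangorn::RF.dist(ape::unroot(a), ape::unroot(b),
                                              normalize = TRUE)))
  }
})
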