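test_that("exhaustive enumeration visits the right number of topologies", {
  s4 <- sim_small(n = 4, seed = 1, rate = 0.3, nb = 6, no = 0, nu = 0)
  ex4 <- exhaustive_search(s4$m, search_config(mode = "exhaustive"))
  expect_equal(ex4$log$topologies_scored, 3)       # (2*4-5)!! = 3
  s6 <- sim_small(n = 6, seed = 2, rate = 0.3, nb = 8, no = 0, nu = 0)
  ex6 <- exhaustive_search(s6$m, search_config(mode = "exhaustive"))
  expect_equal(ex6$log$topologies_scored, 105)     # 7!! = 105
  expect_error(exhaustive_search(sim_small(n = 11, seed = 3)$m), "10 taxa")
})

test_that("branch and bound matches exhaustive search on both criteria", {
  for (i in 1:12) {
    n <- sample(6:8, 1)
    s <- sim_small(n = n, seed = 30 + i, rate = 0.5, nb = 8, no = 4, nu = 2,
                   miss = 0.1, poly = 0.05)
    for (crit in c("equal", "implied")) {
      cfg <- search_config(criterion = crit, K = 3, max_trees = 1e5)
      ex <- exhaustive_search(s$m, cfg)
      bb <- branch_and_bound(s$m, cfg)
      expect_equal(bb$objective, ex$objective, tolerance = 1e-9)
      expect_setequal(bb$binary_keys, ex$binary_keys)
    }
  }
})

test_that("a homoplasy-free matrix yields the generating tree as unique MPC", {
  tr <- rand_tree(8, seed = 5)
  m <- perfect_matrix(tr)              # zero-convergence clade characters
  sc <- score_tree(tr, m)
  expect_equal(sc$ci, 1)
  bb <- branch_and_bound(m, search_config())
  expect_equal(bb$objective, sc$length)
  expect_length(bb$mpcs, 1L)
  expect_identical(bb$binary_keys, canonical_key_of(tr))
})

test_that("heuristic search reaches the exact optimum on seeded replicates", {
  hits <- 0L
  for (i in 1:20) {
    s <- sim_small(n = 8, seed = 50 + i, rate = 0.4, nb = 15, no = 5, nu = 2)
    bb <- branch_and_bound(s$m, search_config())
    hs <- heuristic_search(s$m, search_config(mode = "heuristic",
                                              n_replicates = 5,
                                              seed = 1000 + i))
    if (abs(hs$objective - bb$objective) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("seeded heuristic searches are bit-reproducible", {
  s <- sim_small(n = 10, seed = 66, rate = 0.5, nb = 20, no = 5, nu = 2)
  cfg <- search_config(mode = "heuristic", n_replicates = 4, seed = 9)
  h1 <- heuristic_search(s$m, cfg)
  h2 <- heuristic_search(s$m, cfg)
  expect_identical(h1$binary_keys, h2$binary_keys)
  expect_identical(h1$objective, h2$objective)
})

test_that("three-taxon input returns the unique unrooted topology", {
  s <- sim_small(n = 3, seed = 70, rate = 0.2, nb = 5, no = 0, nu = 0)
  hs <- heuristic_search(s$m, search_config(mode = "heuristic"))
  expect_length(hs$mpcs, 1L)
})

test_that("NNI and TBR swap modes also find the optimum on easy data", {
  s <- sim_small(n = 7, seed = 80, rate = 0.3, nb = 20, no = 4, nu = 2)
  bb <- branch_and_bound(s$m, search_config())
  for (sw in c("nni", "tbr")) {
    hs <- heuristic_search(s$m, search_config(mode = "heuristic",
                                              n_replicates = 4, swap = sw,
                                              seed = 2))
    expect_equal(hs$objective, bb$objective, tolerance = 1e-9, label = sw)
  }
})

test_that("condensation is idempotent and collapse rules nest", {
  s <- sim_small(n = 8, seed = 90, rate = 0.25, nb = 12, no = 4, nu = 2)
  bbn <- branch_and_bound(s$m, search_config(collapse = "none"))
  bbz <- branch_and_bound(s$m, search_config(collapse = "min_length_zero"))
  expect_gte(length(bbn$mpcs), length(bbz$mpcs))
  t1 <- bbz$mpcs[[1]]
  once <- condense_tree(t1, s$m)
  twice <- condense_tree(once, s$m)
  expect_equal(canonical_key_of(once), canonical_key_of(twice))
})

test_that("k_sweep partitions the grid into MPC-stability intervals", {
  s <- sim_small(n = 8, seed = 95, rate = 0.6, nb = 15, no = 5, nu = 2)
  sw <- k_sweep(s$m, K_grid = c(1, 2, 3, 1e6),
                config = search_config(criterion = "implied"))
  expect_equal(sum(sw$stability$K_to >= sw$stability$K_from),
               nrow(sw$stability))
  expect_equal(sw$stability$K_from[1], 1)
  # K -> infinity limit equals the equal-weights MPC set
  eq <- branch_and_bound(s$m, search_config(criterion = "equal"))
  expect_setequal(sw$results[["1e+06"]]$mpc_keys, eq$mpc_keys)
  expect_error(k_sweep(s$m, K_grid = numeric(0)), "empty")
  expect_error(k_sweep(s$m, K_grid = c(1, -2)), "positive")
})

test_that("branch-and-bound optimum matches an independent exact search", {
  for (i in 1:4) {
    tr <- rand_tree(8, seed = 1500 + i)
    cells <- sapply(1:14, function(j)
      rand_char(tr$tip.label, 2, seed = 1600 + 20 * i + j))
    rownames(cells) <- tr$tip.label
    m <- char_matrix(cells)
    bb <- branch_and_bound(m, search_config())
    pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1"))
    ref <- phangorn::bab(pd, trace = 0)
    ref_len <- min(phangorn::parsimony(ref, pd, method = "fitch"))
    expect_equal(bb$objective, as.numeric(ref_len))
  }
})
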