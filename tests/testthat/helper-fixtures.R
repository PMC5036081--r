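# shared fixtures and independent oracles, all built in code

# tiny hand-coded matrix: 4 taxa, 3 characters (binary, ordered, unordered)
toy_matrix <- function() {
  cells <- rbind(A = c("0", "0", "0"),
                 B = c("0", "1", "1"),
                 C = c("1", "2", "?"),
                 D = c("1", "2", "2"))
  char_matrix(cells, types = c("binary", "ordered", "unordered"),
              n_states = c(2L, 3L, 3L))
}

# random labelled tree (binary, rooted) under a local seed
rand_tree <- function(n, seed) {
  cladistica:::with_seed(seed, {
    tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- paste0("t", seq_len(n))
    tr
  })
}

# random character column as a named coding vector
rand_char <- function(tips, ns, seed, p_poly = 0, p_miss = 0) {
  cladistica:::with_seed(seed, {
    cells <- as.character(sample(0:(ns - 1), length(tips), replace = TRUE))
    for (i in seq_along(cells)) {
      u <- stats::runif(1)
      if (u < p_miss) cells[i] <- NA_character_
      else if (u < p_miss + p_poly) {
        other <- sample(setdiff(0:(ns - 1), as.integer(cells[i])), 1)
        cells[i] <- paste(sort(c(as.integer(cells[i]), other)), collapse = "")
      }
    }
    stats::setNames(cells, tips)
  })
}

# exhaustive minimum-mutation oracle: enumerate every assignment of internal
# states (and tip choices within polymorphic sets implicitly, via min)
brute_force_steps <- function(tree, char, cost) {
  nTip <- length(tree$tip.label)
  nNode <- max(tree$edge)
  internals <- (nTip + 1):nNode
  ns <- nrow(cost)
  sets <- lapply(char[tree$tip.label], function(cell) {
    if (is.na(cell)) 0:(ns - 1)
    else strtoi(strsplit(cell, "")[[1]], base = 16L)
  })
  best <- Inf
  asn <- rep(1L, length(internals))
  repeat {
    st <- integer(nNode)
    st[internals] <- asn - 1L
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      tot <- tot + if (ch <= nTip)
        min(cost[st[p] + 1, sets[[ch]] + 1]) else cost[st[p] + 1, st[ch] + 1]
    }
    best <- min(best, tot)
    j <- 1L
    while (j <= length(asn)) {
      asn[j] <- asn[j] + 1L
      if (asn[j] <= ns) break
      asn[j] <- 1L; j <- j + 1L
    }
    if (j > length(asn)) break
  }
  best
}

unit_cost <- function(ns) {
  cost <- matrix(1, ns, ns); diag(cost) <- 0; cost
}
linear_cost <- function(ns) abs(outer(0:(ns - 1), 0:(ns - 1), "-"))

# small simulated matrix with a known generating tree
sim_small <- function(n = 8, seed = 1, rate = 0.3, nb = 10, no = 5, nu = 3,
                      miss = 0, poly = 0) {
  tr <- simulate_cladogram(n, seed = seed)
  m <- simulate_matrix(tr, sim_config(n_taxa = n, n_binary = nb,
                                      n_ordered = no, n_unordered = nu,
                                      rate = rate, missing_fraction = miss,
                                      polymorphism_fraction = poly,
                                      seed = seed + 1000))
  list(tree = tr, m = m)
}

extdata <- function(f) system.file("extdata", f, package = "cladistica")

canonical_key_of <- function(tree) cladistica:::canonical_key(tree)
measurement_value_of <- function(tab, name) cladistica:::measurement_value(tab, name)

# homoplasy-free matrix built from a tree: `copies` binary clade-membership
# characters per internal edge (zero-convergence evolution by construction;
# copies > 1 make every clade robust to resampling out single characters)
perfect_matrix <- function(tree, copies = 1L) {
  labels <- tree$tip.label
  splits <- cladistica:::bipartitions(tree)
  cells <- sapply(rep(splits, each = copies), function(k) {
    side <- strsplit(k, ",", fixed = TRUE)[[1]]
    ifelse(labels %in% side, "1", "0")
  })
  rownames(cells) <- labels
  char_matrix(cells)
}
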