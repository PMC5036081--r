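#' Simulation configuration
#'
#' Defaults emulate the shape of a typical beaked-whale morphological
#' matrix: 34 taxa and 51 characters of which 28 binary, 19 ordered
#' multistate and 4 unordered multistate, with a modest fraction of missing
#' and polymorphic cells.
#'
#' @param n_taxa number of taxa.
#' @param n_binary,n_ordered,n_unordered character mix.
#' @param max_states alphabet size for multistate characters (>= 3).
#' @param rate expected number of state changes per character per branch.
#' @param missing_fraction,polymorphism_fraction cell perturbation rates.
#' @param seed RNG seed.
#' @export
sim_config <- function(n_taxa = 34, n_binary = 28, n_ordered = 19,
                       n_unordered = 4, max_states = 3, rate = 0.1,
                       missing_fraction = 0.1, polymorphism_fraction = 0.02,
                       seed = 1L) {
  stopifnot(n_taxa >= 3, n_binary >= 0, n_ordered >= 0, n_unordered >= 0,
            max_states >= 3,
            missing_fraction >= 0, missing_fraction <= 1,
            polymorphism_fraction >= 0, polymorphism_fraction <= 1,
            rate >= 0)
  structure(list(n_taxa = n_taxa, n_binary = n_binary, n_ordered = n_ordered,
                 n_unordered = n_unordered, max_states = max_states,
                 rate = rate, missing_fraction = missing_fraction,
                 polymorphism_fraction = polymorphism_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random cladogram
#'
#' Yule-style rooted binary tree (pure-birth, via [ape::rphylo()]) with
#' branch lengths rescaled to unit mean; reproducible by seed.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed RNG seed.
#' @export
simulate_cladogram <- function(n_taxa, seed = 1L) {
  if (n_taxa < 3) stop("need n_taxa >= 3")
  with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tr$tip.label <- paste0("t", seq_len(n_taxa))
    tr$edge.length <- tr$edge.length / mean(tr$edge.length)
    tr
  })
}

#' Evolve a character matrix along a known tree
#'
#' Characters evolve independently along `tree`: unordered characters by
#' symmetric (Mk-style) jumps to a uniformly chosen other state, ordered
#' characters by stepwise +/-1 walks reflecting at the ends of their state
#' range. The number of change events on each branch is Poisson with mean
#' `rate` (per branch: branch lengths are carried on the tree for display
#' but do not modulate the change process, so internal and terminal
#' branches are equally informative). Missing and polymorphic cells are then injected
#' at the configured rates (polymorphism adds one adjacent state for
#' ordered characters, a random other state for unordered ones). The true
#' per-character number of change events is recorded in
#' `attr(m, "true_changes")`; as `rate -> 0` the matrix becomes
#' homoplasy-free.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param cfg a [sim_config()].
#' @return a [char_matrix()] with attributes `true_changes` and
#'   `true_tree`.
#' @export
simulate_matrix <- function(tree, cfg = sim_config()) {
  nTip <- length(tree$tip.label)
  nChar <- cfg$n_binary + cfg$n_ordered + cfg$n_unordered
  types <- c(rep("binary", cfg$n_binary), rep("ordered", cfg$n_ordered),
             rep("unordered", cfg$n_unordered))
  ns <- ifelse(types == "binary", 2L, cfg$max_states)
  with_seed(cfg$seed, {
    tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    nNode <- max(tree$edge)
    root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
    ord <- seq_len(nrow(tree$edge))
    cells <- matrix(NA_character_, nTip, nChar,
                    dimnames = list(tree$tip.label, NULL))
    changes <- integer(nChar)
    for (j in seq_len(nChar)) {
      state <- integer(nNode)
      state[root] <- sample.int(ns[j], 1) - 1L
      for (i in ord) {
        p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
        s <- state[p]
        k <- stats::rpois(1, cfg$rate)
        if (k > 0) {
          for (e in seq_len(k)) {
            if (types[j] == "ordered") {
              # +/-1 walk, reflecting at 0 and ns-1
              step <- sample(c(-1L, 1L), 1)
              s2 <- s + step
              if (s2 < 0 || s2 >= ns[j]) s2 <- s - step
            } else {
              s2 <- sample(setdiff(0:(ns[j] - 1L), s), 1)
            }
            if (s2 != s) changes[j] <- changes[j] + 1L
            s <- s2
          }
        }
        state[ch] <- s
      }
      cells[, j] <- as.character(state[seq_len(nTip)])
    }
    # polymorphism, then missing
    for (j in seq_len(nChar)) {
      poly <- stats::runif(nTip) < cfg$polymorphism_fraction
      for (i in which(poly)) {
        s <- as.integer(cells[i, j])
        other <- if (types[j] == "ordered") {
          cand <- c(s - 1L, s + 1L)
          cand <- cand[cand >= 0 & cand < ns[j]]
          sample(cand, 1)
        } else sample(setdiff(0:(ns[j] - 1L), s), 1)
        cells[i, j] <- paste(sort(c(s, other)), collapse = "")
      }
      gone <- stats::runif(nTip) < cfg$missing_fraction
      cells[gone, j] <- NA_character_
    }
    m <- char_matrix(cells, types = types, n_states = ns)
    attr(m, "true_changes") <- changes
    attr(m, "true_tree") <- tree
    m
  })
}

#' Tree-recovery experiment on simulated data
#'
#' Simulates `n_reps` matrices on independent random trees and re-searches
#' each one, recording whether the generating tree is among the recovered
#' MPCs and the Robinson-Foulds distance between the strict consensus of
#' the MPCs and the truth.
#'
#' @param cfg a [sim_config()]; its seed seeds the whole experiment.
#' @param n_reps number of replicates.
#' @param config a [search_config()] used for each re-search.
#' @return list with `recovery` (fraction of replicates whose MPC set
#'   contains the truth), `mean_rf` (mean normalized RF distance of the
#'   strict consensus to the truth) and the per-replicate data.frame.
#' @export
recovery_experiment <- function(cfg = sim_config(n_taxa = 10, n_binary = 30,
                                                 n_ordered = 15,
                                                 n_unordered = 5,
                                                 rate = 0.05,
                                                 missing_fraction = 0,
                                                 polymorphism_fraction = 0),
                                n_reps = 50,
                                config = search_config()) {
  seeds <- with_seed(cfg$seed, sample.int(1e6, 2 * n_reps))
  rows <- list()
  for (r in seq_len(n_reps)) {
    tr <- simulate_cladogram(cfg$n_taxa, seed = seeds[2 * r - 1])
    cfg_r <- cfg; cfg_r$seed <- seeds[2 * r]
    m <- simulate_matrix(tr, cfg_r)
    res <- run_search(m, config)
    # a binary tree is among the MPCs iff it attains the optimal score
    # (exact even when the enumerated tie set is capped)
    truth_obj <- if (config$criterion == "implied") {
      sc <- score_tree(tr, m, K = config$K)
      sum(sc$chars$es / (config$K + sc$chars$es))
    } else score_tree(tr, m)$length
    hit <- truth_obj <= res$objective + 1e-9
    cons_splits <- res$consensus_splits
    truth_splits <- bipartitions(tr)
    rf <- (length(setdiff(cons_splits, truth_splits)) +
           length(setdiff(truth_splits, cons_splits))) /
          max(1L, length(cons_splits) + length(truth_splits))
    rows[[r]] <- data.frame(rep = r, recovered = hit, n_mpcs =
                              length(res$mpcs), rf_consensus = rf)
  }
  df <- do.call(rbind, rows)
  list(recovery = mean(df$recovered), mean_rf = mean(df$rf_consensus),
       details = df)
}

#' Robinson-Foulds distance via shared bipartitions
#'
#' Normalized to `[0, 1]` by the total number of internal splits in the
#' two trees.
#' @param a,b `phylo` objects on the same leaf set.
#' @export
rf_distance <- function(a, b) {
  ba <- bipartitions(a); bb <- bipartitions(b)
  denom <- length(ba) + length(bb)
  if (denom == 0) return(0)
  (length(setdiff(ba, bb)) + length(setdiff(bb, ba))) / denom
}
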