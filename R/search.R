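#' Search configuration
#'
#' Bundles the options shared by the tree-search functions.
#'
#' @param criterion `"equal"` (minimize tree length) or `"implied"`
#'   (maximize Goloboff fit at concavity `K`).
#' @param K concavity constant for implied weighting (default 3, the value
#'   conventionally used in beaked-whale cladistics).
#' @param mode `"branch_and_bound"`, `"exhaustive"` (<= 10 taxa) or
#'   `"heuristic"`.
#' @param n_replicates random-addition starts for the heuristic search.
#' @param swap branch-swapping neighborhood: `"spr"` (default), `"nni"` or
#'   `"tbr"`.
#' @param seed integer RNG seed; all stochastic steps run under it.
#' @param collapse branch-collapse rule applied before counting distinct
#'   cladograms: `"min_length_zero"` (PAUP `amb-` analogue, default) or
#'   `"none"`.
#' @param max_trees cap on retained equally optimal trees.
#' @export
search_config <- function(criterion = c("equal", "implied"), K = 3,
                          mode = c("branch_and_bound", "exhaustive", "heuristic"),
                          n_replicates = 10, swap = c("spr", "nni", "tbr"),
                          seed = 1L,
                          collapse = c("min_length_zero", "none"),
                          max_trees = 10000L) {
  criterion <- match.arg(criterion)
  if (criterion == "implied" && (!is.numeric(K) || K <= 0))
    stop("implied weighting requires a positive concavity K")
  structure(list(criterion = criterion, K = K, mode = match.arg(mode),
                 n_replicates = as.integer(n_replicates),
                 swap = match.arg(swap), seed = as.integer(seed),
                 collapse = match.arg(collapse),
                 max_trees = as.integer(max_trees)),
            class = "search_config")
}

# engine-ready data bundle
engine_data <- function(m, config, weights = NULL) {
  validate_char_matrix(m)
  bm <- state_bitmasks(m)
  st <- char_stats(m)
  list(bm = bm, ordered = m$chars$type == "ordered",
       nstates = m$chars$n_states,
       weights = if (is.null(weights)) rep(1, nrow(m$chars)) else weights,
       minref = as.numeric(st$m),
       K = if (config$criterion == "implied") config$K else 1,
       implied = config$criterion == "implied",
       labels = m$taxa)
}

# taxa with most scored cells first: grows informative partial trees early,
# which tightens the branch-and-bound lower bound
addition_order <- function(m) {
  order(rowSums(!is.na(m$cells)), decreasing = TRUE)
}

# Per-level completion bounds for branch-and-bound. Row (k+1), column c is
# an admissible lower bound on the extra steps character c must gain when
# the taxa beyond the first k of `ord` are added: states required by a yet
# unplaced monomorphic tip and unavailable to every placed tip each cost at
# least one further step (unordered), and ordered characters must at least
# span from the placed tips' reachable range to the outermost state
# required by an unplaced monomorphic tip.
completion_bounds <- function(m, ord) {
  bm <- state_bitmasks(m)
  nTip <- length(m$taxa); nChar <- nrow(m$chars)
  singl <- matrix(NA_integer_, nTip, nChar)
  for (j in seq_len(nChar)) for (i in seq_len(nTip)) {
    cell <- m$cells[i, j]
    if (!is.na(cell) && nchar(cell) == 1L)
      singl[i, j] <- strtoi(cell, base = 16L)
  }
  ex <- matrix(0L, nTip + 1, nChar)
  for (j in seq_len(nChar)) {
    ns <- m$chars$n_states[j]
    ordchar <- m$chars$type[j] == "ordered"
    cnt <- tabulate(singl[, j] + 1L, ns)     # unplaced monomorphic tips
    avail <- 0L
    for (k in 0:nTip) {
      if (k > 0) {
        i <- ord[k]
        avail <- bitwOr(avail, bm[i, j])
        if (!is.na(singl[i, j]))
          cnt[singl[i, j] + 1L] <- cnt[singl[i, j] + 1L] - 1L
      }
      if (k >= 3 && k < nTip) {
        req <- which(cnt > 0L) - 1L
        if (length(req)) {
          av <- which(bitwAnd(avail, bitwShiftL(1L, 0:(ns - 1))) > 0L) - 1L
          if (ordchar) {
            ex[k + 1, j] <- max(0L, min(av) - min(req)) +
                            max(0L, max(req) - max(av))
          } else {
            ex[k + 1, j] <- sum(!(req %in% av))
          }
        }
      }
    }
  }
  ex
}

# orient an unrooted engine edge matrix as rooted at tip 1 (parent, child)
orient_edges <- function(em) {
  adj <- vector("list", max(em))
  for (i in seq_len(nrow(em))) {
    adj[[em[i, 1]]] <- c(adj[[em[i, 1]]], em[i, 2])
    adj[[em[i, 2]]] <- c(adj[[em[i, 2]]], em[i, 1])
  }
  out <- matrix(0L, nrow(em), 2)
  parent <- integer(length(adj)); parent[1] <- -1L
  stack <- 1L; n <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (u in adj[[v]]) if (u != parent[v]) {
      n <- n + 1L
      out[n, ] <- c(v, u)
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  out
}

# row-aligned bipartition keys of an engine edge matrix (NA for tip edges)
edge_split_keys <- function(em, nTip, labels, ref = NULL) {
  if (is.null(ref)) ref <- sort(labels)[1]
  adj <- vector("list", max(em))
  for (i in seq_len(nrow(em))) {
    adj[[em[i, 1]]] <- c(adj[[em[i, 1]]], em[i, 2])
    adj[[em[i, 2]]] <- c(adj[[em[i, 2]]], em[i, 1])
  }
  keys <- rep(NA_character_, nrow(em))
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    if (a <= nTip || b <= nTip) next
    seen <- logical(length(adj)); seen[a] <- TRUE
    stack <- b; seen[b] <- TRUE; tips <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= nTip) tips <- c(tips, v)
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
    }
    side <- labels[tips]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) < 2L || length(side) > nTip - 2L) next
    keys[i] <- paste(sort(side), collapse = ",")
  }
  keys
}

finalize_result <- function(raw_trees, best, m, config, ed, log = list()) {
  nTip <- length(ed$labels)
  labels <- ed$labels
  rowkeys <- lapply(raw_trees, edge_split_keys, nTip = nTip, labels = labels)
  bsets <- lapply(rowkeys, function(k) unique(k[!is.na(k)]))
  bkeys <- vapply(bsets, function(k) paste(sort(k), collapse = ";"), "")
  keepb <- !duplicated(bkeys)
  raw_trees <- raw_trees[keepb]; bsets <- bsets[keepb]; bkeys <- bkeys[keepb]
  rowkeys <- rowkeys[keepb]

  if (config$collapse == "none") {
    csets <- bsets
  } else {
    csets <- vector("list", length(raw_trees))
    for (t in seq_along(raw_trees)) {
      emR <- orient_edges(raw_trees[[t]])
      zero <- zero_length_edges_cpp(emR, nTip, ed$bm,
                                    m$chars$type == "ordered",
                                    m$chars$n_states)
      rk <- edge_split_keys(emR, nTip, labels)
      csets[[t]] <- unique(rk[!is.na(rk) & !zero])
    }
  }
  ckeys <- vapply(csets, function(k) paste(sort(k), collapse = ";"), "")
  keep <- !duplicated(ckeys)
  mpcs <- lapply(csets[keep], tree_from_splits, labels = sort(labels))
  class(mpcs) <- "multiPhylo"
  trees <- lapply(raw_trees, edges_to_phylo, nTip = nTip, labels = labels)
  class(trees) <- "multiPhylo"
  score <- score_tree(trees[[1]], m,
                      K = if (config$criterion == "implied") config$K else NULL)
  structure(list(mpcs = mpcs, mpc_keys = ckeys[keep],
                 binary_trees = trees, binary_keys = bkeys,
                 consensus_splits = Reduce(intersect, bsets),
                 best_score = score, objective = best,
                 criterion = config$criterion,
                 K = if (config$criterion == "implied") config$K else NA_real_,
                 collapse = config$collapse, log = log),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  crit <- if (x$criterion == "implied")
    paste0("implied weighting (K = ", x$K, ")") else "equal weights"
  cat("Parsimony search under ", crit, ": ", length(x$mpcs),
      " most parsimonious cladogram(s)\n", sep = "")
  print(x$best_score)
  invisible(x)
}

#' Exhaustive search
#'
#' Enumerates all `(2n-5)!!` unrooted binary topologies and returns every
#' optimum. Intended as the exact reference for small problems.
#'
#' @param m a [char_matrix()].
#' @param config a [search_config()].
#' @return a `parsimony_search` object with the set of most parsimonious
#'   cladograms (`$mpcs`, condensed per the collapse rule), the best
#'   [score_tree()] and a search log.
#' @export
exhaustive_search <- function(m, config = search_config(mode = "exhaustive")) {
  if (length(m$taxa) > 10L) stop("exhaustive search limited to 10 taxa")
  if (length(m$taxa) < 3L) stop("need at least 3 taxa")
  ed <- engine_data(m, config)
  res <- exhaustive_cpp(ed$bm, ed$ordered, ed$nstates, ed$weights, ed$minref,
                        ed$K, ed$implied, seq_along(ed$labels),
                        config$max_trees)
  finalize_result(res$trees, res$score, m, config, ed,
                  log = list(mode = "exhaustive",
                             topologies_scored = res$nodes_visited))
}

#' Branch-and-bound search
#'
#' Exact search by stepwise taxon insertion with admissible lower-bound
#' pruning (the partial-tree score; under implied weighting, per-character
#' extra-step bounds relative to the full-matrix minima). The initial upper
#' bound comes from a greedy stepwise-addition tree refined by SPR.
#'
#' @inheritParams exhaustive_search
#' @return a `parsimony_search`.
#' @export
branch_and_bound <- function(m, config = search_config()) {
  if (length(m$taxa) < 3L) stop("need at least 3 taxa")
  ed <- engine_data(m, config)
  ord <- addition_order(m)
  up <- with_seed(config$seed, {
    g <- stepwise_addition_cpp(ed$bm, ed$ordered, ed$nstates, ed$weights,
                               ed$minref, ed$K, ed$implied, ord)
    hill_climb(g$edges, g$score, ed, swap = "spr", collect = FALSE)$score
  })
  res <- branch_and_bound_cpp(ed$bm, ed$ordered, ed$nstates, ed$weights,
                              ed$minref, ed$K, ed$implied, ord,
                              up + 1e-9, config$max_trees,
                              completion_bounds(m, ord))
  finalize_result(res$trees, res$score, m, config, ed,
                  log = list(mode = "branch_and_bound",
                             upper_bound = up, nodes_visited = res$nodes_visited))
}

# SPR (default) or NNI hill climb from an engine edge matrix
hill_climb <- function(edges, score, ed, swap = "spr", collect = FALSE,
                       max_equal = 200L) {
  if (swap == "nni") return(nni_climb(edges, score, ed))
  repeat {
    nb <- spr_neighbors_cpp(edges, ed$bm, ed$ordered, ed$nstates, ed$weights,
                            ed$minref, ed$K, ed$implied,
                            if (collect) max_equal else 1L)
    if (length(nb$trees) && nb$best_score < score - 1e-9) {
      edges <- nb$trees[[1]]
      score <- nb$best_score
    } else break
  }
  equals <- if (collect && length(nb$trees) &&
                nb$best_score <= score + 1e-9) nb$trees else list()
  list(edges = edges, score = score, equal_neighbors = equals)
}

# the two nearest-neighbor interchanges across each internal edge
nni_neighbors <- function(em, nTip) {
  out <- list()
  for (r in seq_len(nrow(em))) {
    u <- em[r, 1]; v <- em[r, 2]
    if (u <= nTip || v <= nTip) next
    nbu <- setdiff(c(em[em[, 1] == u, 2], em[em[, 2] == u, 1]), v)
    nbv <- setdiff(c(em[em[, 1] == v, 2], em[em[, 2] == v, 1]), u)
    for (k in 1:2) {
      em2 <- em
      a <- nbu[2]; b <- nbv[k]            # swap subtrees a and b
      fix <- function(e, from, to1, to2) {
        for (i in seq_len(nrow(e))) {
          if ((e[i, 1] == from && e[i, 2] == to1) ||
              (e[i, 2] == from && e[i, 1] == to1)) e[i, ] <- c(from, to2)
        }
        e
      }
      em2 <- fix(em2, u, a, b)
      em2 <- fix(em2, v, b, a)
      out[[length(out) + 1L]] <- em2
    }
  }
  out
}

nni_climb <- function(edges, score, ed) {
  nTip <- length(ed$labels)
  repeat {
    improved <- FALSE
    for (em in nni_neighbors(edges, nTip)) {
      sc <- score_unrooted_cpp(em, ed$bm, ed$ordered, ed$nstates, ed$weights,
                               ed$minref, ed$K, ed$implied)
      if (sc < score - 1e-9) { edges <- em; score <- sc; improved <- TRUE; break }
    }
    if (!improved) return(list(edges = edges, score = score,
                               equal_neighbors = list()))
  }
}

# TBR refinement in R: bisect every internal edge, try all reconnections
tbr_pass <- function(edges, score, ed) {
  nTip <- length(ed$labels)
  repeat {
    improved <- FALSE
    for (em in tbr_neighbors(edges, nTip)) {
      sc <- score_unrooted_cpp(em, ed$bm, ed$ordered, ed$nstates, ed$weights,
                               ed$minref, ed$K, ed$implied)
      if (sc < score - 1e-9) { edges <- em; score <- sc; improved <- TRUE; break }
    }
    if (!improved) break
  }
  list(edges = edges, score = score)
}

# All TBR reconnections of an unrooted engine edge matrix. A TBR move
# bisects an internal edge (u,v), suppresses the freed degree-2 nodes by
# merging their remaining neighbor pairs, and rejoins the two components by
# subdividing one edge on each side with u and v and adding edge (u,v).
tbr_neighbors <- function(em, nTip) {
  out <- list()
  nNode <- max(em)
  for (r in seq_len(nrow(em))) {
    u <- em[r, 1]; v <- em[r, 2]
    if (u <= nTip || v <= nTip) next          # internal edges only
    # nodes on v's side of the bisected edge
    adj <- vector("list", nNode)
    for (i in seq_len(nrow(em))) {
      if (i == r) next
      adj[[em[i, 1]]] <- c(adj[[em[i, 1]]], em[i, 2])
      adj[[em[i, 2]]] <- c(adj[[em[i, 2]]], em[i, 1])
    }
    seen <- logical(nNode); seen[v] <- TRUE; stack <- v
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
    }
    # merged edge lists per side, with u and v suppressed
    rows <- setdiff(seq_len(nrow(em)), r)
    sideV <- rows[seen[em[rows, 1]]]
    sideU <- setdiff(rows, sideV)
    mk_side <- function(rowsS, node) {
      keep <- rowsS[em[rowsS, 1] != node & em[rowsS, 2] != node]
      nb <- c(em[setdiff(rowsS, keep), 1], em[setdiff(rowsS, keep), 2])
      nb <- nb[nb != node]
      el <- lapply(keep, function(i) em[i, ])
      if (length(nb) == 2L) el[[length(el) + 1L]] <- nb
      el
    }
    elU <- mk_side(sideU, u)
    elV <- mk_side(sideV, v)
    for (iu in seq_along(elU)) for (iv in seq_along(elV)) {
      # skip the pair of merged edges: reattaching there restores the tree
      if (iu == length(elU) && iv == length(elV) &&
          length(adj[[u]]) == 2L && length(adj[[v]]) == 2L) next
      eU <- elU[[iu]]; eV <- elV[[iv]]
      rest <- c(elU[-iu], elV[-iv])
      newem <- do.call(rbind, c(rest, list(
        c(eU[1], u), c(u, eU[2]), c(eV[1], v), c(v, eV[2]), c(u, v))))
      if (nrow(newem) == nrow(em)) out[[length(out) + 1L]] <- newem
    }
  }
  out
}

#' Heuristic search
#'
#' Random-addition stepwise starts followed by branch swapping to a local
#' optimum; all trees at the best score found are pooled, swapped from until
#' closure (so the returned MPC set is stable), condensed and deduplicated.
#'
#' @inheritParams exhaustive_search
#' @return a `parsimony_search`.
#' @export
heuristic_search <- function(m, config = search_config(mode = "heuristic")) {
  if (length(m$taxa) < 3L) stop("need at least 3 taxa")
  if (length(m$taxa) == 3L) {
    ed <- engine_data(m, config)
    em <- cbind(rep(4L, 3), 1:3)
    return(finalize_result(list(em),
                           score_unrooted_cpp(em, ed$bm, ed$ordered, ed$nstates,
                                              ed$weights, ed$minref, ed$K,
                                              ed$implied),
                           m, config, ed, log = list(mode = "heuristic")))
  }
  ed <- engine_data(m, config)
  with_seed(config$seed, {
    best <- Inf; pool <- list()
    for (rep in seq_len(config$n_replicates)) {
      ord <- sample(length(ed$labels))
      g <- stepwise_addition_cpp(ed$bm, ed$ordered, ed$nstates, ed$weights,
                                 ed$minref, ed$K, ed$implied, ord)
      h <- hill_climb(g$edges, g$score, ed,
                      swap = if (config$swap == "nni") "nni" else "spr")
      if (config$swap == "tbr") h <- tbr_pass(h$edges, h$score, ed)
      if (h$score < best - 1e-9) { best <- h$score; pool <- list(h$edges) }
      else if (h$score <= best + 1e-9) pool[[length(pool) + 1L]] <- h$edges
    }
    # closure over equal-score neighbors
    seen <- new.env(parent = emptyenv())
    queue <- pool; pool <- list()
    while (length(queue) && length(pool) < config$max_trees) {
      em <- queue[[1]]; queue <- queue[-1]
      key <- canonical_key(edges_to_phylo(em, length(ed$labels), ed$labels))
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      pool[[length(pool) + 1L]] <- em
      nb <- spr_neighbors_cpp(em, ed$bm, ed$ordered, ed$nstates, ed$weights,
                              ed$minref, ed$K, ed$implied, 200L)
      if (length(nb$trees) && nb$best_score <= best + 1e-9)
        queue <- c(queue, nb$trees)
    }
    finalize_result(pool, best, m, config, ed,
                    log = list(mode = "heuristic",
                               replicates = config$n_replicates,
                               swap = config$swap))
  })
}

# dispatch on config$mode
run_search <- function(m, config) {
  switch(config$mode,
         exhaustive = exhaustive_search(m, config),
         branch_and_bound = branch_and_bound(m, config),
         heuristic = heuristic_search(m, config))
}

#' Concavity-constant sweep for implied weighting
#'
#' Repeats the search over a grid of concavity constants `K` and reports,
#' besides the per-K results, the partition of the grid into maximal
#' intervals over which the MPC set is constant.
#'
#' @param m a [char_matrix()].
#' @param K_grid positive concavity values (default 1..20 plus a coarse
#'   geometric tail to 1405).
#' @param config a [search_config()]; its criterion is forced to implied.
#' @return list with `results` (one `parsimony_search` per K),
#'   `stability` (data.frame: K_from, K_to, n_mpcs) and `K_grid`.
#' @export
k_sweep <- function(m, K_grid = c(1:20, 32, 64, 128, 256, 512, 1024, 1405),
                    config = search_config(criterion = "implied")) {
  if (length(K_grid) == 0L) stop("empty K grid")
  if (any(K_grid <= 0)) stop("concavity values must be positive")
  results <- vector("list", length(K_grid))
  keys <- character(length(K_grid))
  for (i in seq_along(K_grid)) {
    cfg <- config
    cfg$criterion <- "implied"
    cfg$K <- K_grid[i]
    results[[i]] <- run_search(m, cfg)
    keys[i] <- paste(sort(results[[i]]$mpc_keys), collapse = "||")
  }
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  stability <- data.frame(K_from = K_grid[starts], K_to = K_grid[ends],
                          n_mpcs = vapply(results[starts],
                                          function(x) length(x$mpcs), 1L))
  names(results) <- as.character(K_grid)
  list(results = results, stability = stability, K_grid = K_grid)
}
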