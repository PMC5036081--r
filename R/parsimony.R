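#' @useDynLib cladistica, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal helpers ----------------------------------------------------

# named character-coding vector -> bitmask integer vector in `tips` order
states_to_masks <- function(char, tips, n_states) {
  if (is.null(names(char))) names(char) <- tips
  char <- char[tips]
  full <- bitwShiftL(1L, n_states) - 1L
  vapply(char, function(cell) {
    if (is.na(cell)) return(full)
    st <- cell_states(canon_cell(as.character(cell), 0, 0, "tip"))
    if (length(st) == 0L) return(full)
    if (max(st) >= n_states) stop("state ", max(st), " outside alphabet")
    sum(bitwShiftL(1L, st))
  }, integer(1))
}

infer_n_states <- function(char) {
  st <- unlist(lapply(char[!is.na(char)], function(cell)
    cell_states(canon_cell(as.character(cell), 0, 0, "tip"))))
  max(2L, if (length(st)) max(st) + 1L else 2L)
}

# rooted binary edge matrix for a phylo whose only polytomy (if any) is the
# basal trifurcation of an unrooted tree
binarize_root <- function(tree) {
  tab <- tabulate(tree$edge[, 1])
  nTip <- length(tree$tip.label)
  internal <- which(tab > 0)
  root <- internal[!(internal %in% tree$edge[, 2])]
  poly <- internal[tab[internal] > 2]
  if (length(poly) > 1L || (length(poly) == 1L && poly != root))
    stop("tree has polytomies; a binary tree is required here")
  if (length(poly)) tree <- ape::multi2di(tree)
  tree
}

#' Column of a character matrix as a named coding vector
#' @param m a [char_matrix()].
#' @param j character index (1-based).
#' @export
matrix_column <- function(m, j) {
  stopifnot(j >= 1, j <= nrow(m$chars))
  stats::setNames(m$cells[, j], m$taxa)
}

# ---- per-character operations --------------------------------------------

#' Fitch parsimony steps of an unordered character on a tree
#'
#' Minimum number of state changes of a single unordered character, computed
#' with the Fitch pass. Polymorphic tips may take any of their coded states
#' at no cost; missing tips carry the full alphabet. The count is invariant
#' under rerooting.
#'
#' @param tree a binary `phylo` (rooted, or unrooted with a basal
#'   trifurcation).
#' @param char named vector of state codings (names = tip labels); accepts
#'   the same cell syntax as [char_matrix()].
#' @param n_states alphabet size (default: inferred from the data).
#' @return integer step count.
#' @export
fitch_steps <- function(tree, char, n_states = NULL) {
  tree <- binarize_root(tree)
  if (is.null(n_states)) n_states <- infer_n_states(char)
  masks <- states_to_masks(char, tree$tip.label, n_states)
  fitch_steps_cpp(tree$edge, length(tree$tip.label), as.integer(masks))
}

#' Sankoff parsimony steps under an arbitrary step-cost matrix
#'
#' Generalized parsimony via the Sankoff dynamic program; with a unit cost
#' matrix it equals [fitch_steps()], and with linear costs `|i - j|` it
#' scores ordered (additive) characters. Handles multifurcating trees.
#'
#' @inheritParams fitch_steps
#' @param cost square step-cost matrix with zero diagonal; default linear
#'   (ordered) costs.
#' @return minimal total cost (numeric; integral for integer costs).
#' @export
sankoff_steps <- function(tree, char, cost = NULL, n_states = NULL) {
  if (is.null(n_states))
    n_states <- if (!is.null(cost)) nrow(cost) else infer_n_states(char)
  if (is.null(cost)) cost <- abs(outer(0:(n_states - 1), 0:(n_states - 1), "-"))
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be square")
  masks <- states_to_masks(char, tree$tip.label, n_states)
  sankoff_steps_cpp(tree$edge, length(tree$tip.label), as.integer(masks),
                    as.matrix(cost))
}

#' Minimum and maximum conceivable steps of a character
#'
#' `min_steps()` is the smallest number of changes the character can require
#' on any tree: one fewer than the number of states that must be present
#' (unordered), or the narrowest state range compatible with every tip
#' (ordered). `max_steps()` is the number of changes on the star (bush)
#' tree: scored tips minus the largest count achievable by a single state
#' (unordered), or the smallest sum of absolute deviations from a median
#' state (ordered). Polymorphic tips may satisfy either bound with any of
#' their states. An all-missing character returns 0 and is flagged
#' uninformative via `attr(, "uninformative")`.
#'
#' @param char named (or plain) vector of state codings.
#' @param type `"unordered"` (includes binary) or `"ordered"`.
#' @param n_states alphabet size (default inferred).
#' @return integer.
#' @export
min_steps <- function(char, type = c("unordered", "ordered"), n_states = NULL) {
  type <- match.arg(type)
  sets <- lapply(char, function(cell) {
    if (is.na(cell)) return(NULL)
    cell_states(canon_cell(as.character(cell), 0, 0, "tip"))
  })
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0L)
    return(structure(0L, uninformative = TRUE))
  if (type == "ordered") {
    lo <- max(vapply(sets, min, 0))
    hi <- min(vapply(sets, max, 0))
    return(max(0L, as.integer(lo - hi)))
  }
  # unordered: states forced by monomorphic tips, then a greedy set cover of
  # the remaining polymorphic tips
  chosen <- unique(unlist(sets[vapply(sets, length, 1L) == 1L]))
  remaining <- Filter(function(s) !any(s %in% chosen),
                      sets[vapply(sets, length, 1L) > 1L])
  while (length(remaining)) {
    cand <- table(unlist(remaining))
    pick <- as.integer(names(cand)[which.max(cand)])
    chosen <- c(chosen, pick)
    remaining <- Filter(function(s) !(pick %in% s), remaining)
  }
  max(0L, length(chosen) - 1L)
}

#' @rdname min_steps
#' @export
max_steps <- function(char, type = c("unordered", "ordered"), n_states = NULL) {
  type <- match.arg(type)
  sets <- lapply(char, function(cell) {
    if (is.na(cell)) return(NULL)
    cell_states(canon_cell(as.character(cell), 0, 0, "tip"))
  })
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0L)
    return(structure(0L, uninformative = TRUE))
  if (is.null(n_states)) n_states <- max(unlist(sets)) + 1L
  if (type == "ordered") {
    devsum <- vapply(0:(n_states - 1), function(a)
      sum(vapply(sets, function(s) min(abs(s - a)), 0)), 0)
    return(as.integer(min(devsum)))
  }
  hits <- vapply(0:(n_states - 1), function(s)
    sum(vapply(sets, function(x) s %in% x, TRUE)), 0L)
  as.integer(length(sets) - max(hits))
}

#' Per-character parsimony bounds for a whole matrix
#'
#' @param m a [char_matrix()].
#' @return data.frame with `m` (min steps), `g` (max steps) and an
#'   `informative` flag (`g > m`).
#' @export
char_stats <- function(m) {
  type_of <- ifelse(m$chars$type == "ordered", "ordered", "unordered")
  mm <- gg <- integer(nrow(m$chars))
  for (j in seq_len(nrow(m$chars))) {
    col <- m$cells[, j]
    mm[j] <- min_steps(col, type_of[j], m$chars$n_states[j])
    gg[j] <- max_steps(col, type_of[j], m$chars$n_states[j])
  }
  data.frame(index = m$chars$index, m = mm, g = gg, informative = gg > mm)
}

# ---- whole-tree scoring --------------------------------------------------

#' Parsimony score of a tree
#'
#' Scores `tree` against a character matrix: tree length (sum of
#' per-character steps, ordered characters under linear costs), the
#' Goloboff implied-weighting fit when a concavity `K` is supplied,
#' and the ensemble consistency and retention indices.
#'
#' The fit is reported with the conventional negative sign,
#' `fit = -sum(K / (K + es_i))` with `es_i = s_i - m_i` the extra steps of
#' character `i`; a homoplasy-free matrix therefore has `fit = -n_char`.
#' CI is `sum(m)/sum(s)`; RI is `(sum(g) - sum(s))/(sum(g) - sum(m))` with
#' parsimony-uninformative characters (`g == m`) excluded from the RI sums.
#' `ci_informative` additionally excludes uninformative characters from CI.
#'
#' @param tree a `phylo` on exactly the matrix taxa (polytomies allowed).
#' @param m a [char_matrix()].
#' @param K optional positive concavity constant for implied weighting.
#' @return object of class `tree_score`: list with `length`, `fit`, `K`,
#'   `ci`, `ci_informative`, `ri`, and a per-character data.frame `chars`
#'   (`s`, `m`, `g`, `es`, `fit_i`).
#' @export
score_tree <- function(tree, m, K = NULL) {
  validate_char_matrix(m)
  if (!setequal(tree$tip.label, m$taxa))
    stop("tree leaf set does not match matrix taxa")
  if (!is.null(K) && K <= 0) stop("concavity K must be positive")
  bm <- state_bitmasks(m)[tree$tip.label, , drop = FALSE]
  steps <- matrix_steps_cpp(tree$edge, length(tree$tip.label), bm,
                            m$chars$type == "ordered", m$chars$n_states)
  st <- char_stats(m)
  es <- steps - st$m
  fit_i <- if (!is.null(K)) K / (K + es) else rep(NA_real_, length(es))
  info <- st$informative
  sum_s <- sum(steps); sum_m <- sum(st$m); sum_g <- sum(st$g)
  ci <- if (sum_s == 0) 1 else sum_m / sum_s
  ci_inf <- if (sum(steps[info]) == 0) 1 else sum(st$m[info]) / sum(steps[info])
  ri <- if (sum(st$g[info]) == sum(st$m[info])) NA_real_ else
    (sum(st$g[info]) - sum(steps[info])) / (sum(st$g[info]) - sum(st$m[info]))
  structure(list(
    length = sum(steps),
    fit = if (!is.null(K)) -sum(fit_i) else NA_real_,
    K = if (is.null(K)) NA_real_ else K,
    ci = ci, ci_informative = ci_inf, ri = ri,
    chars = data.frame(index = m$chars$index, s = steps, m = st$m, g = st$g,
                       es = es, fit_i = fit_i, informative = info)
  ), class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat("Tree length = ", x$length, sep = "")
  if (!is.na(x$K))
    cat(", Goloboff fit = ", sprintf("%.2f", x$fit), " (K = ", x$K, ")", sep = "")
  cat(", CI = ", sprintf("%.2f", x$ci), ", RI = ", sprintf("%.2f", x$ri),
      "\n", sep = "")
  invisible(x)
}
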