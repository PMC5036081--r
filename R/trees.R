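# Tree plumbing shared by the search, consensus and support modules.
# Internally the search engine uses plain unrooted edge lists (tips
# 1..nTip, internal nodes above); users see ape `phylo` objects.

# unrooted engine edge matrix -> phylo (rooted representation with basal
# trifurcation at the internal node next to tip 1)
edges_to_phylo <- function(em, nTip, labels) {
  adj <- vector("list", max(em))
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  build <- function(v, parent) {
    if (v <= nTip) return(labels[v])
    kids <- setdiff(adj[[v]], parent)
    paste0("(", paste(vapply(kids, build, "", parent = v), collapse = ","), ")")
  }
  root <- adj[[1]][1]
  kids <- adj[[root]]
  txt <- paste0("(", paste(vapply(kids, build, "", parent = root),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

# phylo -> unrooted engine edge matrix (tips renumbered by `labels` order)
phylo_to_edges <- function(tree, labels = tree$tip.label) {
  tree <- ape::unroot(tree)
  nTip <- length(tree$tip.label)
  perm <- match(tree$tip.label, labels)
  if (anyNA(perm)) stop("tree tips not a subset of the given labels")
  map <- integer(max(tree$edge))
  map[seq_len(nTip)] <- perm
  internals <- sort(unique(tree$edge[tree$edge > nTip]))
  map[internals] <- nTip + seq_along(internals)
  cbind(map[tree$edge[, 1]], map[tree$edge[, 2]])
}

# bipartitions of a tree as canonical label keys: the side not containing
# the reference tip (the alphabetically first label), sorted and joined by
# ",". Trivial (pendant) splits are dropped.
bipartitions <- function(tree, ref = NULL) {
  labels <- tree$tip.label
  if (is.null(ref)) ref <- sort(labels)[1]
  pp <- ape::prop.part(tree)
  n <- length(labels)
  keys <- character(0)
  for (part in pp) {
    side <- labels[part]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

# same, straight from an engine edge matrix (cheaper in resampling loops)
edge_bipartitions <- function(em, nTip, labels, ref = NULL) {
  if (is.null(ref)) ref <- sort(labels)[1]
  adj <- vector("list", max(em))
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  keys <- character(0)
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    if (a <= nTip || b <= nTip) next
    # tips on b's side of edge (a,b)
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
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

# order-free identity key for an unrooted (possibly multifurcating) topology
canonical_key <- function(tree) {
  paste(sort(bipartitions(tree)), collapse = ";")
}

# are two canonical bipartition keys (same leaf set, same ref) compatible?
splits_compatible <- function(a, b) {
  A <- strsplit(a, ",", fixed = TRUE)[[1]]
  B <- strsplit(b, ",", fixed = TRUE)[[1]]
  i <- length(intersect(A, B))
  i == 0L || i == length(A) || i == length(B)
}

#' Strict consensus of a set of trees
#'
#' The (possibly multifurcating) tree containing exactly the bipartitions
#' shared by every input tree.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) on identical leaf sets.
#' @return a `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L) stop("no trees given")
  labels <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), labels))
      stop("trees have mismatched leaf sets")
  common <- bipartitions(trees[[1]])
  for (t in trees[-1]) common <- intersect(common, bipartitions(t))
  tree_from_splits(common, labels)
}

# build a phylo from a laminar family of canonical split keys
tree_from_splits <- function(keys, labels) {
  sets <- lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  ord <- order(vapply(sets, length, 1L), decreasing = TRUE)
  sets <- sets[ord]
  build <- function(members, available) {
    # available: indices of sets wholly inside `members`, not yet used
    parts <- list(); used <- character(0); rest <- available
    while (length(rest)) {
      i <- rest[1]; rest <- rest[-1]
      if (length(used) && any(sets[[i]] %in% used)) next
      inner <- rest[vapply(rest, function(j)
        all(sets[[j]] %in% sets[[i]]), TRUE)]
      parts[[length(parts) + 1L]] <- build(sets[[i]], inner)
      used <- c(used, sets[[i]])
      rest <- rest[!vapply(rest, function(j)
        any(sets[[j]] %in% sets[[i]]), TRUE)]
    }
    singles <- setdiff(members, used)
    kids <- c(unlist(parts), singles)
    if (length(kids) == 1L) kids[1]
    else paste0("(", paste(kids, collapse = ","), ")")
  }
  top <- build(labels, seq_along(sets))
  if (!startsWith(top, "(")) top <- paste0("(", top, ")")
  ape::read.tree(text = paste0(top, ";"))
}

# deduplicate a list of phylo by unrooted topology
dedup_trees <- function(trees) {
  keys <- vapply(trees, canonical_key, "")
  trees[!duplicated(keys)]
}

#' Collapse branches of minimum optimized length zero
#'
#' Applies a branch-collapse rule to a binary cladogram: under
#' `"min_length_zero"` (the PAUP `amb-` analogue) an internal branch is
#' collapsed into a polytomy when some most-parsimonious reconstruction of
#' every character places no change on it; `"none"` leaves the tree binary.
#'
#' @param tree a binary `phylo` on the matrix taxa.
#' @param m a [char_matrix()].
#' @param rule `"min_length_zero"` or `"none"`.
#' @return a `phylo`, possibly multifurcating.
#' @export
condense_tree <- function(tree, m, rule = c("min_length_zero", "none")) {
  rule <- match.arg(rule)
  if (rule == "none") return(tree)
  tb <- tree                    # multifurcations are handled by the DP
  bm <- state_bitmasks(m)[tb$tip.label, , drop = FALSE]
  nTip <- length(tb$tip.label)
  zero <- zero_length_edges_cpp(tb$edge, nTip, bm,
                                m$chars$type == "ordered", m$chars$n_states)
  internal <- tb$edge[, 2] > nTip
  tb$edge.length <- ifelse(internal & zero, 0, 1)
  out <- ape::di2multi(tb, tol = 0.5)
  out$edge.length <- NULL
  out
}
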