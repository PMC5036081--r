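#' Morphometric ratio with half-up rounding
#'
#' Ratio of two measurements, rounded half-up to `digits` decimals so that
#' values reproduce the convention of printed comparative tables (e.g.
#' 119/290 -> 0.41).
#'
#' @param numerator,denominator measurements (mm); denominator must be > 0.
#' @param digits decimals (default 2).
#' @export
morph_ratio <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(numerator / denominator, digits)
}

#' Read a measurement table
#'
#' CSV with columns `measurement`, `value_mm`, and optional `flag`
#' (`*` = estimated by doubling a hemi-measurement, `+` = preserved
#' distance, i.e. a minimum). Flags are carried through, not interpreted.
#'
#' @param path CSV path.
#' @return data.frame of class `measurement_table`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("measurement", "value_mm") %in% names(df)))
    stop("expected columns 'measurement' and 'value_mm'")
  if (any(df$value_mm <= 0, na.rm = TRUE)) stop("measurements must be positive")
  if (is.null(df$flag)) df$flag <- ""
  class(df) <- c("measurement_table", "data.frame")
  df
}

measurement_value <- function(tab, name) {
  i <- match(name, tab$measurement)
  if (is.na(i)) stop("measurement not found: ", name)
  tab$value_mm[i]
}

#' Recompute and verify printed ratios
#'
#' Recomputes ratios from a measurement table and compares them with the
#' values printed alongside them; discrepancies are reported, never
#' silently reconciled.
#'
#' @param tab a [read_measurements()] table.
#' @param checks data.frame with columns `numerator`, `denominator`,
#'   `printed` (the published ratio) and optional `digits`.
#' @return data.frame with computed ratios and a `matches` flag.
#' @export
verify_ratios <- function(tab, checks) {
  digits <- if (is.null(checks$digits)) rep(2L, nrow(checks)) else checks$digits
  comp <- vapply(seq_len(nrow(checks)), function(i)
    morph_ratio(measurement_value(tab, checks$numerator[i]),
                measurement_value(tab, checks$denominator[i]), digits[i]), 1)
  data.frame(numerator = checks$numerator, denominator = checks$denominator,
             computed = comp, printed = checks$printed,
             matches = abs(comp - checks$printed) < 1e-9,
             stringsAsFactors = FALSE)
}

# named trait vector aligned to the tree tips, with policy for missing tips
align_trait <- function(tree, trait, discrete = TRUE) {
  if (is.null(names(trait))) stop("trait must be named by taxon")
  miss <- setdiff(tree$tip.label, names(trait))
  vals <- trait[tree$tip.label]
  names(vals) <- tree$tip.label
  if (length(miss))
    warning("tips without trait values: ", paste(miss, collapse = ", "))
  vals
}

#' Fitch ancestral state sets for a discrete trait
#'
#' Most-parsimonious-reconstruction (MPR) state sets for every node of a
#' rooted tree under unordered parsimony: a state belongs to a node's set
#' when some most parsimonious reconstruction assigns it there. Tips
#' lacking a value carry the full alphabet (with a warning). The returned
#' change count equals the Fitch step count of the same column.
#'
#' @param tree a rooted `phylo` (polytomies allowed).
#' @param trait named character/factor vector of states (e.g. areas
#'   `"A"`..`"D"`).
#' @return list with `states` (per-node list of state labels, tips first in
#'   tip order then internal nodes in ape numbering), `changes` (minimum
#'   number of changes), and `alphabet`.
#' @export
map_discrete <- function(tree, trait) {
  trait <- stats::setNames(as.character(trait), names(trait))
  vals <- align_trait(tree, trait)
  alphabet <- sort(unique(vals[!is.na(vals)]))
  ns <- length(alphabet)
  if (ns < 1L) stop("trait has no observed states")
  nTip <- length(tree$tip.label)
  nNode <- max(tree$edge)
  kids <- vector("list", nNode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # postorder
  post <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(v, post)
    stack <- c(stack, kids[[v]])
  }
  INF <- 1e9
  D <- matrix(0, nNode, ns)
  for (v in post) {
    if (v <= nTip) {
      s <- vals[v]
      D[v, ] <- if (is.na(s)) 0 else ifelse(alphabet == s, 0, INF)
    }
    for (ch in kids[[v]]) {
      D[v, ] <- D[v, ] + vapply(seq_len(ns), function(s)
        min(D[ch, ] + as.numeric(seq_len(ns) != s)), 1)
    }
  }
  opt <- min(D[root, ])
  # OUT[v, s]: cost outside subtree(v) given parent(v) has state s
  OUT <- matrix(0, nNode, ns)
  pre <- rev(post)
  for (v in pre) {
    for (ch in kids[[v]]) {
      sib <- setdiff(kids[[v]], ch)
      for (s in seq_len(ns)) {
        tot <- 0
        for (y in sib) tot <- tot + min(D[y, ] + as.numeric(seq_len(ns) != s))
        if (v != root)
          tot <- tot + min(OUT[v, ] + as.numeric(seq_len(ns) != s))
        OUT[ch, s] <- tot
      }
    }
  }
  sets <- vector("list", nNode)
  for (v in seq_len(nNode)) {
    tot <- if (v == root) D[v, ] else {
      vapply(seq_len(ns), function(s)
        D[v, s] + min(OUT[v, ] + as.numeric(seq_len(ns) != s)), 1)
    }
    sets[[v]] <- alphabet[tot <= min(tot) + 1e-9]
  }
  list(states = sets, changes = as.integer(opt), alphabet = alphabet)
}

#' Squared-change parsimony reconstruction of a continuous trait
#'
#' Ancestral values minimizing the sum over edges of squared
#' parent-to-child differences. Internal values solve the induced linear
#' system (each internal node is the mean of its neighbors), so every
#' ancestral value is a convex combination of tip values. Polytomies are
#' allowed; tips without values are pruned with a warning.
#'
#' @param tree a rooted `phylo`.
#' @param trait named numeric vector (e.g. a body-size proxy in mm).
#' @return list with `values` (per-node, tips first), `objective` (the
#'   minimized sum of squared changes) and the pruned `tree`.
#' @export
map_continuous <- function(tree, trait) {
  vals <- align_trait(tree, trait, discrete = FALSE)
  keep <- names(vals)[!is.na(vals)]
  if (length(keep) < 2L) stop("need at least 2 valued tips")
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  vals <- trait[tree$tip.label]
  nTip <- length(tree$tip.label)
  nNode <- max(tree$edge)
  ints <- (nTip + 1):nNode
  A <- matrix(0, length(ints), length(ints))
  b <- numeric(length(ints))
  deg <- tabulate(c(tree$edge[, 1], tree$edge[, 2]), nNode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    pi <- p - nTip
    A[pi, pi] <- A[pi, pi] + 1
    if (ch > nTip) {
      ci <- ch - nTip
      A[ci, ci] <- A[ci, ci] + 1
      A[pi, ci] <- A[pi, ci] - 1
      A[ci, pi] <- A[ci, pi] - 1
    } else {
      b[pi] <- b[pi] + vals[ch]
    }
  }
  x <- solve(A, b)
  values <- c(vals, stats::setNames(x, ints))
  obj <- sum((values[tree$edge[, 1]] - values[tree$edge[, 2]])^2)
  list(values = unname(values), objective = obj, tree = tree,
       tip_values = vals)
}

#' Body-size proxy from postorbital width
#'
#' Applies a user-supplied transform to the postorbital width of the skull
#' to obtain a body-length proxy per taxon. Published regression
#' coefficients relating width to total length are external to this
#' package and must be supplied; the default is the identity (the proxy is
#' the width itself, in mm).
#'
#' @param widths named numeric vector of postorbital widths (mm).
#' @param regression list with elements `a` (intercept) and `b` (slope), or
#'   a function; the proxy is `a + b * width` (default `a = 0, b = 1`).
#' @return named numeric vector usable as a [map_continuous()] trait;
#'   taxa with missing width are dropped with a warning.
#' @export
body_size_proxy <- function(widths, regression = list(a = 0, b = 1)) {
  miss <- names(widths)[is.na(widths)]
  if (length(miss))
    warning("excluded (no postorbital width): ", paste(miss, collapse = ", "))
  w <- widths[!is.na(widths)]
  if (is.function(regression)) return(regression(w))
  regression$a + regression$b * w
}

#' Read a discrete area coding
#'
#' TSV with columns `taxon` and `area`; the package ships an editable
#' mapping for the beaked-whale data set in
#' `inst/extdata/ziphiidae_areas.tsv` (areas A = southeastern Pacific +
#' North Atlantic + Mediterranean, B = southern oceans, C = cosmopolitan,
#' D = antitropical).
#'
#' @param path TSV path.
#' @return named character vector.
#' @export
read_area_coding <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$area, df$taxon)
}
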