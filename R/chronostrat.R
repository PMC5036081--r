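#' Calibration data for stratigraphic tree dating
#'
#' Bundles node age constraints (per named clade) and tip stratigraphic
#' ranges (per species), all in Ma.
#'
#' @param node_constraints data.frame with columns `node` (clade name),
#'   `max_age`, `min_age` (Ma) and `members` (comma-separated taxon list
#'   defining the clade).
#' @param tip_ranges data.frame with columns `taxon`, `oldest`, `youngest`
#'   (Ma; extant taxa have `youngest = 0`) and optional logical
#'   `low_confidence` flagging ranges resolved from broad epoch assignments
#'   (e.g. "Neogene") rather than measured stratigraphy.
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(node_constraints, tip_ranges) {
  stopifnot(all(c("node", "max_age", "min_age", "members") %in%
                names(node_constraints)),
            all(c("taxon", "oldest", "youngest") %in% names(tip_ranges)))
  if (any(node_constraints$max_age < node_constraints$min_age))
    stop("node constraints must have max_age >= min_age")
  if (any(tip_ranges$oldest < tip_ranges$youngest) ||
      any(tip_ranges$youngest < 0))
    stop("tip ranges must have oldest >= youngest >= 0")
  if (is.null(tip_ranges$low_confidence))
    tip_ranges$low_confidence <- FALSE
  structure(list(node_constraints = node_constraints,
                 tip_ranges = tip_ranges),
            class = "calibration_set")
}

#' Read calibration tables
#'
#' `node_path`: TSV mirroring a node-calibration table (columns `node`,
#' `max_age`, `min_age`, `members`). `tip_path`: TSV mirroring a
#' tip-occurrence table (columns `taxon`, `oldest`, `youngest`, optional
#' `low_confidence`).
#'
#' @export
read_calibrations <- function(node_path, tip_path) {
  calibration_set(utils::read.delim(node_path, stringsAsFactors = FALSE),
                  utils::read.delim(tip_path, stringsAsFactors = FALSE))
}

#' Epoch and stage bounds (Ma) used to resolve verbal ages
#'
#' @return data.frame with `interval`, `from`, `to`.
#' @export
epoch_table <- function() {
  data.frame(
    interval = c("Neogene", "Miocene", "early Miocene", "middle Miocene",
                 "late Miocene", "Pliocene", "Tortonian", "Messinian",
                 "Serravallian", "Zanclean", "Unknown"),
    from = c(23.03, 23.03, 23.03, 15.97, 11.63, 5.333, 11.63, 7.246,
             13.82, 5.333, 23.03),
    to = c(2.58, 5.333, 15.97, 11.63, 5.333, 2.58, 7.246, 5.333,
           11.63, 3.6, 2.58),
    stringsAsFactors = FALSE)
}

# resolve a clade name to its MRCA node; error if not monophyletic
resolve_clade <- function(tree, members, name) {
  members <- trimws(strsplit(members, ",")[[1]])
  miss <- setdiff(members, tree$tip.label)
  if (length(miss))
    stop("calibration clade '", name, "': unknown taxa ",
         paste(miss, collapse = ", "))
  if (length(members) == 1L) return(match(members, tree$tip.label))
  node <- ape::getMRCA(tree, members)
  desc <- tree$tip.label[clade_tips(tree, node)]
  if (!setequal(desc, members))
    stop("calibration clade '", name, "' is not monophyletic in the tree ",
         "(MRCA also contains: ",
         paste(setdiff(desc, members), collapse = ", "), ")")
  node
}

clade_tips <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(node)
  kids <- vector("list", max(tree$edge))
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  tips <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= nTip) tips <- c(tips, v) else stack <- c(stack, kids[[v]])
  }
  tips
}

#' Stratigraphically calibrate a cladogram
#'
#' Assigns ages (Ma) to all nodes of a rooted cladogram from fossil tip
#' ranges and node age constraints. Tip ages follow the chosen `policy`:
#' `"range_top"` uses the oldest bound of the stratigraphic range,
#' `"range_mid"` its midpoint. Node ages are propagated rootward: an
#' unconstrained node is `eps` older than its oldest child; a constrained
#' node sits at its constraint age (policy-chosen bound) unless a child is
#' older still, in which case the child age wins and the constraint is
#' reported as dominated. Tips flagged `low_confidence` (broad verbal
#' ranges) do not push their ancestors back in time; they are drawn at
#' their range top but clipped to their parent's age when older.
#'
#' @param tree rooted `phylo` whose tips appear in the calibration set.
#' @param cal a [calibration_set()].
#' @param policy `"range_top"` (default) or `"range_mid"`.
#' @param eps minimum internode (Ma, default 0.1).
#' @return object of class `time_tree`: list with the input `tree`,
#'   `node_age` (named by node id), `tip_age`, `ranges`, and a constraint
#'   `report`.
#' @export
calibrate <- function(tree, cal, policy = c("range_top", "range_mid"),
                      eps = 0.1) {
  policy <- match.arg(policy)
  stopifnot(inherits(cal, "calibration_set"))
  nTip <- length(tree$tip.label)
  tr <- cal$tip_ranges
  idx <- match(tree$tip.label, tr$taxon)
  if (anyNA(idx))
    stop("tips without a stratigraphic range: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  tip_age <- if (policy == "range_top") tr$oldest[idx]
             else (tr$oldest[idx] + tr$youngest[idx]) / 2
  lowconf <- tr$low_confidence[idx]
  names(tip_age) <- tree$tip.label

  nNode <- max(tree$edge)
  con_age <- rep(NA_real_, nNode)
  con_name <- rep(NA_character_, nNode)
  for (i in seq_len(nrow(cal$node_constraints))) {
    nc <- cal$node_constraints[i, ]
    node <- resolve_clade(tree, nc$members, nc$node)
    con_age[node] <- if (policy == "range_top") nc$max_age
                     else (nc$max_age + nc$min_age) / 2
    con_name[node] <- nc$node
  }

  kids <- vector("list", nNode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  post <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(v, post); stack <- c(stack, kids[[v]])
  }

  age <- numeric(nNode)
  binding <- character(0); dominated <- character(0)
  for (v in post) {
    if (v <= nTip) {
      # low-confidence ranges are not allowed to push ancestors back
      age[v] <- if (lowconf[v]) 0 else tip_age[v]
      next
    }
    base <- max(age[kids[[v]]])
    if (!is.na(con_age[v])) {
      if (con_age[v] >= base) {
        age[v] <- con_age[v]
        binding <- c(binding, con_name[v])
      } else {
        age[v] <- base + eps
        dominated <- c(dominated, con_name[v])
      }
    } else {
      age[v] <- base + eps
    }
  }
  # clip low-confidence tip drawing ages under their parents
  parent <- integer(nNode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  draw_age <- tip_age
  clipped <- character(0)
  for (v in seq_len(nTip)) {
    if (lowconf[v] && tip_age[v] > age[parent[v]]) {
      draw_age[v] <- age[parent[v]]
      clipped <- c(clipped, tree$tip.label[v])
    }
    age[v] <- draw_age[v]
  }
  structure(list(tree = tree, node_age = age, tip_age = draw_age,
                 ranges = tr[idx, ],
                 report = list(binding = binding, dominated = dominated,
                               clipped_low_confidence = clipped,
                               policy = policy, eps = eps)),
            class = "time_tree")
}

#' Validate a calibrated time tree
#'
#' Checks that no child is older than its parent, lists binding and
#' dominated constraints, and flags tips whose full stratigraphic range
#' lies entirely above (older than) the parent node's age.
#'
#' @param tt a `time_tree` from [calibrate()].
#' @return list with `n_violations`, `violations` (data.frame), and the
#'   calibration report.
#' @export
validate_timetree <- function(tt) {
  tree <- tt$tree
  age <- tt$node_age
  bad <- list()
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    if (age[ch] > age[p] + 1e-9)
      bad[[length(bad) + 1L]] <- data.frame(parent = p, child = ch,
                                            parent_age = age[p],
                                            child_age = age[ch])
  }
  nTip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  above <- tt$ranges$taxon[tt$ranges$youngest > age[parent[seq_len(nTip)]] + 1e-9]
  list(n_violations = length(bad),
       violations = if (length(bad)) do.call(rbind, bad) else
         data.frame(parent = integer(0), child = integer(0),
                    parent_age = numeric(0), child_age = numeric(0)),
       tips_above_parent = above,
       report = tt$report)
}

#' @export
print.time_tree <- function(x, ...) {
  nTip <- length(x$tree$tip.label)
  root <- setdiff(x$tree$edge[, 1], x$tree$edge[, 2])[1]
  cat("Calibrated tree: ", nTip, " tips, root age ",
      sprintf("%.2f", x$node_age[root]), " Ma (policy ", x$report$policy,
      ")\n", sep = "")
  if (length(x$report$dominated))
    cat("  dominated constraints: ",
        paste(x$report$dominated, collapse = ", "), "\n", sep = "")
  invisible(x)
}
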