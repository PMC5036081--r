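#' Resampling-based GC (group present/contradicted) node support
#'
#' Perturbs the character matrix `replicates` times, re-searches each
#' perturbed matrix with a fast heuristic, and tallies how often each
#' bipartition is recovered. For every bipartition the GC value is the
#' percentage of replicates recovering the group minus the percentage of
#' the most frequent incompatible group.
#'
#' Two perturbation schemes are available. `"symmetric"` (the TNT default
#' used for GC reporting) re-weights each character independently: with
#' probability `p` the character's weight is changed to 0 or 2 with equal
#' chance, otherwise it stays 1. `"bootstrap"` resamples characters with
#' replacement.
#'
#' @param m a [char_matrix()].
#' @param replicates number of resampling replicates.
#' @param scheme `"symmetric"` or `"bootstrap"`.
#' @param p per-character change probability for symmetric resampling.
#' @param seed RNG seed; results are reproducible run-to-run.
#' @param config a [search_config()] giving the criterion (and K) used in
#'   the per-replicate searches.
#' @param starts random-addition starts per replicate (kept small for
#'   tractability at high replicate counts).
#' @return a `support_table`: data.frame with one row per bipartition seen
#'   in any replicate (`split`, the comma-joined smaller side; `freq`,
#'   percent present; `contra`, percent of the best contradicting group;
#'   `gc`).
#' @export
resample_support <- function(m, replicates = 1000, scheme = c("symmetric", "bootstrap"),
                             p = 0.33, seed = 1L,
                             config = search_config(mode = "heuristic"),
                             starts = 1L) {
  scheme <- match.arg(scheme)
  if (replicates < 1) stop("replicates must be >= 1")
  if (replicates < 100)
    warning("fewer than 100 replicates: support percentages will be coarse")
  ed <- engine_data(m, config)
  nTip <- length(ed$labels)
  nChar <- ncol(ed$bm)
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      w <- if (scheme == "symmetric") {
        ifelse(stats::runif(nChar) < p, sample(c(0, 2), nChar, replace = TRUE), 1)
      } else {
        as.numeric(tabulate(sample.int(nChar, nChar, replace = TRUE), nChar))
      }
      best <- Inf; pool <- list()
      for (s in seq_len(starts)) {
        ord <- sample(nTip)
        g <- stepwise_addition_cpp(ed$bm, ed$ordered, ed$nstates, w,
                                   ed$minref, ed$K, ed$implied, ord)
        h <- hill_climb(g$edges, g$score, within_weights(ed, w))
        if (h$score < best - 1e-9) { best <- h$score; pool <- list(h$edges) }
        else if (h$score <= best + 1e-9) pool[[length(pool) + 1L]] <- h$edges
      }
      # strict intersection over the collected equally best trees
      keysets <- lapply(pool, edge_bipartitions, nTip = nTip, labels = ed$labels)
      keys <- Reduce(intersect, keysets)
      for (k in keys) {
        cur <- counts[[k]]
        assign(k, if (is.null(cur)) 1L else cur + 1L, envir = counts)
      }
    }
  })
  splits <- ls(counts)
  freq <- 100 * vapply(splits, function(k) counts[[k]], 1L) / replicates
  contra <- vapply(seq_along(splits), function(i) {
    rivals <- freq[vapply(seq_along(splits), function(j)
      j != i && !splits_compatible(splits[i], splits[j]), TRUE)]
    if (length(rivals)) max(rivals) else 0
  }, 1)
  out <- data.frame(split = splits, freq = unname(freq),
                    contra = contra, gc = unname(freq) - contra,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$gc), ]
  attr(out, "replicates") <- replicates
  attr(out, "scheme") <- scheme
  attr(out, "labels") <- ed$labels
  class(out) <- c("support_table", "data.frame")
  out
}

within_weights <- function(ed, w) { ed$weights <- w; ed }

#' GC values for the internal branches of a tree
#'
#' Looks each bipartition of `tree` up in a [resample_support()] table;
#' groups never seen in any replicate get frequency 0 and a contradiction
#' equal to their strongest rival in the table.
#'
#' @param tree a `phylo`.
#' @param support a `support_table`.
#' @return data.frame (`split`, `freq`, `contra`, `gc`), one row per
#'   internal bipartition of `tree`.
#' @export
gc_for_tree <- function(tree, support) {
  keys <- bipartitions(tree)
  rows <- lapply(keys, function(k) {
    i <- match(k, support$split)
    if (!is.na(i)) return(support[i, c("split", "freq", "contra", "gc")])
    rivals <- support$freq[!vapply(support$split, splits_compatible, TRUE, a = k)]
    contra <- if (length(rivals)) max(rivals) else 0
    data.frame(split = k, freq = 0, contra = contra, gc = -contra,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate a tree with GC node labels
#'
#' @param tree a `phylo`.
#' @param support a `support_table`.
#' @param only_positive drop labels `<= 0` (as in the usual figure style).
#' @return `tree` with `node.label` set to rounded GC values.
#' @export
annotate_gc <- function(tree, support, only_positive = TRUE) {
  labels <- tree$tip.label
  ref <- sort(labels)[1]
  pp <- ape::prop.part(tree)
  nl <- character(length(pp))
  tab <- gc_for_tree(tree, support)
  for (i in seq_along(pp)) {
    side <- labels[pp[[i]]]
    if (ref %in% side) side <- setdiff(labels, side)
    key <- paste(sort(side), collapse = ",")
    j <- match(key, tab$split)
    if (!is.na(j)) {
      g <- round(tab$gc[j])
      nl[i] <- if (!only_positive || g > 0) as.character(g) else ""
    }
  }
  tree$node.label <- nl
  tree
}

#' Select the preferred most-parsimonious cladogram across a K sweep
#'
#' Reproduces the selection procedure used with implied-weighting sweeps:
#' all candidate MPCs are compared on the summed GC value over their
#' internal branches, computed from one shared resampling run (so the sums
#' are comparable); ties are broken by resolution (more internal branches
#' first) and then by the higher Goloboff fit at the candidate's K.
#'
#' @param sweep result of [k_sweep()] (or a named list `K -> parsimony_search`).
#' @param m the [char_matrix()] the sweep was run on.
#' @param support optional precomputed [resample_support()] table; computed
#'   with defaults when missing.
#' @param ... passed to [resample_support()] when `support` is missing.
#' @return list with `K` (chosen concavity), `tree` (chosen MPC), and
#'   `report` (per-candidate summed GC, resolution and fit).
#' @export
select_mpc <- function(sweep, m, support = NULL, ...) {
  results <- if (!is.null(sweep$results)) sweep$results else sweep
  if (length(results) == 0L) stop("empty MPC map")
  if (is.null(support)) support <- resample_support(m, ...)
  rows <- list()
  for (kname in names(results)) {
    res <- results[[kname]]
    K <- suppressWarnings(as.numeric(kname))
    for (i in seq_along(res$mpcs)) {
      tr <- res$mpcs[[i]]
      gtab <- gc_for_tree(tr, support)
      fit <- score_tree(tr, m, K = if (is.finite(K)) K else NULL)$fit
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, mpc = i, summed_gc = sum(gtab$gc),
        resolution = nrow(gtab), fit = fit, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  # better fit = more negative under the reported sign convention
  ord <- order(-report$summed_gc, -report$resolution, report$fit)
  report <- report[ord, ]
  best <- report[1, ]
  list(K = best$K, tree = results[[as.character(best$K)]]$mpcs[[best$mpc]],
       report = report)
}
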