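#' Morphological character matrix
#'
#' Container for a taxa-by-characters morphological matrix as used in
#' cladistic analyses. Each cell is a state set: a single observed state,
#' several states for a polymorphic coding, or missing (`?`; the gap symbol
#' `-` is also treated as missing, following common practice for
#' morphological data). Characters carry a type: `binary`, `ordered`
#' (additive/Wagner, linear step cost `|i - j|`) or `unordered`
#' (non-additive/Fitch, unit step cost).
#'
#' @param cells character matrix (taxa in rows, characters in columns).
#'   Accepted cell codings: `"0"`..`"9"`, `"?"`, `"-"`, and polymorphisms
#'   `"{01}"`, `"(01)"` or `"01"`.
#' @param types character vector of per-character types (`"binary"`,
#'   `"ordered"`, `"unordered"`); defaults to `binary` for characters with
#'   two observed states and `unordered` otherwise.
#' @param n_states optional integer vector of declared alphabet sizes; by
#'   default the number of observed states (at least 2).
#' @param labels optional character descriptions.
#' @param ingroup logical vector flagging ingroup taxa (default all `TRUE`).
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(cells, types = NULL, n_states = NULL, labels = NULL,
                        ingroup = NULL) {
  if (!is.matrix(cells) || !is.character(cells))
    stop("`cells` must be a character matrix")
  taxa <- rownames(cells)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(cells)))
  if (anyDuplicated(taxa)) stop("taxon names must be unique")
  nc <- ncol(cells)

  parsed <- matrix(NA_character_, nrow(cells), nc, dimnames = list(taxa, NULL))
  for (i in seq_len(nrow(cells))) for (j in seq_len(nc)) {
    parsed[i, j] <- canon_cell(cells[i, j], i, j, taxa[i])
  }

  obs_max <- apply(parsed, 2, function(col) {
    st <- unlist(lapply(col[!is.na(col)], function(s) cell_states(s)))
    if (length(st) == 0L) -1L else max(st)
  })
  if (is.null(n_states)) n_states <- pmax(2L, obs_max + 1L)
  n_states <- as.integer(rep_len(n_states, nc))
  if (any(n_states < 2L)) stop("n_states must be >= 2")
  if (any(obs_max + 1L > n_states)) {
    bad <- which(obs_max + 1L > n_states)[1]
    stop("character ", bad, ": coded state ", obs_max[bad],
         " outside declared alphabet of size ", n_states[bad])
  }
  if (any(n_states > 16L)) stop("at most 16 states per character supported")

  if (is.null(types)) {
    types <- ifelse(n_states <= 2L, "binary", "unordered")
  }
  types <- match.arg(rep_len(types, nc), c("binary", "ordered", "unordered"),
                     several.ok = TRUE)
  bad <- types == "binary" & n_states != 2L
  if (any(bad))
    stop("character ", which(bad)[1], ": binary characters must have 2 states")
  demote <- types != "binary" & n_states < 3L
  if (any(demote & types == "ordered"))
    warning(sum(demote & types == "ordered"),
            " ordered character(s) with a 2-state alphabet reclassified as",
            " binary")
  types[demote] <- "binary"   # 2-state unordered == binary, silently

  if (is.null(labels)) labels <- paste0("char", seq_len(nc))
  if (is.null(ingroup)) ingroup <- rep(TRUE, length(taxa))

  m <- structure(list(
    taxa = taxa,
    cells = parsed,
    chars = data.frame(index = seq_len(nc), label = rep_len(labels, nc),
                       type = types, n_states = n_states,
                       stringsAsFactors = FALSE),
    ingroup = stats::setNames(rep_len(ingroup, length(taxa)), taxa)
  ), class = "char_matrix")
  validate_char_matrix(m)
  m
}

# canonical cell string: sorted digits, NA for missing
canon_cell <- function(x, i, j, taxon) {
  x <- gsub("[[:space:]]", "", x)
  if (is.na(x) || x %in% c("?", "-", "")) return(NA_character_)
  x <- gsub("[{}()\\[\\]]", "", x)
  if (!grepl("^[0-9A-F]+$", x))
    stop("invalid coding '", x, "' for taxon '", taxon, "', character ", j)
  st <- sort(unique(strtoi(strsplit(x, "")[[1]], base = 16L)))
  paste(sprintf("%X", st), collapse = "")
}

# integer states of a canonical cell
cell_states <- function(cell) {
  if (is.na(cell)) return(integer(0))
  strtoi(strsplit(cell, "")[[1]], base = 16L)
}

#' @export
validate_char_matrix <- function(m) {
  stopifnot(inherits(m, "char_matrix"))
  if (anyDuplicated(m$taxa)) stop("taxon names must be unique")
  if (ncol(m$cells) != nrow(m$chars))
    stop("cells and character table disagree on the number of characters")
  if (nrow(m$cells) != length(m$taxa)) stop("cells and taxa disagree")
  for (j in seq_len(ncol(m$cells))) {
    ns <- m$chars$n_states[j]
    st <- unlist(lapply(m$cells[, j], cell_states))
    if (length(st) && max(st) >= ns)
      stop("character ", j, ": coded state ", max(st),
           " outside declared alphabet of size ", ns)
  }
  bad <- m$chars$type == "binary" & m$chars$n_states != 2L
  if (any(bad)) stop("binary characters must have exactly 2 states")
  bad <- m$chars$type != "binary" & m$chars$n_states < 3L
  if (any(bad)) stop("ordered/unordered characters must have >= 3 states")
  invisible(m)
}

#' Bitmask encoding of a character matrix
#'
#' Integer matrix with bit `s` set when state `s` is available at the tip;
#' missing cells carry the full alphabet. This is the encoding consumed by
#' the scoring engine.
#' @keywords internal
state_bitmasks <- function(m) {
  nT <- length(m$taxa); nC <- nrow(m$chars)
  out <- matrix(0L, nT, nC, dimnames = list(m$taxa, NULL))
  full <- bitwShiftL(1L, m$chars$n_states) - 1L
  for (j in seq_len(nC)) {
    col <- m$cells[, j]
    for (i in seq_len(nT)) {
      if (is.na(col[i])) out[i, j] <- full[j]
      else out[i, j] <- sum(bitwShiftL(1L, cell_states(col[i])))
    }
  }
  out
}

#' Summary counts for a character matrix
#'
#' @param m a [char_matrix()].
#' @return list with taxon and character counts by type, ingroup/outgroup
#'   counts, and the fractions of missing and polymorphic cells.
#' @export
summarize_matrix <- function(m) {
  validate_char_matrix(m)
  tab <- table(factor(m$chars$type, c("binary", "ordered", "unordered")))
  poly <- mean(!is.na(m$cells) & nchar(m$cells) > 1L)
  list(
    n_taxa = length(m$taxa),
    n_char = nrow(m$chars),
    binary = unname(tab["binary"]),
    ordered = unname(tab["ordered"]),
    unordered = unname(tab["unordered"]),
    ingroup = sum(m$ingroup),
    outgroup = sum(!m$ingroup),
    missing_fraction = mean(is.na(m$cells)),
    polymorphic_fraction = poly
  )
}

#' @export
print.char_matrix <- function(x, ...) {
  s <- summarize_matrix(x)
  cat("Morphological character matrix: ", s$n_taxa, " taxa x ", s$n_char,
      " characters\n", sep = "")
  cat("  types: ", s$binary, " binary, ", s$ordered, " ordered, ",
      s$unordered, " unordered\n", sep = "")
  cat("  ingroup ", s$ingroup, " / outgroup ", s$outgroup,
      "; missing ", sprintf("%.1f%%", 100 * s$missing_fraction),
      "; polymorphic ", sprintf("%.1f%%", 100 * s$polymorphic_fraction),
      "\n", sep = "")
  invisible(x)
}

#' Drop taxa from a character matrix
#' @keywords internal
subset_taxa <- function(m, keep) {
  idx <- match(keep, m$taxa)
  if (anyNA(idx)) stop("unknown taxa: ", paste(keep[is.na(idx)], collapse = ", "))
  m$taxa <- m$taxa[idx]
  m$cells <- m$cells[idx, , drop = FALSE]
  m$ingroup <- m$ingroup[idx]
  m
}
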