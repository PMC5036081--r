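#' Read a morphological character matrix
#'
#' Reads NEXUS (`DATA`/`CHARACTERS` block, with an optional `ASSUMPTIONS`
#' `TYPESET` giving ordered/unordered assignments) or TNT (`xread` plus an
#' optional `ccode` block) files. Polymorphic codings may use `{..}`, `(..)`
#' or `[..]`; `?` and `-` are both read as missing data.
#'
#' @param path file path.
#' @param dialect `"auto"` (default, sniffed from the first line), `"nexus"`
#'   or `"tnt"`.
#' @return a [char_matrix()].
#' @export
read_matrix <- function(path, dialect = c("auto", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    first <- toupper(trimws(lines[nzchar(trimws(lines))][1]))
    dialect <- if (startsWith(first, "#NEXUS")) "nexus" else "tnt"
  }
  if (dialect == "nexus") read_nexus_matrix(lines) else read_tnt_matrix(lines)
}

# ---- NEXUS ---------------------------------------------------------------

read_nexus_matrix <- function(lines) {
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\s*$", up)
  if (length(mstart) == 0L)
    stop("NEXUS parse error: no MATRIX statement found")
  mstart <- mstart[1]
  dims <- grep("DIMENSIONS", up, value = TRUE)
  ntax <- nchar_decl <- NA_integer_
  if (length(dims)) {
    ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", toupper(dims[1])))
    nchar_decl <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", toupper(dims[1])))
  }
  rows <- list(); taxa <- character(0)
  i <- mstart + 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == ";" || grepl(";\\s*$", ln)) {
      ln <- sub(";\\s*$", "", ln)
      if (nzchar(trimws(ln))) {
        p <- parse_matrix_row(ln, i)
        taxa <- c(taxa, p$taxon); rows[[length(rows) + 1L]] <- p$states
      }
      break
    }
    if (nzchar(ln) && !startsWith(ln, "[")) {
      p <- parse_matrix_row(ln, i)
      taxa <- c(taxa, p$taxon); rows[[length(rows) + 1L]] <- p$states
    }
    i <- i + 1
  }
  if (length(rows) == 0L) stop("NEXUS parse error: empty MATRIX block")
  ncols <- vapply(rows, length, 1L)
  if (length(unique(ncols)) != 1L)
    stop("NEXUS parse error: rows differ in character count (line ",
         mstart + which(ncols != ncols[1])[1], ")")
  if (!is.na(nchar_decl) && ncols[1] != nchar_decl)
    stop("NEXUS parse error: NCHAR=", nchar_decl, " but rows have ",
         ncols[1], " characters")
  if (!is.na(ntax) && length(rows) != ntax)
    stop("NEXUS parse error: NTAX=", ntax, " but found ", length(rows), " taxa")
  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa

  types <- parse_nexus_typeset(lines, ncols[1])
  ig <- parse_flag_set(lines, "INGROUP", taxa)
  ns <- parse_nstates(lines, ncols[1])
  char_matrix(cells, types = types, n_states = ns, ingroup = ig)
}

# optional bracketed comment "[NSTATES: 2 3 3 ...]" preserving declared
# alphabet sizes across a write/read round trip
parse_nstates <- function(lines, nchar) {
  ln <- grep("\\[NSTATES:", toupper(lines))
  if (!length(ln)) return(NULL)
  body <- sub(".*:", "", sub("\\].*", "", lines[ln[1]]))
  ns <- as.integer(strsplit(trimws(body), "\\s+")[[1]])
  if (length(ns) != nchar) return(NULL)
  ns
}

parse_matrix_row <- function(ln, lineno) {
  mm <- regmatches(ln, regexec("^(\\S+|'[^']+')\\s+(.+)$", ln))[[1]]
  if (length(mm) != 3L)
    stop("parse error at line ", lineno, ": expected 'taxon states'")
  taxon <- gsub("^'|'$", "", mm[2])
  states <- tokenize_states(gsub("\\s", "", mm[3]), lineno)
  list(taxon = taxon, states = states)
}

# split a state string into per-character tokens, honouring {..} (..) [..]
tokenize_states <- function(s, lineno) {
  out <- character(0); i <- 1; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("{", "(", "[")) {
      close <- c("{" = "}", "(" = ")", "[" = "]")[ch]
      j <- i + 1
      while (j <= n && substr(s, j, j) != close) j <- j + 1
      if (j > n) stop("parse error at line ", lineno, ": unbalanced '", ch, "'")
      out <- c(out, substr(s, i + 1, j - 1))
      i <- j + 1
    } else if (grepl("[0-9A-Fa-f?\\-]", ch)) {
      out <- c(out, ch)
      i <- i + 1
    } else {
      stop("parse error at line ", lineno, ": state symbol '", ch,
           "' outside declared alphabet")
    }
  }
  out
}

parse_nexus_typeset <- function(lines, nchar) {
  up <- toupper(lines)
  ts <- grep("TYPESET", up)
  types <- rep("unordered", nchar)
  explicit <- rep(FALSE, nchar)
  if (length(ts)) {
    # gather the full statement (may span lines, ends with ;)
    stmt <- lines[ts[1]]
    k <- ts[1]
    while (!grepl(";", stmt) && k < length(lines)) { k <- k + 1; stmt <- paste(stmt, lines[k]) }
    stmt <- sub(".*=", "", sub(";.*", "", stmt))
    for (part in strsplit(stmt, ",")[[1]]) {
      mm <- regmatches(part, regexec("^\\s*(ord|unord)\\s*:\\s*(.+)$",
                                     tolower(part)))[[1]]
      if (length(mm) != 3L) next
      idx <- parse_index_list(mm[3], nchar)
      types[idx] <- if (mm[2] == "ord") "ordered" else "unordered"
      explicit[idx] <- TRUE
    }
  }
  attr(types, "explicit") <- explicit
  types
}

# "1 3 5-7" -> integer indices (1-based)
parse_index_list <- function(s, nmax) {
  out <- integer(0)
  for (tok in strsplit(trimws(s), "\\s+")[[1]]) {
    if (grepl("^[0-9]+-[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    }
  }
  out[out >= 1 & out <= nmax]
}

# optional bracketed comment "[INGROUP: t1 t2 ...]"
parse_flag_set <- function(lines, key, taxa) {
  ln <- grep(paste0("\\[", key, ":"), toupper(lines))
  if (!length(ln)) return(NULL)
  body <- sub(".*:", "", sub("\\].*", "", lines[ln[1]]))
  members <- strsplit(trimws(body), "\\s+")[[1]]
  taxa %in% members
}

# ---- TNT -----------------------------------------------------------------

read_tnt_matrix <- function(lines) {
  up <- toupper(trimws(lines))
  xr <- grep("^XREAD", up)
  if (!length(xr)) stop("TNT parse error: no xread statement")
  i <- xr[1] + 1
  # optional quoted title and bracketed comment lines
  repeat {
    ln <- trimws(lines[i])
    if (i <= length(lines) && startsWith(ln, "[")) { i <- i + 1; next }
    if (i <= length(lines) && grepl("^'", ln)) {
      while (i <= length(lines) && !grepl("'\\s*$", sub("^'", "", trimws(lines[i]))))
        i <- i + 1
      i <- i + 1
      next
    }
    break
  }
  dims <- strsplit(trimws(lines[i]), "\\s+")[[1]]
  if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop("TNT parse error at line ", i, ": expected 'nchar ntax'")
  nchar_decl <- as.integer(dims[1]); ntax <- as.integer(dims[2])
  i <- i + 1
  rows <- list(); taxa <- character(0)
  while (i <= length(lines) && length(rows) < ntax) {
    ln <- trimws(sub(";\\s*$", "", lines[i]))
    if (nzchar(ln) && !startsWith(ln, "[")) {
      p <- parse_matrix_row(ln, i)
      taxa <- c(taxa, p$taxon); rows[[length(rows) + 1L]] <- p$states
    }
    i <- i + 1
  }
  if (length(rows) != ntax)
    stop("TNT parse error: expected ", ntax, " taxa, found ", length(rows))
  ncols <- vapply(rows, length, 1L)
  if (any(ncols != nchar_decl))
    stop("TNT parse error: row with ", ncols[ncols != nchar_decl][1],
         " characters, declared ", nchar_decl)
  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa

  types <- rep("unordered", nchar_decl)
  cc <- grep("^CCODE", up)
  if (length(cc)) {
    stmt <- lines[cc[1]]
    k <- cc[1]
    while (!grepl(";", stmt) && k < length(lines)) { k <- k + 1; stmt <- paste(stmt, lines[k]) }
    stmt <- sub(";.*", "", sub("(?i)ccode", "", stmt, perl = TRUE))
    mode <- NULL
    for (tok in strsplit(trimws(stmt), "\\s+")[[1]]) {
      if (tok == "+") { mode <- "ordered"; next }
      if (tok == "-") { mode <- "unordered"; next }
      if (is.null(mode)) next
      if (grepl("^[0-9]+\\.[0-9]+$", tok)) {         # TNT range a.b
        ab <- as.integer(strsplit(tok, "\\.")[[1]])
        idx <- seq(ab[1], ab[2]) + 1L                # ccode is 0-based
      } else if (grepl("^[0-9]+$", tok)) {
        idx <- as.integer(tok) + 1L
      } else next
      idx <- idx[idx >= 1 & idx <= nchar_decl]
      types[idx] <- mode
    }
  }
  ig <- parse_flag_set(lines, "INGROUP", taxa)
  ns <- parse_nstates(lines, nchar_decl)
  char_matrix(cells, types = types, n_states = ns, ingroup = ig)
}

# ---- writing -------------------------------------------------------------

#' Write a character matrix
#'
#' @param m a [char_matrix()].
#' @param path output file.
#' @param dialect `"nexus"` or `"tnt"`.
#' @export
write_matrix <- function(m, path, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  validate_char_matrix(m)
  fmt_cell <- function(cell, tnt) {
    if (is.na(cell)) return("?")
    if (nchar(cell) == 1L) return(cell)
    if (tnt) paste0("[", cell, "]") else paste0("{", cell, "}")
  }
  nm_w <- max(nchar(m$taxa)) + 2L
  row_str <- function(i, tnt) {
    paste0(formatC(m$taxa[i], width = -nm_w),
           paste(vapply(m$cells[i, ], fmt_cell, "", tnt = tnt), collapse = ""))
  }
  ig_line <- if (!all(m$ingroup))
    paste0("[INGROUP: ", paste(m$taxa[m$ingroup], collapse = " "), "]")
  ns_line <- paste0("[NSTATES: ", paste(m$chars$n_states, collapse = " "), "]")
  if (dialect == "nexus") {
    ord <- which(m$chars$type == "ordered")
    unord <- which(m$chars$type != "ordered")
    out <- c(
      "#NEXUS",
      ns_line,
      if (!is.null(ig_line)) ig_line,
      "BEGIN DATA;",
      paste0("DIMENSIONS NTAX=", length(m$taxa), " NCHAR=", nrow(m$chars), ";"),
      "FORMAT DATATYPE=STANDARD GAP=- MISSING=? SYMBOLS=\"0123456789ABCDEF\";",
      "MATRIX",
      vapply(seq_along(m$taxa), row_str, "", tnt = FALSE),
      ";",
      "END;",
      "BEGIN ASSUMPTIONS;",
      paste0("TYPESET * default = ",
             paste(c(if (length(ord)) paste("ord:", paste(ord, collapse = " ")),
                     if (length(unord)) paste("unord:", paste(unord, collapse = " "))),
                   collapse = ", "),
             ";"),
      "END;")
  } else {
    ord <- which(m$chars$type == "ordered") - 1L
    unord <- which(m$chars$type != "ordered") - 1L
    out <- c(
      "xread",
      ns_line,
      if (!is.null(ig_line)) ig_line,
      paste(nrow(m$chars), length(m$taxa)),
      vapply(seq_along(m$taxa), row_str, "", tnt = TRUE),
      ";",
      paste0("ccode ",
             if (length(ord)) paste("+", paste(ord, collapse = " ")) else "",
             if (length(unord)) paste(" -", paste(unord, collapse = " ")) else "",
             ";"),
      "proc /;")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- trees ---------------------------------------------------------------

#' Read / write trees
#'
#' Thin wrappers over ape's Newick and NEXUS tree IO returning a
#' `multiPhylo` list. Node annotations (e.g. GC support) written by
#' [write_trees()] as node labels survive a round trip.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"newick"` or `"nexus"`.
#' @return a `multiPhylo`.
#' @export
read_trees <- function(path, dialect = c("auto", "newick", "nexus")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- toupper(trimws(readLines(path, n = 1, warn = FALSE)))
    dialect <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tr <- if (dialect == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- c(tr)
  class(tr) <- "multiPhylo"
  tr
}

#' @param trees a `phylo` or `multiPhylo`.
#' @rdname read_trees
#' @export
write_trees <- function(trees, path, dialect = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (dialect == "nexus") ape::write.nexus(trees, file = path)
  else ape::write.tree(trees, file = path)
  invisible(path)
}
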