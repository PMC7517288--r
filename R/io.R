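#' Read and write hypergraphs as plain text
#'
#' The interchange format is one hyperedge per line: whitespace-separated
#' **0-based** integer vertex ids, with `#` starting a comment and blank lines
#' ignored. An ordinary two-column edge list is the special case in which every
#' line has exactly two ids. In-memory objects use 1-based ids (the usual R
#' convention); the shift happens transparently on read/write, and
#' `read(write(H))` returns `H` up to hyperedge order.
#'
#' On read, the hyperedge family is re-validated: repeated ids within a line,
#' non-integer tokens and subset violations (non-simple families) are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param n_vertices optional vertex count; defaults to `max id + 1` so that
#'   trailing isolated vertices must be declared explicitly.
#' @param require_simple error if the family is not simple (default `TRUE`).
#' @return `read_hypergraph()` returns a [hypergraph()]; `write_hypergraph()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".hyp")
#' write_hypergraph(hypergraph(list(c(1, 2, 3), c(3, 4))), f)
#' read_hypergraph(f)
#' @export
read_hypergraph <- function(path, n_vertices = NULL, require_simple = TRUE) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  edges <- list()
  line_of <- integer(0)
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) next
    if (!all(grepl("^[0-9]+$", toks))) {
      stop(sprintf("line %d: non-integer vertex id token", ln), call. = FALSE)
    }
    ids <- as.integer(toks)
    if (length(ids) < 2) {
      stop(sprintf("line %d: hyperedge has fewer than 2 vertices", ln),
           call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop(sprintf("line %d: repeated vertex id within hyperedge", ln),
           call. = FALSE)
    }
    edges[[length(edges) + 1L]] <- ids + 1L  # 0-based file -> 1-based memory
    line_of[length(edges)] <- ln
  }
  if (is.null(n_vertices)) {
    n_vertices <- if (length(edges) > 0) max(unlist(edges)) else 0L
  }
  H <- hypergraph(edges, n_vertices = n_vertices)
  if (require_simple) {
    v <- validate_simple(H)
    if (!v$ok) {
      bad <- v$violations
      stop(sprintf(
        "hypergraph is not simple: line %d is contained in line %d%s",
        line_of[bad$inner[1]], line_of[bad$outer[1]],
        if (nrow(bad) > 1) sprintf(" (and %d more violations)", nrow(bad) - 1) else ""
      ), call. = FALSE)
    }
  }
  H
}

#' @rdname read_hypergraph
#' @param H a [hypergraph()] to write.
#' @export
write_hypergraph <- function(H, path) {
  stopifnot(is_hypergraph(H))
  lines <- vapply(H$edges, function(e) paste(e - 1L, collapse = " "),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a graph as a two-column edge list (0-based, plain text)
#'
#' Thin wrappers over the hypergraph format restricted to cardinality-2 lines.
#'
#' @param path file path.
#' @param n_vertices optional vertex count (default `max id + 1`).
#' @return `read_edgelist()` returns an [igraph::graph];
#'   `write_edgelist()` returns `path` invisibly.
#' @export
read_edgelist <- function(path, n_vertices = NULL) {
  H <- read_hypergraph(path, n_vertices = n_vertices, require_simple = TRUE)
  if (length(H$edges) > 0 && any(hyperedge_sizes(H) != 2)) {
    stop("edge-list file contains lines with more than two vertex ids",
         call. = FALSE)
  }
  two_section(H)
}

#' @rdname read_edgelist
#' @param g an [igraph::graph] (undirected, simple).
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE)
  writeLines(apply(el - 1L, 1, paste, collapse = " "), path)
  invisible(path)
}
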