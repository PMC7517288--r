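#' Construct a hypergraph
#'
#' A hypergraph is a vertex set `1..n_vertices` together with a family of
#' hyperedges, each a set of at least two distinct vertices. Group interactions
#' of any size can be represented; the generators in this package produce
#' rank-3 hypergraphs (hyperedges of cardinality 2 and 3).
#'
#' Hyperedges are stored canonically as sorted integer vectors, so equality and
#' subset tests are order-independent. Vertex ids are 1-based in memory; the
#' plain-text interchange format used by [read_hypergraph()] /
#' [write_hypergraph()] is 0-based.
#'
#' @param hyperedges list of integer vectors, each of length >= 2, with
#'   distinct entries in `1..n_vertices`.
#' @param n_vertices number of vertices. Defaults to the largest id mentioned.
#' @param check validate hyperedge well-formedness (default `TRUE`).
#' @return an object of class `hypergraph` with fields `n` and `edges`.
#' @examples
#' H <- hypergraph(list(c(1, 2, 3), c(3, 4)))
#' H
#' @export
hypergraph <- function(hyperedges, n_vertices = NULL, check = TRUE) {
  edges <- lapply(hyperedges, function(e) sort(as.integer(e)))
  if (is.null(n_vertices)) {
    n_vertices <- if (length(edges) > 0) max(unlist(edges)) else 0L
  }
  n_vertices <- as.integer(n_vertices)
  if (check) {
    if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 0L) {
      stop("`n_vertices` must be a single non-negative integer", call. = FALSE)
    }
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      if (length(e) < 2L) {
        stop(sprintf("hyperedge %d has cardinality %d (< 2)", i, length(e)),
             call. = FALSE)
      }
      if (anyDuplicated(e)) {
        stop(sprintf("hyperedge %d contains repeated vertex ids", i),
             call. = FALSE)
      }
      if (anyNA(e) || e[1] < 1L || e[length(e)] > n_vertices) {
        stop(sprintf("hyperedge %d has vertex ids outside 1..%d", i, n_vertices),
             call. = FALSE)
      }
    }
  }
  structure(list(n = n_vertices, edges = edges), class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  card <- hyperedge_sizes(x)
  cat(sprintf("<hypergraph> %d vertices, %d hyperedges", x$n, length(x$edges)))
  if (length(card) > 0) {
    tab <- table(card)
    cat(" (", paste(sprintf("%s of size %s", tab, names(tab)), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
format.hypergraph <- function(x, ...) {
  sprintf("<hypergraph: %d vertices, %d hyperedges>", x$n, length(x$edges))
}

#' @rdname hypergraph
#' @param x object to test or print.
#' @export
is_hypergraph <- function(x) inherits(x, "hypergraph")

#' Hyperedge cardinalities, rank and co-rank
#'
#' `hyperedge_sizes()` returns the cardinality of every hyperedge;
#' `hypergraph_rank()` and `hypergraph_corank()` the maximum and minimum
#' cardinality present. An `s`-uniform hypergraph has rank = co-rank = s.
#'
#' @param H a [hypergraph()].
#' @return integer vector / single integer.
#' @export
hyperedge_sizes <- function(H) {
  stopifnot(is_hypergraph(H))
  lengths(H$edges)
}

#' @rdname hyperedge_sizes
#' @export
hypergraph_rank <- function(H) {
  s <- hyperedge_sizes(H)
  if (length(s) == 0) return(NA_integer_)
  max(s)
}

#' @rdname hyperedge_sizes
#' @export
hypergraph_corank <- function(H) {
  s <- hyperedge_sizes(H)
  if (length(s) == 0) return(NA_integer_)
  min(s)
}

# canonical string keys for hyperedges, used for set comparisons
edge_keys <- function(edges) {
  vapply(edges, function(e) paste(e, collapse = " "), character(1))
}

#' Check simplicity of a hypergraph
#'
#' A hypergraph is *simple* when no hyperedge is a subset of (or equal to)
#' another. Simplicity is what makes the m-degrees and the promotion algorithm
#' well defined: a pair interaction nested inside a group interaction would be
#' counted twice.
#'
#' Subset checks are only needed between cardinality classes (plus exact
#' duplicates within a class), so the scan compares smaller against larger
#' hyperedges per class pair.
#'
#' @param H a [hypergraph()].
#' @return a list with `ok` (logical) and `violations`, a tibble with columns
#'   `inner`, `outer` (indices into `H$edges`) listing each containment
#'   `edges[[inner]] <= edges[[outer]]` found.
#' @examples
#' validate_simple(hypergraph(list(c(1, 2), c(1, 2, 3))))$ok
#' @export
validate_simple <- function(H) {
  stopifnot(is_hypergraph(H))
  edges <- H$edges
  sizes <- lengths(edges)
  inner <- integer(0)
  outer <- integer(0)
  keys <- edge_keys(edges)
  # duplicates (equal hyperedges)
  dup <- which(duplicated(keys))
  for (j in dup) {
    i <- which(keys == keys[j])[1]
    inner <- c(inner, j); outer <- c(outer, i)
  }
  # strict containments: compare every smaller size class against larger ones
  usz <- sort(unique(sizes))
  if (length(usz) > 1) {
    for (si in usz[-length(usz)]) {
      small_idx <- which(sizes == si)
      big_idx <- which(sizes > si)
      for (i in small_idx) {
        e <- edges[[i]]
        for (j in big_idx) {
          if (all(e %in% edges[[j]])) {
            inner <- c(inner, i); outer <- c(outer, j)
          }
        }
      }
    }
  }
  list(ok = length(inner) == 0,
       violations = tibble::tibble(inner = inner, outer = outer))
}

#' Reduce a hypergraph to a simple hypergraph
#'
#' Removes every hyperedge that is a subset of (or equal to) another one;
#' the surviving family is simple and the operation is idempotent.
#'
#' @param H a [hypergraph()].
#' @return a simple [hypergraph()] on the same vertex set.
#' @examples
#' simplify_hypergraph(hypergraph(list(c(1, 2), c(1, 2, 3))))
#' @export
simplify_hypergraph <- function(H) {
  stopifnot(is_hypergraph(H))
  edges <- H$edges
  keys <- edge_keys(edges)
  keep <- !duplicated(keys)
  edges <- edges[keep]
  sizes <- lengths(edges)
  drop <- rep(FALSE, length(edges))
  usz <- sort(unique(sizes))
  if (length(usz) > 1) {
    for (si in usz[-length(usz)]) {
      small_idx <- which(sizes == si)
      big_idx <- which(sizes > si)
      big_edges <- edges[big_idx]
      for (i in small_idx) {
        e <- edges[[i]]
        for (be in big_edges) {
          if (all(e %in% be)) { drop[i] <- TRUE; break }
        }
      }
    }
  }
  hypergraph(edges[!drop], n_vertices = H$n, check = FALSE)
}

#' 2-section (graph projection) of a hypergraph
#'
#' Two distinct vertices are adjacent in the 2-section iff they belong to at
#' least one common hyperedge. The strategy-update step of the game dynamics
#' operates on this projection.
#'
#' @param H a [hypergraph()].
#' @return an [igraph::graph] on the same vertex set (no multi-edges).
#' @export
two_section <- function(H) {
  stopifnot(is_hypergraph(H))
  pair_list <- lapply(H$edges, function(e) {
    if (length(e) == 2) return(matrix(e, ncol = 2))
    t(utils::combn(e, 2))
  })
  pairs <- do.call(rbind, c(pair_list, list(matrix(integer(0), ncol = 2))))
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)  # rows already sorted (hyperedges are sorted)
  }
  g <- igraph::make_empty_graph(H$n, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  igraph::simplify(g)
}

#' Per-vertex m-degrees and generalized degree
#'
#' The m-degree `k_m(i)` counts the hyperedges of cardinality m incident on
#' vertex i; the generalized degree `k(i)` is the sum over m. The column sums
#' satisfy `sum_i k_m(i) = m * (# hyperedges of cardinality m)`.
#'
#' @param H a [hypergraph()].
#' @return a tibble with one row per vertex: `vertex`, one `k{m}` column per
#'   cardinality present in `H`, and the generalized degree `k`.
#' @examples
#' m_degrees(hypergraph(list(c(1, 2), c(1, 3, 4))))
#' @export
m_degrees <- function(H) {
  stopifnot(is_hypergraph(H))
  sizes <- hyperedge_sizes(H)
  usz <- sort(unique(sizes))
  out <- tibble::tibble(vertex = seq_len(H$n))
  total <- integer(H$n)
  for (m in usz) {
    km <- integer(H$n)
    idx <- unlist(H$edges[sizes == m], use.names = FALSE)
    if (length(idx) > 0) {
      tab <- tabulate(idx, nbins = H$n)
      km <- tab
    }
    out[[paste0("k", m)]] <- km
    total <- total + km
  }
  out$k <- total
  out
}

#' Fractions of hyperedges per cardinality
#'
#' Returns `p_m`, the fraction of hyperedges of cardinality m, which weights
#' the well-mixed critical synergy `alpha_cr = sum_m m * p_m`.
#'
#' @param H a [hypergraph()] with at least one hyperedge.
#' @return tibble with columns `m`, `count`, `p`.
#' @export
cardinality_fractions <- function(H) {
  stopifnot(is_hypergraph(H))
  sizes <- hyperedge_sizes(H)
  if (length(sizes) == 0) {
    stop("hypergraph has no hyperedges; cardinality fractions undefined",
         call. = FALSE)
  }
  tab <- table(sizes)
  tibble::tibble(
    m = as.integer(names(tab)),
    count = as.integer(tab),
    p = as.integer(tab) / length(sizes)
  )
}

#' Local (Watts-Strogatz) clustering coefficient
#'
#' Number of edges among a vertex's neighbours divided by `k(k-1)/2`.
#' Vertices of degree < 2 get clustering 0 by convention (not NaN), which keeps
#' the rewiring acceptance checks total.
#'
#' @param g an [igraph::graph].
#' @param v vertices (default all).
#' @return numeric vector in `[0, 1]`.
#' @export
local_clustering <- function(g, v = igraph::V(g)) {
  cc <- igraph::transitivity(g, type = "local", vids = v, isolates = "zero")
  cc[is.na(cc)] <- 0
  cc
}
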