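#' Holme-Kim scale-free network with tunable clustering
#'
#' Growing network combining preferential attachment (PA) with triad
#' formation. The graph is seeded with a clique on `m + 1` vertices; every
#' arriving vertex places `m` links: the first by PA (target drawn with
#' probability proportional to degree among vertices it is not yet linked to),
#' and each of the remaining `m - 1` links, with probability `p_t`, by a
#' triad-formation step (a uniformly random not-yet-connected neighbour of the
#' previous PA target, closing a triangle) and otherwise by a fresh PA step.
#' When no eligible neighbour exists the step falls back to PA.
#'
#' With `p_t = 1` transitivity is maximal: every edge belongs to at least one
#' 3-clique, so promoting all 3-cliques yields a 3-uniform hypergraph. The mean
#' degree approaches `2 m` (about 6 for `m = 3`).
#'
#' @param n number of vertices (> m + 1).
#' @param m links added per arriving vertex (>= 1).
#' @param p_t triad-formation probability in `[0, 1]`.
#' @return an undirected simple connected [igraph::graph].
#' @examples
#' g <- generate_hk(100, m = 3, p_t = 1)
#' mean(igraph::degree(g))
#' @export
generate_hk <- function(n, m = 3, p_t = 1) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || m < 1 || n <= m + 1) {
    stop("need n > m + 1 and m >= 1", call. = FALSE)
  }
  if (p_t < 0 || p_t > 1) stop("p_t must lie in [0, 1]", call. = FALSE)

  # adjacency as list of integer vectors; degree vector for PA sampling
  adj <- vector("list", n)
  n0 <- m + 1L
  for (v in seq_len(n0)) adj[[v]] <- setdiff(seq_len(n0), v)
  deg <- integer(n)
  deg[seq_len(n0)] <- m

  pa_target <- function(v) {
    # degree-proportional draw among existing vertices not yet linked to v
    cand <- setdiff(which(deg > 0), c(v, adj[[v]]))
    if (length(cand) == 0) return(NA_integer_)
    if (length(cand) == 1) return(cand)
    sample(cand, 1, prob = deg[cand])
  }

  for (v in (n0 + 1L):n) {
    last_pa <- NA_integer_
    links <- 0L
    while (links < m) {
      tgt <- NA_integer_
      if (links > 0L && !is.na(last_pa) && runif(1) < p_t) {
        cand <- setdiff(adj[[last_pa]], c(v, adj[[v]]))
        if (length(cand) > 0) {
          tgt <- if (length(cand) == 1) cand else sample(cand, 1)
        }
      }
      if (is.na(tgt)) {
        tgt <- pa_target(v)
        if (is.na(tgt)) break  # no eligible target at all
        last_pa <- tgt
      }
      adj[[v]] <- c(adj[[v]], tgt)
      adj[[tgt]] <- c(adj[[tgt]], v)
      deg[v] <- deg[v] + 1L
      deg[tgt] <- deg[tgt] + 1L
      links <- links + 1L
    }
  }
  graph_from_adj(adj, n)
}

#' Dorogovtsev-Mendes growing network
#'
#' Seeded with a triangle; every arriving vertex attaches to both endpoints of
#' one uniformly chosen existing edge, closing a triangle. The mean degree
#' tends to 4, every edge lies in at least one 3-clique (complete percolation
#' of triangles), and every vertex satisfies `k3(i) at p = 1` equal to
#' `k2(i) at p = 0` minus 1 after full promotion.
#'
#' @param n number of vertices (>= 3).
#' @return an undirected simple connected [igraph::graph].
#' @export
generate_dm <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3) stop("need n >= 3", call. = FALSE)
  # edges stored as a growing 2-column matrix for uniform edge sampling
  n_edges <- 3L + 2L * (n - 3L)
  ea <- integer(n_edges); eb <- integer(n_edges)
  ea[1:3] <- c(1L, 1L, 2L); eb[1:3] <- c(2L, 3L, 3L)
  cnt <- 3L
  if (n > 3L) {
    for (v in 4L:n) {
      j <- sample.int(cnt, 1)
      ea[cnt + 1L] <- v; eb[cnt + 1L] <- ea[j]
      ea[cnt + 2L] <- v; eb[cnt + 2L] <- eb[j]
      cnt <- cnt + 2L
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::add_edges(g, rbind(ea, eb))
}

#' Erdos-Renyi random graph with fixed edge count
#'
#' `G(N, M)` with `M = round(N * k_mean / 2)` edges drawn uniformly without
#' replacement, pinning the mean degree exactly. Used as the homogeneous,
#' weakly clustered reference structure.
#'
#' @param n number of vertices.
#' @param k_mean target mean degree (< n - 1).
#' @param connected resample until the realization is connected (default
#'   `FALSE`). The dynamics experiments use connected realizations: an
#'   isolated vertex can never update its strategy, so absorption into a
#'   homogeneous population would be impossible by construction rather than
#'   for dynamical reasons.
#' @return an undirected simple [igraph::graph].
#' @export
generate_er <- function(n, k_mean = 6, connected = FALSE) {
  n <- as.integer(n)
  if (k_mean < 0 || k_mean >= n - 1) {
    stop("need 0 <= k_mean < n - 1", call. = FALSE)
  }
  m_edges <- round(n * k_mean / 2)
  for (i in 1:100) {
    g <- igraph::sample_gnm(n, m_edges, directed = FALSE)
    if (!connected || igraph::is_connected(g)) return(g)
  }
  stop("no connected G(n, m) realization found in 100 draws", call. = FALSE)
}

graph_from_adj <- function(adj, n) {
  el <- do.call(rbind, lapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    nb <- nb[nb > v]
    if (length(nb) == 0) return(NULL)
    cbind(v, nb)
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  igraph::simplify(g)
}

#' Enumerate all 3-cliques of a graph
#'
#' Every unordered vertex triple whose three edges are all present, listed
#' once.
#'
#' @param g an undirected simple [igraph::graph].
#' @return integer matrix with 3 columns, one row per 3-clique (0 rows if
#'   none); rows are sorted triples.
#' @export
enumerate_3cliques <- function(g) {
  tr <- igraph::triangles(g)
  if (length(tr) == 0) return(matrix(integer(0), ncol = 3))
  m <- matrix(as.integer(tr), ncol = 3, byrow = TRUE)
  t(apply(m, 1, sort))
}

#' Promote a fraction of 3-cliques to triangular hyperedges
#'
#' The rank-3 construction: starting from a simple base graph, a fraction `p`
#' of its 3-cliques is picked uniformly at random (without replacement, from
#' the full clique list); each picked 3-clique becomes a cardinality-3
#' hyperedge ("triangle"); then every 2-edge that is a subset of at least one
#' selected triangle is removed, so the result is a simple hypergraph. The
#' number promoted is `round(p * #3-cliques)` (round-half-to-even). By
#' construction the base graph is exactly the 2-section of the result, for
#' every `p`.
#'
#' @param g an undirected simple [igraph::graph].
#' @param p conversion fraction in `[0, 1]`.
#' @return a simple rank-<= 3 [hypergraph()] whose [two_section()] equals `g`.
#' @examples
#' g <- generate_dm(50)
#' H <- promote_cliques(g, 0.5)
#' cardinality_fractions(H)
#' @export
promote_cliques <- function(g, p) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single value in [0, 1]", call. = FALSE)
  }
  cl <- enumerate_3cliques(g)
  n_sel <- round(p * nrow(cl))
  sel <- if (n_sel > 0) cl[sample.int(nrow(cl), n_sel), , drop = FALSE]
         else cl[0, , drop = FALSE]
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) el <- t(apply(el, 1, sort)) else el <- el
  if (nrow(sel) > 0) {
    covered_keys <- unique(c(
      paste(sel[, 1], sel[, 2]),
      paste(sel[, 1], sel[, 3]),
      paste(sel[, 2], sel[, 3])
    ))
    edge_key <- paste(el[, 1], el[, 2])
    el <- el[!(edge_key %in% covered_keys), , drop = FALSE]
  }
  edges <- c(
    lapply(seq_len(nrow(sel)), function(i) sel[i, ]),
    lapply(seq_len(nrow(el)), function(i) el[i, ])
  )
  hypergraph(edges, n_vertices = igraph::vcount(g), check = FALSE)
}
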