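#' Null-model rewirings of a base network
#'
#' Two degree-preserving randomization procedures used to characterize
#' topological traps:
#'
#' * `rewire_preserve_clustering()` additionally preserves the local
#'   clustering coefficient of every vertex, exactly: a proposed link
#'   exchange is accepted only if the triangle count of each vertex it could
#'   affect (the four endpoints and the common neighbours of the removed and
#'   added vertex pairs) is unchanged. Degrees being fixed, unchanged triangle
#'   counts mean an unchanged per-vertex clustering vector.
#' * `rewire_preserve_3k()` preserves the joint degree distributions over
#'   edges `P(k, k')` and over 2-paths `P(k, k', k'')` (second-order degree
#'   correlations), but not clustering: the two chosen vertices must have
#'   equal degree, and so must the two far endpoints of the exchanged links.
#'
#' `n_steps` counts *accepted* exchanges; rejected proposals are retried up to
#' `max_attempts` total proposals (so graphs with no admissible move
#' terminate). Both procedures keep the graph simple (no self-loops or
#' multi-edges) and never touch the degree sequence.
#'
#' @param g an undirected simple [igraph::graph].
#' @param n_steps number of accepted exchanges to perform (default 1e5).
#' @param max_attempts cap on total proposals (default `200 * n_steps`).
#' @return the rewired [igraph::graph], with attributes `accepted` and
#'   `attempts` recording the realized counts.
#' @export
rewire_preserve_clustering <- function(g, n_steps = 1e5,
                                       max_attempts = 200 * n_steps) {
  el <- igraph::as_edgelist(g, names = FALSE)
  out <- cpp_rewire_clustering(igraph::vcount(g),
                               matrix(as.integer(el - 1L), ncol = 2),
                               as.integer(n_steps), max_attempts)
  rewired_graph(g, out)
}

#' @rdname rewire_preserve_clustering
#' @export
rewire_preserve_3k <- function(g, n_steps = 1e5,
                               max_attempts = 200 * n_steps) {
  el <- igraph::as_edgelist(g, names = FALSE)
  out <- cpp_rewire_3k(igraph::vcount(g),
                       matrix(as.integer(el - 1L), ncol = 2),
                       as.integer(n_steps), max_attempts)
  rewired_graph(g, out)
}

rewired_graph <- function(g, out) {
  gg <- igraph::make_empty_graph(igraph::vcount(g), directed = FALSE)
  if (nrow(out$edgelist) > 0) gg <- igraph::add_edges(gg, t(out$edgelist + 1L))
  attr(gg, "accepted") <- out$accepted
  attr(gg, "attempts") <- out$attempts
  gg
}

#' Joint degree histograms over edges and 2-paths
#'
#' Summaries preserved by [rewire_preserve_3k()]: `P(k, k')` over unordered
#' edges and `P(k, k', k'')` over 2-paths (middle vertex second, end degrees
#' sorted). Returned as count tables keyed by degree tuples, convenient for
#' exact before/after comparison.
#'
#' @param g an undirected simple [igraph::graph].
#' @return list with `pkk` and `pkkk`, named integer tables.
#' @export
joint_degree_histograms <- function(g) {
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  d1 <- pmin(deg[el[, 1]], deg[el[, 2]])
  d2 <- pmax(deg[el[, 1]], deg[el[, 2]])
  pkk <- table(paste(d1, d2))
  adj <- igraph::as_adj_list(g, mode = "all")
  keys <- unlist(lapply(seq_along(adj), function(v) {
    nb <- as.integer(adj[[v]])
    if (length(nb) < 2) return(character(0))
    pr <- utils::combn(deg[nb], 2)
    paste(pmin(pr[1, ], pr[2, ]), deg[v], pmax(pr[1, ], pr[2, ]))
  }))
  pkkk <- table(keys)
  list(pkk = pkk, pkkk = pkkk)
}

#' Mean convergence time corrected for non-converged runs
#'
#' When a fraction of runs hits `tmax` without absorbing, the raw mean
#' convergence time mixes genuine convergence with the cutoff. The corrected
#' mean over the converged runs only is
#' `tC = runs * (t_mean - n_nc * tmax / runs) / (runs - n_nc)`.
#'
#' @param t_mean raw mean convergence time over all runs.
#' @param n_nc number of non-converged runs.
#' @param tmax the cutoff used.
#' @param runs total runs (default 100).
#' @return the corrected mean time.
#' @examples
#' corrected_convergence_time(2450, 10, 2e4)  # 500
#' @export
corrected_convergence_time <- function(t_mean, n_nc, tmax, runs = 100) {
  if (n_nc < 0 || n_nc >= runs) {
    stop("need 0 <= n_nc < runs (all runs unconverged leaves no data)",
         call. = FALSE)
  }
  if (t_mean < n_nc * tmax / runs - 1e-9) {
    stop("inconsistent t_mean: smaller than the non-converged contribution",
         call. = FALSE)
  }
  runs * (t_mean - n_nc * tmax / runs) / (runs - n_nc)
}
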