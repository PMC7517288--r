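#' Payoff line of a local configuration
#'
#' With per-round payoffs, a vertex's payoff is linear in the synergy alpha.
#' Given its m-degree sequence `km`, the total number of cooperating
#' co-members per cardinality `nc_m` (summed over its m-hyperedges) and its
#' own strategy, the payoff is `f(alpha) = intercept + slope * alpha` with
#' `intercept = -b * k * sigma` and
#' `slope = b * sum_m (nc_m + km * sigma) / m`.
#'
#' @param sigma strategy of the focal vertex (0/1).
#' @param km named numeric vector of m-degrees (names are cardinalities).
#' @param nc_m named numeric vector, total cooperating co-members per
#'   cardinality (same names as `km`).
#' @param b contribution (default 1).
#' @return list with `intercept` and `slope`.
#' @export
payoff_line <- function(sigma, km, nc_m, b = 1) {
  m <- as.numeric(names(km))
  if (anyNA(m) || !identical(names(km), names(nc_m))) {
    stop("km and nc_m must share cardinality names", call. = FALSE)
  }
  if (any(nc_m > km * (m - 1))) {
    stop("nc_m cannot exceed km * (m - 1)", call. = FALSE)
  }
  list(intercept = -b * sum(km) * sigma,
       slope = b * sum((nc_m + km * sigma) / m))
}

#' Bottleneck threshold: synergy equalizing a cooperator and a defector
#'
#' A bottleneck trap is pinned by the synergy values at which a cooperator
#' and a defector in a given local configuration earn the same payoff; between
#' two such thresholds the favoured imitation direction alternates and the
#' configuration cycles instead of absorbing. Payoffs being linear in alpha
#' ([payoff_line()]), the threshold is the crossing of the two lines.
#'
#' @param coop list with `km` and `nc_m` for the cooperator (see
#'   [payoff_line()]).
#' @param defe same for the defector.
#' @param b contribution (default 1).
#' @return list with `alpha_th` (the crossing, `NA` if none) and `status`:
#'   `"crossing"`, `"parallel"` (never equal) or `"always_equal"` (identical
#'   lines).
#' @examples
#' # pairwise-only case: cooperator with k2 links and nc cooperating
#' # neighbours vs defector with ncp cooperating neighbours
#' bottleneck_threshold(
#'   coop = list(km = c("2" = 4), nc_m = c("2" = 2)),
#'   defe = list(km = c("2" = 4), nc_m = c("2" = 1))
#' )  # alpha_th = 2 * 4 / (4 + 2 - 1)
#' @export
bottleneck_threshold <- function(coop, defe, b = 1) {
  lc <- payoff_line(1, coop$km, coop$nc_m, b = b)
  ld <- payoff_line(0, defe$km, defe$nc_m, b = b)
  dslope <- lc$slope - ld$slope
  dint <- ld$intercept - lc$intercept
  if (abs(dslope) < 1e-12) {
    if (abs(dint) < 1e-12) {
      return(list(alpha_th = NA_real_, status = "always_equal"))
    }
    return(list(alpha_th = NA_real_, status = "parallel"))
  }
  list(alpha_th = dint / dslope, status = "crossing")
}

#' Structural bottleneck-trap candidates
#'
#' Bottleneck traps need bridge links lacking redundant paths: a link that is
#' not contained in any 3-clique of the 2-section. Structures with complete
#' triangle percolation (every link inside a 3-clique, as Dorogovtsev-Mendes
#' networks have) admit no bottleneck traps. This diagnostic returns the
#' bridge-type links; it flags where such traps *can* live, it is not an
#' exhaustive trap classifier.
#'
#' @param g an undirected simple [igraph::graph] (e.g. a 2-section).
#' @return tibble with columns `from`, `to`, one row per link outside every
#'   3-clique (0 rows when none exist).
#' @export
find_bottleneck_candidates <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(tibble::tibble(from = integer(0), to = integer(0)))
  cl <- enumerate_3cliques(g)
  covered <- character(0)
  if (nrow(cl) > 0) {
    covered <- unique(c(paste(cl[, 1], cl[, 2]), paste(cl[, 1], cl[, 3]),
                        paste(cl[, 2], cl[, 3])))
  }
  a <- pmin(el[, 1], el[, 2]); bb <- pmax(el[, 1], el[, 2])
  keep <- !(paste(a, bb) %in% covered)
  tibble::tibble(from = as.integer(a[keep]), to = as.integer(bb[keep]))
}

#' Trap census: non-convergence on original vs rewired structures
#'
#' Runs matched sweeps (same grid, seeds, cutoff) of the dynamics on
#' hypergraphs promoted from (i) the original base network, (ii) its
#' degree+clustering-preserving rewiring and (iii) its 3K-preserving
#' rewiring, and tabulates the non-convergence count per 100 runs at each grid
#' point. Persistent non-convergence under a null model means the
#' corresponding structural feature (local clustering vs second-order degree
#' correlations) carries the traps.
#'
#' @param g_list list of base networks ([igraph::graph]).
#' @param p conversion fraction for the promotion.
#' @param r_grid ascending grid of reduced synergy values.
#' @param beta,b,c0,runs,tmax sweep settings (see [pgg_sweep()]).
#' @param rewire_steps accepted exchanges per rewiring (default 1e5).
#' @param rewire_attempts proposal cap per rewiring (default
#'   `200 * rewire_steps`); the clustering-preserving null accepts only a
#'   small fraction of proposals, so this bounds its runtime.
#' @param seed master seed.
#' @return a tibble with columns `structure` (`original`,
#'   `preserve_clustering`, `preserve_3k`), `r`, `alpha`, `mean_cinf`,
#'   `mean_t`, `n_nc_per100`, plus a `traps_persist` logical attribute per
#'   structure (any non-convergence on the grid).
#' @export
trap_census <- function(g_list, p, r_grid, beta = 1, b = 1, c0 = 0.5,
                        runs = 25, tmax = 5e3, rewire_steps = 1e5,
                        rewire_attempts = 200 * rewire_steps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- spawn_seeds(4)
  variants <- list(
    original = g_list,
    preserve_clustering = {
      set.seed(seeds[1])
      lapply(g_list, rewire_preserve_clustering, n_steps = rewire_steps,
             max_attempts = rewire_attempts)
    },
    preserve_3k = {
      set.seed(seeds[2])
      lapply(g_list, rewire_preserve_3k, n_steps = rewire_steps,
             max_attempts = rewire_attempts)
    }
  )
  out <- purrr::imap(variants, function(gs, nm) {
    set.seed(seeds[3])  # same promotion + run seeds across structures
    H_list <- lapply(gs, promote_cliques, p = p)
    sw <- pgg_sweep(H_list, beta = beta, b = b, r_grid = r_grid, runs = runs,
                    c0 = c0, tmax = tmax, seed = seeds[4])
    dplyr::mutate(tibble::as_tibble(sw), structure = nm, .before = 1)
  })
  res <- dplyr::bind_rows(out)
  persist <- dplyr::summarise(
    dplyr::group_by(res, .data$structure),
    traps_persist = any(.data$n_nc_per100 > 0), .groups = "drop")
  attr(res, "traps_persist") <- persist
  res
}
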