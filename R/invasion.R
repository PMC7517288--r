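#' Identify hubs of a hypergraph by degree percentile
#'
#' Hubs are the vertices whose degree is at or above the given percentile of
#' the degree distribution. The degree used is configurable: the generalized
#' degree `k(i)` (number of incident hyperedges, the default) or the 2-section
#' degree.
#'
#' @param H a [hypergraph()].
#' @param percentile percentile in (0, 100), e.g. 97 or 99.
#' @param degree `"generalized"` or `"two_section"`.
#' @return integer vector of hub vertex ids.
#' @export
identify_hubs <- function(H, percentile = 97,
                          degree = c("generalized", "two_section")) {
  degree <- match.arg(degree)
  deg <- switch(degree,
                generalized = m_degrees(H)$k,
                two_section = igraph::degree(two_section(H)))
  thr <- quantile(deg, percentile / 100)
  hubs <- which(deg >= thr)
  if (length(hubs) == 0) stop("empty hub set", call. = FALSE)
  hubs
}

#' Hub-to-neighbourhood degree ratio
#'
#' For an s-uniform hypergraph, `xi_s = kbar_s / ks_hub`: the mean s-degree
#' over hub neighbourhoods (in the 2-section) relative to the mean hub
#' s-degree. Scale-free structures have `xi_s` well below 1 — a hub's
#' neighbours are far less connected than the hub — which is what depresses
#' the hub invasion threshold. Per-hub neighbourhood means are averaged across
#' hubs.
#'
#' @param H a [hypergraph()].
#' @param hubs hub vertex ids (see [identify_hubs()]).
#' @param s cardinality whose m-degree is used (default the rank of `H`).
#' @return list with `xi_s`, `ks_hub`, `kbar_s`.
#' @export
xi_s <- function(H, hubs, s = hypergraph_rank(H)) {
  md <- m_degrees(H)
  col <- paste0("k", s)
  if (!col %in% names(md)) {
    stop(sprintf("hypergraph has no hyperedges of cardinality %d", s),
         call. = FALSE)
  }
  ks <- md[[col]]
  g <- two_section(H)
  adj <- igraph::as_adj_list(g, mode = "all")
  nb_means <- vapply(hubs, function(v) {
    nb <- as.integer(adj[[v]])
    if (length(nb) == 0) return(NA_real_)
    mean(ks[nb])
  }, numeric(1))
  ks_hub <- mean(ks[hubs])
  kbar_s <- mean(nb_means, na.rm = TRUE)
  list(xi_s = kbar_s / ks_hub, ks_hub = ks_hub, kbar_s = kbar_s)
}

#' Initial cooperating-neighbour fractions for the hub analysis
#'
#' With a uniformly random initial fraction `c0` of cooperators, a defector's
#' neighbours cooperate with average fraction `qbar0_d = c0 N / (N - 1)` and
#' the (cooperator) hub's with `q0_hub = qbar0_d - 1 / (N - 1)`.
#'
#' @param c0 initial cooperator fraction in (0, 1).
#' @param N population size (>= 3).
#' @return list with `q0_hub` and `qbar0_d`.
#' @export
initial_q <- function(c0, N) {
  if (!(c0 > 0 && c0 < 1)) stop("c0 must lie in (0, 1)", call. = FALSE)
  if (N < 3) stop("need N >= 3", call. = FALSE)
  qbar0_d <- c0 * N / (N - 1)
  list(q0_hub = qbar0_d - 1 / (N - 1), qbar0_d = qbar0_d)
}

#' Cooperator-hub invasion threshold
#'
#' The synergy above which a cooperator hub with m-degree sequence `km_hub`,
#' surrounded by average neighbours with mean degrees `kbar_m`, earns at least
#' the average payoff of its defector neighbours at t = 0 — so whenever the
#' hub and a defector neighbour meet for a strategy update, the hub's survival
#' (and the defector's conversion) is favoured:
#' `alpha_th = sum_m km_hub / sum_m (km_hub / m +
#'   ((m-1)/m) (q0_hub km_hub - qbar0_d kbar_m))`.
#'
#' @param km_hub named numeric vector of hub mean m-degrees (names are
#'   cardinalities).
#' @param kbar_m named numeric vector of neighbourhood mean m-degrees (same
#'   names).
#' @param c0 initial cooperator fraction.
#' @param N population size.
#' @return the threshold synergy, or `NA` (with a warning) when the
#'   denominator is non-positive and no finite threshold exists.
#' @export
hub_threshold <- function(km_hub, kbar_m, c0, N) {
  m <- as.numeric(names(km_hub))
  if (anyNA(m) || !identical(names(km_hub), names(kbar_m))) {
    stop("km_hub and kbar_m must share cardinality names", call. = FALSE)
  }
  q <- initial_q(c0, N)
  denom <- sum(km_hub / m + (m - 1) / m *
                 (q$q0_hub * km_hub - q$qbar0_d * kbar_m))
  if (denom <= 0) {
    warning("non-positive denominator: no finite hub threshold")
    return(NA_real_)
  }
  sum(km_hub) / denom
}

#' Reduced hub threshold for s-uniform hypergraphs
#'
#' For an s-uniform hypergraph with `kbar_s = xi_s * ks_hub` the hub threshold
#' relative to the well-mixed critical synergy reduces to
#' `r_hub = 1 / (1 + (s - 1) (q0_hub - qbar0_d xi_s))`, a monotone decreasing
#' function of s: the higher the interaction order, the earlier (in r) a
#' cooperator hub becomes unbeatable, which is the analytic footprint of the
#' reciprocity gain from group interactions.
#'
#' @param s uniform cardinality (>= 2).
#' @param xi_s neighbourhood-to-hub degree ratio (see [xi_s()]).
#' @param c0 initial cooperator fraction.
#' @param N population size.
#' @return the ratio `alpha_th_hub / alpha_cr`, or `NA` when no finite
#'   threshold exists.
#' @examples
#' r_hub(2, xi_s = 0.5, c0 = 0.5, N = 501)  # ~0.801
#' @export
r_hub <- function(s, xi_s, c0, N) {
  q <- initial_q(c0, N)
  denom <- 1 + (s - 1) * (q$q0_hub - q$qbar0_d * xi_s)
  out <- ifelse(denom > 0, 1 / denom, NA_real_)
  if (anyNA(out)) warning("non-positive denominator: no finite hub threshold")
  out
}

#' Evaluate the hub invasion ratio on a generated hypergraph
#'
#' Convenience pipeline: identify hubs at a degree percentile, measure
#' `xi_s`, and evaluate [r_hub()] at the hypergraph's (uniform) cardinality.
#'
#' @param H an s-uniform [hypergraph()].
#' @param percentile hub percentile.
#' @param c0 initial cooperator fraction.
#' @param s cardinality (default rank).
#' @param degree degree definition for hub selection (see [identify_hubs()]).
#' @return one-row tibble: `percentile`, `s`, `n_hubs`, `ks_hub`, `xi_s`,
#'   `r_hub`.
#' @export
hub_invasion <- function(H, percentile = 97, c0 = 0.5,
                         s = hypergraph_rank(H),
                         degree = c("generalized", "two_section")) {
  hubs <- identify_hubs(H, percentile, degree = match.arg(degree))
  xs <- xi_s(H, hubs, s = s)
  tibble::tibble(percentile = percentile, s = s, n_hubs = length(hubs),
                 ks_hub = xs$ks_hub, xi_s = xs$xi_s,
                 r_hub = r_hub(s, xs$xi_s, c0, H$n))
}

#' Isolated-defector scenario
#'
#' The local configuration for the invasion analysis: a defector `d` with
#' degree pair `(k2_d, k3_d)` whose neighbours are all cooperators, each
#' treated as the average vertex with degree pair `(k2_c, k3_c)`, sharing
#' `kappa_d` triangles with `d` (and `kappa_c` with their own neighbours).
#' Neighbourhood sizes default to `|Omega| = k2 + 2 k3 / kappa` and can be
#' overridden (as when reproducing the survival-probability curves, where
#' `|Omega|` is a free parameter).
#'
#' @param k2_d,k3_d defector link- and triangle-degrees.
#' @param k2_c,k3_c cooperator-neighbour link- and triangle-degrees.
#' @param kappa_d triangles each cooperator neighbour shares with `d`.
#' @param kappa_c triangles each cooperator shares with one of its own
#'   neighbours (defaults to `kappa_d`).
#' @param omega_d,omega neighbourhood sizes of `d` and of a cooperator
#'   neighbour (defaults from the degree pairs).
#' @param b contribution (default 1).
#' @return a list of class `defector_scenario`.
#' @export
defector_scenario <- function(k2_d, k3_d, k2_c, k3_c, kappa_d,
                              kappa_c = kappa_d, omega_d = NULL,
                              omega = NULL, b = 1) {
  if (k3_d > 0 && kappa_d <= 0) {
    stop("kappa_d must be positive when the defector has triangles",
         call. = FALSE)
  }
  if (is.null(omega_d)) {
    omega_d <- k2_d + if (k3_d > 0) 2 * k3_d / kappa_d else 0
  }
  if (is.null(omega)) {
    omega <- k2_c + if (k3_c > 0) 2 * k3_c / kappa_c else 0
  }
  structure(list(k2_d = k2_d, k3_d = k3_d, k2_c = k2_c, k3_c = k3_c,
                 kappa_d = kappa_d, kappa_c = kappa_c,
                 omega_d = omega_d, omega = omega, b = b),
            class = "defector_scenario")
}

#' Payoff gap between a cooperator neighbour and an isolated defector
#'
#' For a defector surrounded (to sufficient depth) by cooperators,
#' `f(j) - f(d) = b (alpha (k2_j - k2_d/2 + k3_j - 2 k3_d/3 - a_j)
#'   - k2_j - k3_j)` where `a_j` is 1/2 if `j` neighbours `d` through a link
#' and `kappa_d / 3` if through a triangle. Linear in alpha; for `alpha -> 0`
#' the gap tends to `-b (k2_j + k3_j) < 0` (the cooperator only pays costs).
#'
#' @param scn a [defector_scenario()].
#' @param alpha synergy factor (vectorized).
#' @param via `"link"` or `"triangle"`: how `j` neighbours `d`.
#' @return numeric gap(s) `f(cooperator) - f(defector)`.
#' @export
defector_payoff_gap <- function(scn, alpha, via = c("link", "triangle")) {
  stopifnot(inherits(scn, "defector_scenario"))
  via <- match.arg(via)
  a_j <- if (via == "link") 1 / 2 else scn$kappa_d / 3
  scn$b * (alpha * (scn$k2_c - scn$k2_d / 2 + scn$k3_c - 2 * scn$k3_d / 3 -
                      a_j) - scn$k2_c - scn$k3_c)
}

#' Joint probability that an isolated defector survives and invades
#'
#' Probability that the defector keeps its strategy for one round and
#' simultaneously converts `w` of its cooperator neighbours:
#' `(1 - p_d) * (F(f_d - f_c) / |Omega|)^w`, where
#' `p_d = F(f_c - f_d)` is the defector's own switching probability (all its
#' neighbours are cooperators with the same average payoff) and each
#' cooperator picks `d` among its `|Omega|` neighbours with probability
#' `1/|Omega|`. For `beta -> 0` this tends to `(1/2) (1 / (2 |Omega|))^w`.
#'
#' @param scn a [defector_scenario()].
#' @param alpha synergy (vectorized).
#' @param beta selection strength.
#' @param w number of simultaneous invasions, `0 <= w <= |Omega(d)|`.
#' @param via `"link"` or `"triangle"` interaction channel.
#' @return probability (vectorized over `alpha`).
#' @export
survive_and_invade_prob <- function(scn, alpha, beta, w = 1,
                                    via = c("link", "triangle")) {
  stopifnot(inherits(scn, "defector_scenario"))
  if (w < 0 || w > scn$omega_d) {
    stop("w must lie in [0, |Omega(d)|]", call. = FALSE)
  }
  gap <- defector_payoff_gap(scn, alpha, via = match.arg(via))
  p_d <- fermi(gap, beta)
  (1 - p_d) * (fermi(-gap, beta) / scn$omega)^w
}

#' Degree/clustering conditions for defector-cooperator competition
#'
#' Reports whether the cooperator-defector payoff gap *shrinks* as alpha
#' grows (`d(f_c - f_d)/d alpha < 0`), the condition under which raising the
#' synergy paradoxically helps a high-degree defector hold out, widening the
#' transition region:
#' * `general`: `((|Omega_d| + 1)/|Omega_d|) (k2_d/2 + 2 k3_d/3) > k2_c + k3_c`
#'   (impossible on a regular structure, where the left factor is <= 3/2).
#' * `p0`: the pairwise-only (`p = 0`) specialization
#'   `k2_d / k2_c > 2 - 1/k2_c`.
#' * `p1`: the triangle-only (`p = 1`) condition rewritten in `p = 0` degrees
#'   via `k3 = k2 kappa / 2`: `k2_d / k2_c > (3/2)(kappa_c/kappa_d) - 1/k2_c`.
#' * `implication`: `p0` implies `p1` iff `kappa_d / kappa_c > 3/4`,
#'   equivalently `C_d (k2_d - 1) / (C_c (k2_c - 1)) > 3/4` in terms of local
#'   clustering.
#' * `band`: the interval `(3/2)(kappa_c/kappa_d) k2_c - 1 < k2_d <=
#'   2 k2_c - 1` of intermediate defector degrees for which the competition
#'   exists with triangles but not with links.
#'
#' @param scn a [defector_scenario()].
#' @return a list with logical fields `general`, `p0`, `p1`, `implication`
#'   and numeric `band` (`lower`, `upper`).
#' @export
competition_conditions <- function(scn) {
  stopifnot(inherits(scn, "defector_scenario"))
  general <- (scn$omega_d + 1) / scn$omega_d *
    (scn$k2_d / 2 + 2 * scn$k3_d / 3) > scn$k2_c + scn$k3_c
  p0 <- scn$k2_d / scn$k2_c > 2 - 1 / scn$k2_c
  p1 <- scn$k2_d / scn$k2_c >
    (3 / 2) * (scn$kappa_c / scn$kappa_d) - 1 / scn$k2_c
  implication <- scn$kappa_d / scn$kappa_c > 3 / 4
  band <- c(lower = (3 / 2) * (scn$kappa_c / scn$kappa_d) * scn$k2_c - 1,
            upper = 2 * scn$k2_c - 1)
  list(general = general, p0 = p0, p1 = p1, implication = implication,
       band = band)
}

#' Shared-triangle count from local clustering
#'
#' In the promoted structures, the number of triangles a vertex shares with a
#' neighbour relates to its base-network local clustering C and link-degree
#' k2 as `kappa = C * (k2 - 1)` (evaluated at p = 0).
#'
#' @param C local clustering coefficient in `[0, 1]` (vectorized).
#' @param k2 link degree (>= 1).
#' @return numeric `kappa`.
#' @export
kappa_from_clustering <- function(C, k2) {
  if (any(C < 0 | C > 1)) stop("C must lie in [0, 1]", call. = FALSE)
  if (any(k2 < 1)) stop("k2 must be >= 1", call. = FALSE)
  C * (k2 - 1)
}
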