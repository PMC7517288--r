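#' Mean-field map for the cooperator density
#'
#' Under the mean-field approximation (every vertex carries the average
#' m-degree sequence, local states uncorrelated), the density obeys
#' `c(t+1) = c(t) + c(t)(1 - c(t)) (F(df) - F(-df))` with the
#' strategy-independent payoff gap `df = b * sum_m (alpha/m - 1) <k_m>`.
#' `c = 0` and `c = 1` are fixed points for every synergy; the interior flow
#' changes direction at `alpha = alpha_cr`.
#'
#' @param c cooperator density in `[0, 1]` (vectorized).
#' @param km_means named numeric vector of mean m-degrees, names are the
#'   cardinalities (e.g. `c("2" = 3, "3" = 2)`).
#' @param params a [game_params()].
#' @return next density (same length as `c`).
#' @export
mean_field_step <- function(c, km_means, params) {
  stopifnot(inherits(params, "game_params"))
  df <- mean_field_gap(km_means, params)
  c + c * (1 - c) * (fermi(df, params$beta) - fermi(-df, params$beta))
}

mean_field_gap <- function(km_means, params) {
  m <- as.numeric(names(km_means))
  if (anyNA(m)) stop("km_means must be named by cardinality", call. = FALSE)
  params$b * sum((params$alpha / m - 1) * km_means)
}

#' Iterate the mean-field map to a fixed point
#'
#' @inheritParams mean_field_step
#' @param c0 initial density.
#' @param tol stopping tolerance on `|c(t+1) - c(t)|` (default 1e-12).
#' @param max_iter iteration cap (default 1e6).
#' @return list with `c_star`, `iterations`, `converged`, and the sign of the
#'   payoff gap `gap`.
#' @export
mean_field_fixed_point <- function(c0, km_means, params, tol = 1e-12,
                                   max_iter = 1e6) {
  cc <- c0
  it <- 0L
  repeat {
    cn <- mean_field_step(cc, km_means, params)
    it <- it + 1L
    if (abs(cn - cc) < tol || it >= max_iter) {
      return(list(c_star = cn, iterations = it,
                  converged = abs(cn - cc) < tol,
                  gap = mean_field_gap(km_means, params)))
    }
    cc <- cn
  }
}

#' Mean-field critical synergy from mean m-degrees
#'
#' `alpha_cr = sum_m <k_m> / sum_m <k_m> / m`, equivalently `sum_m m p_m`
#' under the weighting `p_m` proportional to `<k_m> / m` — the same number
#' [alpha_cr()] computes from hyperedge counts, providing a two-route
#' consistency check on any generated hypergraph.
#'
#' @param x either a named numeric vector of mean m-degrees or a
#'   [hypergraph()] (whose mean m-degrees are then used).
#' @return a single numeric value.
#' @examples
#' alpha_cr_mean_field(c("2" = 3, "3" = 3))  # 2.4
#' @export
alpha_cr_mean_field <- function(x) {
  if (is_hypergraph(x)) {
    md <- m_degrees(x)
    cols <- grep("^k[0-9]+$", names(md), value = TRUE)
    km <- vapply(md[cols], mean, numeric(1))
    names(km) <- sub("^k", "", cols)
    x <- km
  }
  m <- as.numeric(names(x))
  if (anyNA(m) || !any(x > 0)) {
    stop("need mean m-degrees named by cardinality, at least one positive",
         call. = FALSE)
  }
  sum(x) / sum(x / m)
}

#' Finite-size critical synergy of a complete m-uniform hypergraph
#'
#' For a complete m-uniform simple hypergraph on N vertices under strong
#' selection (`beta * b >> 1`) the defection/cooperation transition sits at
#' `alpha_cr^m = m (N - 1) / (N - m)`, above the infinite-population value m,
#' and the relative shift grows with m.
#'
#' @param m group size (>= 2).
#' @param N population size (> m).
#' @return a single numeric value.
#' @examples
#' alpha_cr_finite(3, 500)  # ~3.012
#' @export
alpha_cr_finite <- function(m, N) {
  if (any(m < 2)) stop("m must be >= 2", call. = FALSE)
  if (any(N <= m)) stop("need N > m", call. = FALSE)
  m * (N - 1) / (N - m)
}
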