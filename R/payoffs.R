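#' Game parameters for the public goods game
#'
#' @param alpha synergy factor; the pot collected in a group of size m is
#'   multiplied by `alpha` and split equally among the m members. The social
#'   dilemma exists for `1 < alpha < m`.
#' @param b contribution a cooperator pays into each group it belongs to
#'   (default 1).
#' @param beta selection strength of the Fermi imitation rule; large `beta`
#'   approaches best-response, small `beta` a noisy replicator-like rule.
#' @return a list of class `game_params`.
#' @export
game_params <- function(alpha, b = 1, beta = 1) {
  if (!(alpha > 0)) stop("alpha must be positive", call. = FALSE)
  if (!(b > 0)) stop("b must be positive", call. = FALSE)
  if (!(beta > 0)) stop("beta must be positive", call. = FALSE)
  structure(list(alpha = alpha, b = b, beta = beta), class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("<game_params> alpha = %g, b = %g, beta = %g\n",
              x$alpha, x$b, x$beta))
  invisible(x)
}

#' Per-group public-goods payoff
#'
#' Payoff of one player in a single group (hyperedge) of size `m` in which
#' `nc` of its `m - 1` co-members cooperate:
#' `b * ((alpha/m - 1) * sigma + (alpha * (m-1) / m) * q)` with
#' `q = nc / (m - 1)`. Equivalent to pot redistribution: every cooperator pays
#' `b`, the pot `b * (nc + sigma) * alpha` is split `m` ways.
#'
#' @param sigma player strategy, 1 = cooperate, 0 = defect (vectorized).
#' @param nc number of cooperating co-members, `0 <= nc <= m - 1`.
#' @param m group size (>= 2).
#' @param params a [game_params()].
#' @return numeric payoff(s).
#' @examples
#' hyperedge_payoff(0, nc = 2, m = 3, game_params(alpha = 2))  # 4/3
#' @export
hyperedge_payoff <- function(sigma, nc, m, params) {
  stopifnot(inherits(params, "game_params"))
  if (any(m < 2)) stop("group size m must be >= 2", call. = FALSE)
  if (any(nc < 0 | nc > m - 1)) {
    stop("nc must lie in [0, m - 1]", call. = FALSE)
  }
  q <- nc / (m - 1)
  params$b * ((params$alpha / m - 1) * sigma +
                params$alpha * (m - 1) / m * q)
}

#' Per-round payoff vector over a hypergraph
#'
#' Sums the per-group payoff over every hyperedge incident on each vertex,
#' using the hyperedge's actual cooperator count at the given state. Payoffs
#' are per-round quantities (recomputed from scratch each round, never
#' accumulated). This pure-R implementation is the reference against which the
#' compiled simulator and the closed-form invasion expressions are checked.
#'
#' @param H a [hypergraph()].
#' @param sigma binary strategy vector of length `H$n` (1 = cooperate).
#' @param params a [game_params()].
#' @return numeric payoff vector of length `H$n`.
#' @export
total_payoff <- function(H, sigma, params) {
  stopifnot(is_hypergraph(H), length(sigma) == H$n,
            inherits(params, "game_params"))
  f <- numeric(H$n)
  K <- integer(H$n)
  for (e in H$edges) {
    m <- length(e)
    ncs <- sum(sigma[e])
    f[e] <- f[e] + params$b * (params$alpha / m) * ncs
    K[e] <- K[e] + 1L
  }
  f - params$b * K * sigma
}

#' Fermi imitation probability
#'
#' `F(x; beta) = 1 / (1 + exp(-beta * x))`: the probability of adopting a
#' neighbour's strategy given payoff difference `x` (their payoff minus own).
#' Satisfies `F(x) + F(-x) = 1`; for small `beta`,
#' `F(x) ~ 1/2 + beta * x / 4`.
#'
#' @param x payoff difference (vectorized).
#' @param beta selection strength (> 0).
#' @return probabilities in (0, 1).
#' @export
fermi <- function(x, beta) {
  if (!(beta > 0)) stop("beta must be positive", call. = FALSE)
  1 / (1 + exp(-beta * x))
}
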