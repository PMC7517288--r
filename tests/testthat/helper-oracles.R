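# Independent oracles used across the suite.

# Pot-redistribution payoff: every cooperator in a group of size m pays b,
# the pot is multiplied by alpha and split equally. Independent of the
# closed-form per-group payoff expression.
pot_payoff <- function(sigma, nc, m, alpha, b = 1) {
  pot <- b * (nc + sigma) * alpha
  pot / m - b * sigma
}

# Exact Markov-chain oracle for the synchronous dynamics on tiny systems.
# Enumerates all 2^n strategy states; each vertex independently flips to the
# opposite strategy with probability
#   p_i = (1/|Omega_i|) sum_{j in Omega_i, sigma_j != sigma_i} F(f_j - f_i),
# the marginal of "draw one neighbour uniformly, Fermi-imitate".
markov_transition_matrix <- function(H, params) {
  n <- H$n
  g <- two_section(H)
  adj <- igraph::as_adj_list(g, mode = "all")
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  ns <- nrow(states)
  P <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    sigma <- states[s, ]
    f <- total_payoff(H, sigma, params)
    pflip <- vapply(seq_len(n), function(i) {
      nb <- as.integer(adj[[i]])
      if (length(nb) == 0) return(0)
      mean(ifelse(sigma[nb] != sigma[i],
                  fermi(f[nb] - f[i], params$beta), 0))
    }, numeric(1))
    for (t in seq_len(ns)) {
      tau <- states[t, ]
      P[s, t] <- prod(ifelse(tau == sigma, 1 - pflip, pflip))
    }
  }
  list(P = P, states = states)
}

# Absorption probability into the all-cooperate state from each state.
markov_absorption_allc <- function(H, params) {
  mk <- markov_transition_matrix(H, params)
  P <- mk$P
  states <- mk$states
  n <- ncol(states)
  absorbing_c <- which(rowSums(states) == n)
  absorbing_d <- which(rowSums(states) == 0)
  trans <- setdiff(seq_len(nrow(P)), c(absorbing_c, absorbing_d))
  Q <- P[trans, trans, drop = FALSE]
  R <- P[trans, absorbing_c, drop = FALSE]
  u <- solve(diag(length(trans)) - Q, rowSums(R))
  out <- numeric(nrow(P))
  out[absorbing_c] <- 1
  out[trans] <- u
  list(prob = out, states = states)
}

state_index <- function(states, sigma) {
  which(apply(states, 1, function(s) all(s == sigma)))
}

# Explicit star-of-groups configuration for the isolated-defector analysis:
# defector d with k2_d link-neighbours and k3_d triangles, one focal
# cooperator neighbour j (via a link or via kappa shared triangles) padded
# with fresh all-cooperator groups to reach its own degree pair. Everyone
# except d cooperates. Returns the hypergraph, indices of d and j, and sigma.
build_defector_config <- function(k2_d, k3_d, k2_j, k3_j, kappa = 0,
                                  via = c("link", "triangle")) {
  via <- match.arg(via)
  edges <- list()
  nxt <- 3L  # 1 = d, 2 = j
  new_v <- function(k) {
    v <- nxt:(nxt + k - 1L); nxt <<- nxt + as.integer(k); v
  }
  d <- 1L; j <- 2L
  if (via == "link") {
    stopifnot(k2_d >= 1, kappa == 0)
    edges <- c(edges, list(c(d, j)))
    for (i in seq_len(k2_d - 1)) edges <- c(edges, list(c(d, new_v(1))))
    for (i in seq_len(k3_d)) edges <- c(edges, list(c(d, new_v(1), new_v(1))))
    j_links <- k2_j - 1; j_tris <- k3_j
  } else {
    stopifnot(kappa >= 1, k3_d >= kappa)
    for (i in seq_len(kappa)) edges <- c(edges, list(c(d, j, new_v(1))))
    for (i in seq_len(k3_d - kappa)) {
      edges <- c(edges, list(c(d, new_v(1), new_v(1))))
    }
    for (i in seq_len(k2_d)) edges <- c(edges, list(c(d, new_v(1))))
    j_links <- k2_j; j_tris <- k3_j - kappa
  }
  stopifnot(j_links >= 0, j_tris >= 0)
  for (i in seq_len(j_links)) edges <- c(edges, list(c(j, new_v(1))))
  for (i in seq_len(j_tris)) edges <- c(edges, list(c(j, new_v(1), new_v(1))))
  H <- hypergraph(edges, n_vertices = nxt - 1L)
  sigma <- rep(1L, H$n); sigma[d] <- 0L
  list(H = H, d = d, j = j, sigma = sigma)
}
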