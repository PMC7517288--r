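# CSR packing of a hypergraph and its 2-section, consumed by the compiled
# simulator. 0-based indices on the C++ side.
pack_hypergraph <- function(H) {
  stopifnot(is_hypergraph(H))
  sizes <- lengths(H$edges)
  e_ptr <- c(0L, cumsum(sizes))
  e_mem <- unlist(H$edges, use.names = FALSE)
  if (is.null(e_mem)) e_mem <- integer(0)
  g <- two_section(H)
  adj <- igraph::as_adj_list(g, mode = "all")
  a_len <- lengths(adj)
  a_ptr <- c(0L, cumsum(a_len))
  a_idx <- unlist(lapply(adj, as.integer), use.names = FALSE)
  if (is.null(a_idx)) a_idx <- integer(0)
  list(n = H$n,
       e_ptr = as.integer(e_ptr), e_mem = as.integer(e_mem) - 1L,
       a_ptr = as.integer(a_ptr), a_idx = as.integer(a_idx) - 1L,
       isolated = sum(a_len == 0))
}

#' Draw an initial strategy state
#'
#' Picks, uniformly at random, `round(c0 * n)` vertices as cooperators.
#'
#' @param n number of players.
#' @param c0 initial cooperator fraction in `[0, 1]`.
#' @return binary integer vector (1 = cooperate).
#' @export
initial_state <- function(n, c0) {
  if (c0 < 0 || c0 > 1) stop("c0 must lie in [0, 1]", call. = FALSE)
  sigma <- integer(n)
  k <- round(c0 * n)
  if (k > 0) sigma[sample.int(n, k)] <- 1L
  sigma
}

#' One synchronous imitation round (reference implementation)
#'
#' Every player draws one neighbour uniformly at random in the 2-section and
#' adopts that neighbour's strategy with Fermi probability of the payoff
#' difference; all updates apply simultaneously. If the drawn neighbour plays
#' the same strategy the update is a no-op (and consumes no Fermi variate).
#' Isolated vertices keep their strategy (with a one-time warning).
#'
#' This pure-R step exists as a readable reference and oracle; long
#' trajectories should use [run_pgg()], which runs the same rule in compiled
#' code.
#'
#' @param H a [hypergraph()].
#' @param sigma binary strategy vector.
#' @param params a [game_params()].
#' @param g optional pre-computed 2-section.
#' @return the next strategy vector.
#' @export
pgg_step <- function(H, sigma, params, g = NULL) {
  if (is.null(g)) g <- two_section(H)
  f <- total_payoff(H, sigma, params)
  adj <- igraph::as_adj_list(g, mode = "all")
  if (any(lengths(adj) == 0)) {
    warning("isolated vertices present; their strategies are frozen")
  }
  new_sigma <- sigma
  for (i in seq_along(sigma)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0) next
    j <- nb[sample.int(length(nb), 1)]
    if (sigma[j] == sigma[i]) next
    if (runif(1) < fermi(f[j] - f[i], params$beta)) new_sigma[i] <- sigma[j]
  }
  new_sigma
}

#' Run the public-goods-game dynamics to absorption
#'
#' Iterates the synchronous Fermi-imitation round until the population is
#' homogeneous (cooperator density 0 or 1, the absorbing states) or `tmax`
#' rounds have elapsed. When `tmax` is hit without absorption the last density
#' is taken as the asymptotic value, following the Monte Carlo protocol.
#'
#' @param H a [hypergraph()].
#' @param params a [game_params()].
#' @param c0 initial cooperator fraction; ignored if `sigma0` is given.
#' @param sigma0 optional explicit initial binary strategy vector.
#' @param tmax maximum number of rounds (default 2e4).
#' @param record_traj keep the full density trajectory (default `TRUE`).
#' @return an object of class `pgg_run`: list with `c_final`, `t_conv`
#'   (rounds to absorption, `tmax` if not absorbed, 0 if already absorbed at
#'   t = 0), `absorbed`, `sigma`, and `c_traj` (densities at t = 0..t_end)
#'   when recorded.
#' @examples
#' H <- promote_cliques(generate_dm(60), 1)
#' res <- run_pgg(H, game_params(alpha = 2.5), c0 = 0.5, tmax = 500)
#' glance(res)
#' @export
run_pgg <- function(H, params, c0 = 0.5, sigma0 = NULL, tmax = 2e4,
                    record_traj = TRUE) {
  stopifnot(is_hypergraph(H), inherits(params, "game_params"), tmax >= 1)
  pk <- pack_hypergraph(H)
  if (pk$isolated > 0) {
    warning(sprintf("%d isolated vertices; their strategies are frozen",
                    pk$isolated))
  }
  if (is.null(sigma0)) sigma0 <- initial_state(H$n, c0)
  stopifnot(length(sigma0) == H$n, all(sigma0 %in% c(0L, 1L)))
  out <- cpp_run_pgg(pk$n, pk$e_ptr, pk$e_mem, pk$a_ptr, pk$a_idx,
                     as.integer(sigma0), params$alpha, params$b, params$beta,
                     as.integer(tmax), record_traj)
  structure(list(c_final = out$c_final, t_conv = out$t_conv,
                 absorbed = out$absorbed, sigma = out$sigma,
                 c_traj = if (record_traj) out$c_traj else NULL,
                 params = params, n = H$n, tmax = tmax),
            class = "pgg_run")
}

#' @export
print.pgg_run <- function(x, ...) {
  cat(sprintf("<pgg_run> n = %d, c_final = %.3f, %s after %d rounds\n",
              x$n, x$c_final,
              if (x$absorbed) "absorbed" else "NOT absorbed", x$t_conv))
  invisible(x)
}

#' @export
tidy.pgg_run <- function(x, ...) {
  if (is.null(x$c_traj)) {
    stop("trajectory was not recorded; rerun with record_traj = TRUE",
         call. = FALSE)
  }
  tibble::tibble(t = seq_along(x$c_traj) - 1L, c = x$c_traj)
}

#' @export
glance.pgg_run <- function(x, ...) {
  tibble::tibble(n = x$n, c_final = x$c_final, t_conv = x$t_conv,
                 absorbed = x$absorbed, alpha = x$params$alpha,
                 beta = x$params$beta, b = x$params$b, tmax = x$tmax)
}

#' @export
autoplot.pgg_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$t, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "round", y = "cooperator density c(t)") +
    ggplot2::theme_minimal()
}
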