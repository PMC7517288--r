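#' Well-mixed critical synergy of a hypergraph
#'
#' `alpha_cr = sum_m m * p_m`, the mean hyperedge cardinality, where `p_m` is
#' the fraction of hyperedges of cardinality m ([cardinality_fractions()]).
#' This is the synergy at which an infinite well-mixed population with the
#' same group-size mix transitions abruptly from full defection to full
#' cooperation.
#'
#' @param H a [hypergraph()] with at least one hyperedge.
#' @return a single numeric value.
#' @examples
#' alpha_cr(hypergraph(list(c(1, 2), c(1, 2, 3), c(2, 3, 4), c(1, 3, 4))))
#' @export
alpha_cr <- function(H) {
  cf <- cardinality_fractions(H)
  sum(cf$m * cf$p)
}

# spawn reproducible sub-seeds below 2^31 from the current RNG state
spawn_seeds <- function(k) sample.int(2147483646L, k)

#' Monte Carlo sweep of the dynamics over a synergy grid
#'
#' For each grid point and each hypergraph, runs `runs` independent
#' realizations of the dynamics (fresh random initial state each run),
#' averages the asymptotic cooperator density and the convergence time first
#' within each hypergraph and then across hypergraphs, and counts
#' non-converged runs per 100.
#'
#' The grid may be given either as synergy values `alpha_grid` or as reduced
#' values `r_grid`; in the latter case each hypergraph plays at
#' `alpha = r * alpha_cr(H)` with its own critical synergy, so `r` is directly
#' comparable across structures.
#'
#' With `stop_when_above` set, the grid is scanned in ascending order and the
#' scan halts once the across-hypergraph mean density exceeds the threshold:
#' the natural mode when only the survival onset is needed.
#'
#' @param H_list list of [hypergraph()] objects (replicate structures).
#' @param beta,b game parameters (see [game_params()]).
#' @param r_grid,alpha_grid exactly one must be given; ascending numeric grid.
#' @param runs runs per hypergraph per grid point.
#' @param c0 initial cooperator fraction.
#' @param tmax maximum rounds per run.
#' @param seed optional integer; the whole sweep is reproducible given it, and
#'   per-run seeds are pre-spawned so results do not depend on evaluation
#'   order.
#' @param stop_when_above optional density threshold for the ascending early
#'   stop.
#' @return a tibble of class `pgg_sweep` with columns `r`, `alpha`,
#'   `mean_cinf`, `mean_t`, `n_nc_per100`, `n_runs`.
#' @export
pgg_sweep <- function(H_list, beta = 1, b = 1, r_grid = NULL,
                      alpha_grid = NULL, runs = 25, c0 = 0.5, tmax = 2e4,
                      seed = NULL, stop_when_above = NULL) {
  if (is.null(r_grid) == is.null(alpha_grid)) {
    stop("give exactly one of r_grid or alpha_grid", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  use_r <- !is.null(r_grid)
  grid <- if (use_r) r_grid else alpha_grid
  if (is.unsorted(grid)) stop("grid must be ascending", call. = FALSE)
  nH <- length(H_list)
  acr <- vapply(H_list, alpha_cr, numeric(1))
  packs <- lapply(H_list, pack_hypergraph)
  n_pts <- length(grid)
  run_seeds <- array(spawn_seeds(n_pts * nH * runs), dim = c(n_pts, nH, runs))

  rows <- vector("list", n_pts)
  for (gidx in seq_len(n_pts)) {
    cinf_h <- numeric(nH); t_h <- numeric(nH); nnc <- 0L
    for (h in seq_len(nH)) {
      alpha_h <- if (use_r) grid[gidx] * acr[h] else grid[gidx]
      pk <- packs[[h]]
      cf <- numeric(runs); tt <- numeric(runs)
      for (rr in seq_len(runs)) {
        set.seed(run_seeds[gidx, h, rr])
        sigma0 <- initial_state(pk$n, c0)
        out <- cpp_run_pgg(pk$n, pk$e_ptr, pk$e_mem, pk$a_ptr, pk$a_idx,
                           sigma0, alpha_h, b, beta, as.integer(tmax), FALSE)
        cf[rr] <- out$c_final
        tt[rr] <- out$t_conv
        if (!out$absorbed) nnc <- nnc + 1L
      }
      cinf_h[h] <- mean(cf)
      t_h[h] <- mean(tt)
    }
    mean_cinf <- mean(cinf_h)
    rows[[gidx]] <- tibble::tibble(
      r = if (use_r) grid[gidx] else grid[gidx] / mean(acr),
      alpha = if (use_r) grid[gidx] * mean(acr) else grid[gidx],
      mean_cinf = mean_cinf,
      mean_t = mean(t_h),
      n_nc_per100 = 100 * nnc / (nH * runs),
      n_runs = nH * runs
    )
    if (!is.null(stop_when_above) && mean_cinf > stop_when_above) break
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pgg_sweep", class(out))
  attr(out, "beta") <- beta
  attr(out, "b") <- b
  attr(out, "c0") <- c0
  attr(out, "tmax") <- tmax
  attr(out, "alpha_cr") <- acr
  out
}

#' Full Monte Carlo experiment: generate structures, then sweep
#'
#' Implements the simulation protocol: generate `n_hypergraphs` base networks
#' of the requested model, promote a fraction `p` of their 3-cliques to
#' triangles, and run a [pgg_sweep()] over the grid, averaging within and then
#' across structures.
#'
#' @param model `"hk"`, `"dm"` or `"er"`.
#' @param n vertices of the base network.
#' @param p conversion fraction of 3-cliques to triangles.
#' @param n_hypergraphs replicate structures.
#' @param m,p_t Holme-Kim parameters (links per vertex, triad probability).
#' @param k_mean Erdos-Renyi mean degree.
#' @param seed master seed; hypergraph seeds and per-run seeds are spawned
#'   from it.
#' @inheritParams pgg_sweep
#' @return a `pgg_sweep` tibble (see [pgg_sweep()]).
#' @examples
#' \donttest{
#' sw <- mc_experiment("dm", n = 150, p = 1, r_grid = seq(0.5, 0.8, 0.05),
#'                     runs = 5, n_hypergraphs = 2, tmax = 2000, seed = 1)
#' sw
#' }
#' @export
mc_experiment <- function(model = c("hk", "dm", "er"), n = 500, p = 0,
                          beta = 1, b = 1, r_grid = NULL, alpha_grid = NULL,
                          runs = 25, n_hypergraphs = 3, c0 = 0.5, tmax = 2e4,
                          m = 3, p_t = 1, k_mean = 6, seed = NULL,
                          stop_when_above = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  hg_seeds <- spawn_seeds(n_hypergraphs)
  sweep_seed <- spawn_seeds(1)
  H_list <- lapply(hg_seeds, function(s) {
    set.seed(s)
    g <- switch(model,
                hk = generate_hk(n, m = m, p_t = p_t),
                dm = generate_dm(n),
                er = generate_er(n, k_mean = k_mean, connected = TRUE))
    promote_cliques(g, p)
  })
  pgg_sweep(H_list, beta = beta, b = b, r_grid = r_grid,
            alpha_grid = alpha_grid, runs = runs, c0 = c0, tmax = tmax,
            seed = sweep_seed, stop_when_above = stop_when_above)
}

#' Survival onset of cooperation from a sweep
#'
#' `alpha_surv` is the smallest grid synergy at which the mean asymptotic
#' cooperator density rises above `epsilon` (default half a player,
#' `1 / (2 n)`, with n taken from the sweep's run metadata when available).
#'
#' @param sweep a `pgg_sweep` tibble.
#' @param epsilon density threshold for "grows above zero".
#' @return list with `alpha_surv` and `r_surv` (both `NA` if the transition is
#'   not bracketed by the grid).
#' @export
estimate_alpha_surv <- function(sweep, epsilon) {
  idx <- which(sweep$mean_cinf > epsilon)
  if (length(idx) == 0) {
    return(list(alpha_surv = NA_real_, r_surv = NA_real_))
  }
  i <- idx[1]
  list(alpha_surv = sweep$alpha[i], r_surv = sweep$r[i])
}

#' Structural reciprocity ratio
#'
#' The ratio `alpha_surv / alpha_cr`. Values below 1 mean the structure sustains
#' cooperation below the well-mixed threshold; `r(0)` is the classical network
#' reciprocity, and decreasing `r(p)` with growing conversion fraction p means
#' group interactions reinforce it.
#'
#' @param alpha_surv survival onset synergy.
#' @param H a [hypergraph()] (or pass `acr` directly).
#' @param acr optional pre-computed critical synergy.
#' @return a single numeric value.
#' @export
reciprocity_ratio <- function(alpha_surv, H = NULL, acr = NULL) {
  if (is.null(acr)) acr <- alpha_cr(H)
  alpha_surv / acr
}

#' @export
glance.pgg_sweep <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    beta = attr(x, "beta"), b = attr(x, "b"), c0 = attr(x, "c0"),
    tmax = attr(x, "tmax"),
    alpha_cr = mean(attr(x, "alpha_cr")),
    max_nnc = max(x$n_nc_per100),
    max_mean_t = max(x$mean_t)
  )
}

#' @export
autoplot.pgg_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("r", "mean_cinf", "mean_t")],
    c("mean_cinf", "mean_t"),
    names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("mean_cinf", "mean_t"),
                          c("asymptotic density", "convergence time"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "r = alpha / alpha_cr", y = NULL) +
    ggplot2::theme_minimal()
}
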