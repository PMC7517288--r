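#' Estimate a structural-reciprocity endpoint r(p)
#'
#' The full pipeline behind one point of the r(p) curve: generate replicate
#' base networks, promote a fraction `p` of 3-cliques, sweep the reduced
#' synergy ratio `alpha / alpha_cr` upward from `r_from` until the mean
#' asymptotic cooperator density first exceeds `epsilon` (default half a
#' player, `1 / (2 n)`), and report that grid value as `r_surv`.
#'
#' @inheritParams mc_experiment
#' @param r_from,r_to,r_step ascending grid of reduced synergy values.
#' @param epsilon onset threshold on the mean density (default `1 / (2 n)`).
#' @return one-row tibble: `model`, `p`, `beta`, `r_surv`, `alpha_surv`,
#'   `alpha_cr`, `n_runs_per_point`, plus the sweep as attribute `"sweep"`.
#' @export
reciprocity_endpoint <- function(model, p, beta = 1, b = 1, n = 500,
                                 r_from = 0.5, r_to = 1.05, r_step = 0.01,
                                 runs = 25, n_hypergraphs = 3, c0 = 0.5,
                                 tmax = 5e3, m = 3, p_t = 1, k_mean = 6,
                                 epsilon = 1 / (2 * n), seed = NULL) {
  r_grid <- seq(r_from, r_to, by = r_step)
  sw <- mc_experiment(model, n = n, p = p, beta = beta, b = b,
                      r_grid = r_grid, runs = runs,
                      n_hypergraphs = n_hypergraphs, c0 = c0, tmax = tmax,
                      m = m, p_t = p_t, k_mean = k_mean, seed = seed,
                      stop_when_above = epsilon)
  est <- estimate_alpha_surv(sw, epsilon)
  out <- tibble::tibble(model = model, p = p, beta = beta,
                        r_surv = est$r_surv, alpha_surv = est$alpha_surv,
                        alpha_cr = mean(attr(sw, "alpha_cr")),
                        n_runs_per_point = runs * n_hypergraphs)
  attr(out, "sweep") <- sw
  out
}

#' Reciprocity endpoints r(0) and r(1) for a model/selection pair
#'
#' Applies [reciprocity_endpoint()] at the pure-graph (`p = 0`) and fully
#' promoted (`p = 1`) ends, the two values summarizing how much the
#' higher-order structure lowers the survival synergy. Monotone decrease of
#' r(p) in between is the structural-reciprocity gain.
#'
#' @inheritParams reciprocity_endpoint
#' @param p_values conversion fractions to evaluate (default `c(0, 1)`).
#' @return a tibble with one row per `p`.
#' @export
summarize_r_endpoints <- function(model, beta = 1, p_values = c(0, 1), ...,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- spawn_seeds(length(p_values))
  purrr::list_rbind(purrr::map2(p_values, seeds, function(p, s) {
    reciprocity_endpoint(model, p = p, beta = beta, ..., seed = s)
  }))
}

default_experiment_config <- function() {
  list(
    model = "hk", n = 500, m = 3, p_t = 1, k_mean = 6,
    p = c(0, 1), beta = 1, b = 1, c0 = 0.5,
    r_from = 0.5, r_to = 1.05, r_step = 0.01,
    runs = 100, n_hypergraphs = 10, tmax = 2e4,
    scale = 1, seed = 1, out_csv = NULL, out_provenance = NULL
  )
}

#' Run a configured sweep experiment
#'
#' Reproducible experiment driver over a config (a named list or a YAML/JSON
#' file path). The config holds generator settings, promotion fractions, game
#' parameters, the r grid, replicate counts, the cutoff and the master seed;
#' `scale` in `(0, 1]` multiplies the replicate counts (`runs`,
#' `n_hypergraphs`, with a floor of 1) for desk-scale reductions at an
#' unchanged grid. Unknown config keys are an error (catches typos before any
#' compute). Results are returned as a tibble (and optionally written as CSV),
#' together with a provenance record (config, spawned seeds, package and R
#' versions) optionally written as JSON. Reruns with the same config are
#' identical.
#'
#' @param config named list, or path to a YAML or JSON file.
#' @return tibble with one row per (p, r) point: sweep columns plus `p`;
#'   provenance record as attribute `"provenance"`.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- default_experiment_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(config)] <- config
  if (!(cfg$scale > 0 && cfg$scale <= 1)) {
    stop("scale must lie in (0, 1]", call. = FALSE)
  }
  runs <- max(1L, round(cfg$runs * cfg$scale))
  n_h <- max(1L, round(cfg$n_hypergraphs * cfg$scale))
  r_grid <- seq(cfg$r_from, cfg$r_to, by = cfg$r_step)

  set.seed(cfg$seed)
  p_seeds <- spawn_seeds(length(cfg$p))
  res <- purrr::list_rbind(purrr::map2(cfg$p, p_seeds, function(p, s) {
    sw <- mc_experiment(cfg$model, n = cfg$n, p = p, beta = cfg$beta,
                        b = cfg$b, r_grid = r_grid, runs = runs,
                        n_hypergraphs = n_h, c0 = cfg$c0, tmax = cfg$tmax,
                        m = cfg$m, p_t = cfg$p_t, k_mean = cfg$k_mean,
                        seed = s)
    dplyr::mutate(tibble::as_tibble(sw), p = p, .before = 1)
  }))

  prov <- list(config = cfg, runs_effective = runs,
               n_hypergraphs_effective = n_h, p_seeds = p_seeds,
               package_version = as.character(utils::packageVersion("hyperpgg")),
               r_version = R.version.string)
  if (!is.null(cfg$out_csv)) {
    utils::write.csv(res, cfg$out_csv, row.names = FALSE)
  }
  if (!is.null(cfg$out_provenance)) {
    jsonlite::write_json(prov, cfg$out_provenance, auto_unbox = TRUE,
                         digits = NA)
  }
  attr(res, "provenance") <- prov
  res
}
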