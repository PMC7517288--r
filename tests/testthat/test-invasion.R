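test_that("reduced hub threshold matches hand substitution and is monotone in s", {
  # bracket vanishes -> threshold at the well-mixed point
  q <- initial_q(0.5, 501)
  xi_star <- q$q0_hub / q$qbar0_d
  expect_equal(r_hub(3, xi_star, 0.5, 501), 1)
  # s = 2, N = 501, c0 = 0.5, xi = 0.5
  expect_equal(r_hub(2, 0.5, 0.5, 501), 1 / 1.2485, tolerance = 1e-10)
  # strictly decreasing in s at fixed xi, c0
  vals <- vapply(2:10, function(s) r_hub(s, 0.4, 0.5, 500), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("general hub threshold reduces to the uniform closed form", {
  for (s in 2:4) {
    ks <- 40
    xi <- 0.35
    km_hub <- setNames(ks, as.character(s))
    kbar <- setNames(xi * ks, as.character(s))
    ath <- hub_threshold(km_hub, kbar, c0 = 0.5, N = 500)
    expect_equal(ath / s, r_hub(s, xi, 0.5, 500), tolerance = 1e-12)
  }
  expect_warning(r_hub(10, 5, 0.5, 500), "no finite")
})

test_that("hub identification and the neighbourhood degree ratio behave on toys", {
  star <- hypergraph(lapply(2:8, function(v) c(1, v)))
  expect_equal(identify_hubs(star, 99), 1L)
  # regular structure: xi = 1
  ring <- hypergraph(lapply(1:6, function(i) c(i, i %% 6 + 1)))
  hubs <- identify_hubs(ring, 50)
  xs <- xi_s(ring, hubs, s = 2)
  expect_equal(xs$xi_s, 1)
})

test_that("hub invasion ratio on scale-free 3-uniform structures sits well below 1", {
  set.seed(61)
  vals <- purrr::map_dfr(1:3, function(i) {
    H <- promote_cliques(generate_hk(500, 3, 1), 1)
    dplyr::bind_rows(hub_invasion(H, 97, c0 = 0.5),
                     hub_invasion(H, 99, c0 = 0.5))
  })
  expect_true(all(vals$xi_s < 1))
  expect_true(all(vals$r_hub < 1))
  # hubs at the 99th percentile are rarer and larger than at the 97th
  expect_true(mean(vals$n_hubs[vals$percentile == 99]) <
                mean(vals$n_hubs[vals$percentile == 97]))
})

test_that("defector payoff gap matches brute-force payoffs on explicit configurations", {
  set.seed(62)
  for (rep in 1:8) {
    via <- if (rep %% 2) "link" else "triangle"
    kappa <- if (via == "link") 0 else sample(1:2, 1)
    k2_d <- sample(1:4, 1); k3_d <- max(kappa, sample(0:3, 1))
    k2_j <- sample(1:4, 1); k3_j <- max(kappa, sample(0:3, 1))
    if (via == "link") k2_j <- max(1, k2_j)
    cfg <- build_defector_config(k2_d, k3_d, k2_j, k3_j, kappa, via)
    pars <- game_params(alpha = runif(1, 1.2, 3.5), b = 1)
    f <- total_payoff(cfg$H, cfg$sigma, pars)
    scn <- defector_scenario(k2_d = k2_d, k3_d = k3_d,
                             k2_c = k2_j, k3_c = k3_j,
                             kappa_d = max(kappa, 1))
    scn$kappa_d <- kappa  # a(j) uses the actual shared-triangle count
    gap <- defector_payoff_gap(scn, pars$alpha, via = via)
    expect_equal(f[cfg$j] - f[cfg$d], gap, tolerance = 1e-10)
  }
})

test_that("defector gap limits: negative at alpha -> 0, linear slope in alpha", {
  scn <- defector_scenario(k2_d = 5, k3_d = 4, k2_c = 3, k3_c = 2,
                           kappa_d = 2)
  expect_equal(defector_payoff_gap(scn, 0, via = "link"), -(3 + 2))
  g1 <- defector_payoff_gap(scn, 1, via = "triangle")
  g2 <- defector_payoff_gap(scn, 2, via = "triangle")
  slope <- 3 - 5 / 2 + 2 - 2 * 4 / 3 - 2 / 3
  expect_equal(g2 - g1, slope)
})

test_that("survive-and-invade probability has the stated limits and channel preference", {
  scn0 <- defector_scenario(k2_d = 8, k3_d = 0, k2_c = 5, k3_c = 0,
                            kappa_d = 1, omega = 5)
  # w = 0: survival only
  gap <- defector_payoff_gap(scn0, 2, via = "link")
  expect_equal(survive_and_invade_prob(scn0, 2, beta = 1, w = 0, via = "link"),
               1 - fermi(gap, 1))
  # beta -> 0: (1/2) * (1/(2 Omega))^w
  expect_equal(survive_and_invade_prob(scn0, 2, beta = 1e-9, w = 1,
                                       via = "link"),
               0.5 / (2 * 5), tolerance = 1e-6)
  expect_error(survive_and_invade_prob(scn0, 2, beta = 1, w = 99), "w must")

  # isolated defector with |Omega(d)| = 8, kappa_d = 1.75: when its
  # neighbourhood outsizes its neighbours' (|Omega| < |Omega(d)|), playing
  # through triangles beats playing through links; and both channels lose
  # ground as the neighbours' own neighbourhoods grow
  alphas <- seq(1, 4, 0.25)
  probs <- lapply(c(5, 6, 8, 12), function(omega) {
    list(
      link = survive_and_invade_prob(
        defector_scenario(8, 0, omega, 0, kappa_d = 1.75, omega_d = 8,
                          omega = omega),
        alphas, beta = 1, w = 1, via = "link"),
      tri = survive_and_invade_prob(
        defector_scenario(0, 8 * 1.75 / 2, 0, omega * 1.75 / 2,
                          kappa_d = 1.75, omega_d = 8, omega = omega),
        alphas, beta = 1, w = 1, via = "triangle"))
  })
  for (i in 1:2) expect_true(all(probs[[i]]$tri > probs[[i]]$link))
  for (i in 1:3) {
    expect_true(all(probs[[i + 1]]$link < probs[[i]]$link))
    expect_true(all(probs[[i + 1]]$tri < probs[[i]]$tri))
  }
})

test_that("competition conditions: regular structures never qualify; band as derived", {
  reg <- defector_scenario(k2_d = 4, k3_d = 3, k2_c = 4, k3_c = 3,
                           kappa_d = 2)
  cc <- competition_conditions(reg)
  expect_false(cc$general)

  # k2_c = 4, kappa_c = kappa_d: intermediate band 5 < k2_d <= 7
  scn <- defector_scenario(k2_d = 6, k3_d = 6, k2_c = 4, k3_c = 4,
                           kappa_d = 2, kappa_c = 2)
  cc2 <- competition_conditions(scn)
  expect_equal(unname(cc2$band["lower"]), 5)
  expect_equal(unname(cc2$band["upper"]), 7)
  expect_true(cc2$p1)     # 6/4 > 3/2 - 1/4
  expect_false(cc2$p0)    # 6/4 < 2 - 1/4
  expect_true(cc2$implication)  # kappa_d/kappa_c = 1 > 3/4
  scn3 <- defector_scenario(k2_d = 6, k3_d = 6, k2_c = 4, k3_c = 4,
                            kappa_d = 1, kappa_c = 2)
  expect_false(competition_conditions(scn3)$implication)
})

test_that("kappa from clustering matches direct shared-triangle counts", {
  expect_equal(kappa_from_clustering(0, 5), 0)
  expect_equal(kappa_from_clustering(1, 3), 2)
  # corner of a K3: C = 1, k2 = 2 -> kappa = 1 shared triangle per neighbour
  g <- igraph::make_full_graph(3)
  expect_equal(kappa_from_clustering(local_clustering(g)[1], 2), 1)
  # DM networks: local clustering scales like 1/k2, so kappa is near-constant
  set.seed(63)
  gd <- generate_dm(1000)
  deg <- igraph::degree(gd)
  cc <- local_clustering(gd)
  keep <- deg >= 3 & deg <= 30
  fit <- stats::lm(log(cc[keep]) ~ log(deg[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.25)
})
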