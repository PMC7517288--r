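test_that("payoff lines and bottleneck thresholds solve the linear crossing", {
  # pairwise-only: alpha_th = 2 k2 / (k2 + nc - nc')
  for (k2 in c(3, 4, 6)) {
    for (nc in 0:2) {
      for (ncp in 0:2) {
        if (k2 + nc - ncp <= 0) next
        bt <- bottleneck_threshold(
          coop = list(km = c("2" = k2), nc_m = c("2" = nc)),
          defe = list(km = c("2" = k2), nc_m = c("2" = ncp)))
        expect_equal(bt$alpha_th, 2 * k2 / (k2 + nc - ncp))
        expect_equal(bt$status, "crossing")
      }
    }
  }
  # identical strategy environments and degrees: payoffs equal for all alpha
  same <- list(km = c("2" = 3), nc_m = c("2" = 2))
  bt2 <- bottleneck_threshold(coop = list(km = c("2" = 0, "3" = 0),
                                          nc_m = c("2" = 0, "3" = 0)),
                              defe = list(km = c("2" = 0, "3" = 0),
                                          nc_m = c("2" = 0, "3" = 0)))
  expect_equal(bt2$status, "always_equal")
  # parallel lines: same slope, different intercept
  bt3 <- bottleneck_threshold(
    coop = list(km = c("2" = 2), nc_m = c("2" = 2)),
    defe = list(km = c("2" = 4), nc_m = c("2" = 4)))
  expect_equal(bt3$status, "parallel")
  expect_error(payoff_line(1, c("2" = 2), c("2" = 5)), "exceed")
})

test_that("a bridge-vertex trap cycles between its two states inside the threshold window", {
  # bridge A with degree 8: one cooperator neighbour (degree 4, otherwise
  # surrounded by cooperators) and 7 defector neighbours. Payoff-favoured
  # imitation flips A to C when it meets the cooperator, and back to D when
  # it meets a defector -- an endless cycle for synergies inside the window.
  kA <- 8; knc <- 4
  edges <- list()
  edges <- c(edges, lapply(2:9, function(v) c(1, v)))        # A = 1, nbrs 2..9
  edges <- c(edges, lapply(10:12, function(v) c(2, v)))      # c = 2 + 3 coops
  H <- hypergraph(edges, n_vertices = 12)
  sigma_d <- c(0L, 1L, rep(0L, 7), rep(1L, 3))  # state 1: A defects
  sigma_c <- sigma_d; sigma_c[1] <- 1L          # state 2: A cooperates

  # thresholds from the payoff lines of A vs its two neighbour types
  up <- bottleneck_threshold(  # A (C, one coop neighbour) vs defector nbr
    coop = list(km = c("2" = kA), nc_m = c("2" = 1)),
    defe = list(km = c("2" = knc), nc_m = c("2" = 1)))$alpha_th
  lo <- bottleneck_threshold(  # cooperator nbr vs A (D, one coop neighbour)
    coop = list(km = c("2" = knc), nc_m = c("2" = knc - 1)),
    defe = list(km = c("2" = kA), nc_m = c("2" = 1)))$alpha_th
  expect_lt(lo, up)

  alpha <- (lo + up) / 2
  pars <- game_params(alpha, b = 1, beta = 1)
  f1 <- total_payoff(H, sigma_d, pars)
  expect_gt(f1[2], f1[1])   # cooperator beats the defecting bridge: A -> C
  f2 <- total_payoff(H, sigma_c, pars)
  expect_gt(f2[3], f2[1])   # defectors beat the cooperating bridge: A -> D

  # outside the window the cycle breaks
  f_hi <- total_payoff(H, sigma_c, game_params(up + 0.3, b = 1))
  expect_gt(f_hi[1], f_hi[3])
  f_lo <- total_payoff(H, sigma_d, game_params(max(1.01, lo - 0.3), b = 1))
  expect_gt(f_lo[1], f_lo[2])
})

test_that("bottleneck candidates are the links outside all 3-cliques", {
  set.seed(81)
  # trees: every link is a candidate
  tr <- igraph::make_tree(10, mode = "undirected")
  expect_equal(nrow(find_bottleneck_candidates(tr)), 9)
  # DM structures percolate triangles completely: no candidates
  expect_equal(nrow(find_bottleneck_candidates(generate_dm(300))), 0)
  expect_equal(nrow(find_bottleneck_candidates(generate_hk(300, 3, 1))), 0)
  # mixed case
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)), directed = FALSE)
  cand <- find_bottleneck_candidates(g)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$from, cand$to), c(3L, 4L))
})
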