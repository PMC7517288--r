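test_that("Holme-Kim graphs have the expected density and full triangle coverage", {
  set.seed(101)
  g <- generate_hk(500, m = 3, p_t = 1)
  expect_true(igraph::is_connected(g))
  expect_true(abs(mean(igraph::degree(g)) - 6) < 0.3)
  # with p_t = 1 every edge belongs to at least one 3-clique
  expect_equal(nrow(find_bottleneck_candidates(g)), 0)
})

test_that("generators are deterministic given a seed", {
  for (gen in list(function() generate_hk(80, 3, 1),
                   function() generate_dm(80),
                   function() generate_er(80, 6))) {
    set.seed(5); g1 <- gen()
    set.seed(5); g2 <- gen()
    expect_equal(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  }
})

test_that("Dorogovtsev-Mendes growth matches the by-hand small case and density", {
  set.seed(3)
  g4 <- generate_dm(4)
  expect_equal(igraph::vcount(g4), 4)
  expect_equal(igraph::ecount(g4), 5)
  expect_equal(nrow(enumerate_3cliques(g4)), 2)  # two 3-cliques share an edge

  g <- generate_dm(500)
  expect_equal(igraph::ecount(g), 3 + 2 * 497)
  expect_true(abs(mean(igraph::degree(g)) - 4) < 0.05)
  expect_equal(nrow(find_bottleneck_candidates(g)), 0)
})

test_that("full promotion of DM links m-degrees across p: k3 at p=1 is k2 at p=0 minus 1", {
  set.seed(11)
  g <- generate_dm(200)
  H <- promote_cliques(g, 1)
  expect_equal(hypergraph_rank(H), 3L)
  expect_equal(hypergraph_corank(H), 3L)
  expect_equal(m_degrees(H)$k3, unname(igraph::degree(g)) - 1L)
})

test_that("Erdos-Renyi fixes the edge count exactly", {
  set.seed(2)
  g <- generate_er(500, 6)
  expect_equal(igraph::ecount(g), 1500)
  expect_equal(igraph::ecount(generate_er(50, 0)), 0)
  expect_error(generate_er(10, 10), "k_mean")
})

test_that("3-clique enumeration lists each triangle once", {
  expect_equal(nrow(enumerate_3cliques(igraph::make_full_graph(3))), 1)
  expect_equal(nrow(enumerate_3cliques(igraph::make_tree(10, mode = "undirected"))), 0)
  cl4 <- enumerate_3cliques(igraph::make_full_graph(4))
  expect_equal(nrow(cl4), 4)
  expect_equal(nrow(unique(cl4)), 4)
})

test_that("promotion follows the selection-then-removal algorithm", {
  K3 <- igraph::make_full_graph(3)
  H <- promote_cliques(K3, 1)
  expect_equal(H$edges, list(c(1L, 2L, 3L)))

  set.seed(4)
  g <- generate_dm(50)
  H0 <- promote_cliques(g, 0)
  expect_true(all(hyperedge_sizes(H0) == 2))
  expect_equal(length(H0$edges), igraph::ecount(g))

  K4 <- igraph::make_full_graph(4)
  H4 <- promote_cliques(K4, 1)
  expect_equal(sort(hyperedge_sizes(H4)), rep(3L, 4))
  expect_equal(igraph::ecount(two_section(H4)), 6)
  expect_error(promote_cliques(K4, 1.2), "p must")
})

test_that("promotion output is simple and its 2-section returns the base graph", {
  set.seed(9)
  sorted_el <- function(gg) {
    e <- igraph::as_edgelist(gg, names = FALSE)
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  for (rep in 1:6) {
    g <- switch(1 + rep %% 3,
                generate_hk(60, 3, 1), generate_dm(60), generate_er(60, 6))
    p <- runif(1)
    H <- promote_cliques(g, p)
    expect_true(validate_simple(H)$ok)
    expect_equal(sorted_el(two_section(H)), sorted_el(g))
  }
})

test_that("surviving 2-edges are non-increasing in the conversion fraction", {
  set.seed(12)
  g <- generate_dm(80)
  n2 <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    mean(vapply(1:5, function(i) sum(hyperedge_sizes(
      promote_cliques(g, p)) == 2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(n2) <= 0))
  expect_equal(n2[5], 0)  # DM: complete triangle percolation
})
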