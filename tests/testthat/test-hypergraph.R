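test_that("simplicity validation finds exactly the containment violations", {
  expect_false(validate_simple(hypergraph(list(c(1, 2), c(1, 2, 3))))$ok)
  v <- validate_simple(hypergraph(list(c(1, 2), c(1, 2, 3))))
  expect_equal(nrow(v$violations), 1)
  expect_equal(v$violations$inner, 1)

  expect_true(validate_simple(hypergraph(list(c(1, 2, 3), c(3, 4, 5))))$ok)
  # all C(4,3) triples of a K4 promotion: pairwise non-nested
  expect_true(validate_simple(hypergraph(
    list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))))$ok)
  # duplicates are violations too
  expect_false(validate_simple(hypergraph(list(c(1, 2), c(2, 1))))$ok)
})

test_that("malformed hyperedges are rejected at construction", {
  expect_error(hypergraph(list(c(1, 1, 2))), "repeated")
  expect_error(hypergraph(list(5), n_vertices = 5), "cardinality")
  expect_error(hypergraph(list(c(1, 9)), n_vertices = 3), "outside")
})

test_that("simplification removes nested hyperedges and is idempotent", {
  H <- simplify_hypergraph(hypergraph(list(c(1, 2), c(1, 2, 3))))
  expect_equal(H$edges, list(c(1L, 2L, 3L)))

  H2 <- hypergraph(list(c(1, 2), c(2, 3), c(1, 3), c(1, 2, 3)))
  expect_equal(simplify_hypergraph(H2)$edges, list(c(1L, 2L, 3L)))

  H3 <- hypergraph(list(c(1, 2, 3), c(3, 4)))
  expect_equal(simplify_hypergraph(H3)$edges, H3$edges)
  s1 <- simplify_hypergraph(H2)
  expect_equal(simplify_hypergraph(s1)$edges, s1$edges)
  expect_true(validate_simple(s1)$ok)
})

test_that("2-section links exactly the pairs sharing a hyperedge", {
  el <- function(g) {
    e <- igraph::as_edgelist(g, names = FALSE)
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  g <- two_section(hypergraph(list(c(1, 2, 3))))
  expect_equal(el(g), rbind(c(1, 2), c(1, 3), c(2, 3)))

  g2 <- two_section(hypergraph(list(c(1, 2), c(1, 2, 3))))
  expect_equal(el(g2), rbind(c(1, 2), c(1, 3), c(2, 3)))

  # fully promoted K4: 2-section is K4 again
  K4tris <- hypergraph(list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  expect_equal(igraph::ecount(two_section(K4tris)), 6)
  expect_equal(igraph::vcount(two_section(K4tris)), 4)
})

test_that("m-degrees count incidences per cardinality and sum correctly", {
  H <- hypergraph(list(c(1, 2), c(1, 3, 4)))
  md <- m_degrees(H)
  expect_equal(md$k2[1], 1L)
  expect_equal(md$k3[1], 1L)
  expect_equal(md$k[1], 2L)

  H2 <- hypergraph(list(c(1, 2)), n_vertices = 3)  # vertex 3 isolated
  expect_equal(m_degrees(H2)$k[3], 0L)

  # complete 3-uniform on N = 4: each vertex in C(3,2) = 3 triples
  expect_true(all(m_degrees(hypergraph(
    list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))))$k3 == 3))
})

test_that("column sums of m-degrees equal m times the hyperedge counts", {
  set.seed(42)
  for (rep in 1:5) {
    g <- generate_dm(60)
    H <- promote_cliques(g, runif(1))
    md <- m_degrees(H)
    cf <- cardinality_fractions(H)
    for (i in seq_len(nrow(cf))) {
      m <- cf$m[i]
      expect_equal(sum(md[[paste0("k", m)]]), m * cf$count[i])
    }
  }
})

test_that("cardinality fractions are normalized counts", {
  H <- hypergraph(c(lapply(1:10, function(i) c(i, i + 10)),
                    lapply(1:10, function(i) c(i, i + 20, i + 30))))
  cf <- cardinality_fractions(H)
  expect_equal(cf$p, c(0.5, 0.5))

  expect_equal(cardinality_fractions(hypergraph(list(c(1, 2))))$p, 1)
  cf3 <- cardinality_fractions(hypergraph(
    list(c(1, 2), c(2, 3), c(3, 4), c(1, 2, 5))))
  expect_equal(cf3$p, c(0.75, 0.25))
  expect_error(cardinality_fractions(hypergraph(list(), n_vertices = 3)),
               "no hyperedges")
})

test_that("local clustering follows the Watts-Strogatz definition, 0 for low degree", {
  expect_equal(local_clustering(igraph::make_full_graph(3)), rep(1, 3))
  star <- igraph::make_star(5, mode = "undirected")
  cc <- local_clustering(star)
  expect_equal(cc[1], 0)      # hub: no edges among leaves
  expect_equal(cc[2], 0)      # leaves: degree 1, convention 0 not NaN
  # vertex with 3 neighbours, 2 edges among them -> 2/3
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(3, 4)), directed = FALSE)
  expect_equal(local_clustering(g)[1], 2 / 3)
})
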