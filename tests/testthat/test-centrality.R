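path_graph <- function() {
  list(nodes = c("a", "b", "c"),
       edges = data.frame(from = c("a", "b"), to = c("b", "c")))
}

star_graph <- function() {
  list(nodes = c("hub", "x", "y", "z"),
       edges = data.frame(from = "hub", to = c("x", "y", "z")))
}

test_that("worked examples: degree, closeness, eccentricity, radiality", {
  tri <- list(nodes = c("a", "b", "c"),
              edges = data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c")))
  expect_equal(unname(degree_centrality(tri)), c(2, 2, 2))
  st <- star_graph()
  expect_equal(degree_centrality(st)[["hub"]], 3)
  expect_equal(unname(degree_centrality(st)[c("x", "y", "z")]), rep(1, 3))
  iso <- list(nodes = c("a", "b", "solo"),
              edges = data.frame(from = "a", to = "b"))
  expect_equal(degree_centrality(iso)[["solo"]], 0)

  p <- path_graph()
  expect_equal(closeness_centrality(p)[["b"]], 2)
  expect_equal(closeness_centrality(p)[["a"]], 1.5)
  two_edges <- list(nodes = c("a", "b", "c", "d"),
                    edges = data.frame(from = c("a", "c"),
                                       to = c("b", "d")))
  expect_equal(unname(closeness_centrality(two_edges)), rep(1, 4))

  expect_equal(eccentricity_centrality(p)[["b"]], 1)
  expect_equal(eccentricity_centrality(p)[["a"]], 0.5)
  k4 <- list(nodes = letters[1:4],
             edges = data.frame(from = c("a", "a", "a", "b", "b", "c"),
                                to = c("b", "c", "d", "c", "d", "d")))
  expect_equal(unname(eccentricity_centrality(k4)), rep(1, 4))

  expect_equal(unname(radiality_centrality(tri)), rep(1, 3))
  expect_equal(radiality_centrality(p)[["b"]], 2)
  expect_equal(radiality_centrality(p)[["a"]], 1.5)
  expect_equal(unname(radiality_centrality(k4)), rep(1, 4))
})

test_that("worked examples: betweenness and MCC", {
  st <- star_graph()
  bw <- betweenness_centrality(st)
  expect_equal(bw[["hub"]], 3)
  expect_equal(unname(bw[c("x", "y", "z")]), rep(0, 3))
  tri <- list(nodes = c("a", "b", "c"),
              edges = data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c")))
  expect_equal(unname(betweenness_centrality(tri)), rep(0, 3))

  k4 <- list(nodes = letters[1:4],
             edges = data.frame(from = c("a", "a", "a", "b", "b", "c"),
                                to = c("b", "c", "d", "c", "d", "d")))
  expect_equal(unname(mcc_centrality(k4)), rep(6, 4))
  p <- path_graph()
  expect_equal(mcc_centrality(p)[["b"]], 2)
  expect_equal(mcc_centrality(p)[["a"]], 1)
})

test_that("EPC limits are exact and the single-edge expectation is met", {
  p <- path_graph()
  e1 <- epc_centrality(p, n_realizations = 5, p_keep = 1, seed = 1)
  expect_equal(unname(e1), c(2, 2, 2))
  e0 <- epc_centrality(p, n_realizations = 5, p_keep = 0, seed = 1)
  expect_equal(unname(e0), c(0, 0, 0))
  edge <- list(nodes = c("u", "v"),
               edges = data.frame(from = "u", to = "v"))
  e <- epc_centrality(edge, n_realizations = 1000, p_keep = 0.5, seed = 42)
  expect_lt(max(abs(e - 0.5)), 0.05)
})

test_that("all seven algorithms match brute-force oracles on random graphs", {
  set.seed(2024)
  n_graphs <- 60
  for (i in seq_len(n_graphs)) {
    g <- random_graph(sample(4:8, 1))
    A <- graph_adjmat(g)
    expect_equal(unname(degree_centrality(g)), unname(oracle_degree(A)))
    expect_equal(unname(closeness_centrality(g)), oracle_closeness(A),
                 tolerance = 1e-12)
    expect_equal(unname(eccentricity_centrality(g)),
                 oracle_eccentricity(A), tolerance = 1e-12)
    expect_equal(unname(radiality_centrality(g)), oracle_radiality(A),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(A),
                 tolerance = 1e-9)
    expect_equal(unname(mcc_centrality(g)), oracle_mcc(A))
  }
})

test_that("EPC agrees with the exact edge-subset expectation", {
  set.seed(99)
  for (i in 1:8) {
    g <- random_graph(sample(4:6, 1), max_m = 8L)
    exact <- oracle_epc_exact(g, 0.5)
    est <- epc_centrality(g, n_realizations = 1000, p_keep = 0.5,
                          seed = 1000 + i)
    tol <- 3 * sqrt(exact$var / 1000) + 1e-9
    expect_true(all(abs(est - exact$mean) <= tol))
  }
})

test_that("centralities agree with the igraph reference where definitions coincide", {
  skip_if_not_installed("igraph")
  set.seed(555)
  for (i in 1:10) {
    g <- random_graph(sample(5:8, 1))
    if (nrow(g$edges) == 0L) next
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes)
    expect_equal(unname(degree_centrality(g)),
                 unname(igraph::degree(ig)))
    expect_equal(unname(betweenness_centrality(g)),
                 unname(igraph::betweenness(ig)), tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(g)),
                 unname(igraph::harmonic_centrality(ig)),
                 tolerance = 1e-9)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(77)
  algos <- list(degree_centrality, closeness_centrality,
                eccentricity_centrality, radiality_centrality,
                betweenness_centrality, mcc_centrality)
  for (i in 1:10) {
    g <- random_graph(6)
    perm <- sample(g$nodes)
    relabel <- setNames(sprintf("r%02d", seq_along(perm)), perm)
    g2 <- list(nodes = unname(relabel[g$nodes]),
               edges = data.frame(from = unname(relabel[g$edges$from]),
                                  to = unname(relabel[g$edges$to])))
    for (f in algos) {
      s1 <- f(g)
      s2 <- f(g2)
      expect_equal(unname(s2[relabel[names(s1)]]), unname(s1),
                   tolerance = 1e-12)
    }
  }
})
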