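# Fixtures: paths, stars, cliques, and the worked examples whose values were
# derived by hand or by the enumeration oracles in helper-oracles.R.

path_graph <- function(n, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  connectome(m)
}
star_graph <- function(leaves) {
  m <- matrix(0, leaves + 1, leaves + 1)
  m[1, -1] <- m[-1, 1] <- 1
  connectome(m)
}
complete_graph <- function(n, w = 1) connectome(matrix(w, n, n) - diag(w, n))

test_that("density, strength and efficiency match hand-derived values", {
  expect_equal(net_density(complete_graph(4)), 1)
  expect_equal(net_density(connectome(matrix(0, 84, 84))), 0)
  expect_equal(net_density(path_graph(4)), 0.5)
  expect_error(net_density(connectome(matrix(0, 1, 1))), "2 nodes")

  expect_equal(avg_strength(complete_graph(3)), 2)
  two <- matrix(0, 2, 2); two[1, 2] <- two[2, 1] <- 5
  expect_equal(avg_strength(connectome(two)), 5)
  expect_equal(avg_strength(complete_graph(4, 0.5)), 1.5)

  expect_equal(global_efficiency(complete_graph(5)), 1)
  expect_equal(global_efficiency(connectome(matrix(0, 2, 2))), 0)
  expect_equal(global_efficiency(path_graph(3)), mean(c(1, 1, 0.5)))
})

test_that("characteristic path length and edge count follow the geodesics", {
  expect_equal(char_path_and_edge_count(complete_graph(4)),
               c(char_path_length = 1, edge_count = 1))
  expect_equal(char_path_and_edge_count(path_graph(3)),
               c(char_path_length = 4 / 3, edge_count = 4 / 3))
  # P4 hop counts {1,1,1,2,2,3}
  expect_equal(char_path_and_edge_count(path_graph(4))[["edge_count"]], 10 / 6)
  # disconnected graph: only finite pairs counted; fully empty is undefined
  expect_true(all(is.na(char_path_and_edge_count(connectome(matrix(0, 3, 3))))))
})

test_that("clustering and local efficiency match triangle enumeration", {
  expect_equal(avg_clustering(complete_graph(3)), 1)
  expect_equal(avg_clustering(path_graph(5)), 0)  # trees have no triangles
  k4 <- matrix(1, 4, 4) - diag(4); k4[1, 2] <- k4[2, 1] <- 0.5
  expect_equal(avg_clustering(connectome(k4)), oracle_clustering(k4),
               tolerance = 1e-12)

  expect_equal(avg_local_efficiency(complete_graph(3)), 1)
  expect_equal(avg_local_efficiency(star_graph(4)), 0)
  expect_equal(avg_local_efficiency(path_graph(3)), 0)
})

test_that("betweenness and assortativity match hand-derived values", {
  expect_equal(avg_betweenness(path_graph(3)), 1 / 3)
  expect_equal(avg_betweenness(complete_graph(5)), 0)
  # star with 4 leaves: center carries all C(4,2)=6 leaf pairs
  expect_equal(avg_betweenness(star_graph(4)) * 5, 6)

  expect_equal(assortativity_binary(path_graph(4)), -0.5)
  expect_equal(assortativity_binary(star_graph(4)), -1)
  ring <- matrix(0, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  expect_true(is.na(assortativity_binary(connectome(ring))))  # regular
})

test_that("modularity follows its defining formula and Q bounds", {
  two_tri <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    two_tri[e[1], e[2]] <- two_tri[e[2], e[1]] <- 1
  }
  ml <- modularity_louvain(connectome(two_tri), seed = 5)
  expect_equal(ml$modularity, 0.5)
  expect_equal(ml$partition$n_communities, 2)
  # Q of the trivial one-community partition is 0
  expect_equal(siteharm:::modularity_value(two_tri, rep(1, 6)), 0)
  # returned Q always equals direct evaluation on the returned partition
  set.seed(9)
  for (i in 1:10) {
    w <- random_graph(8, 0.5, 3)
    if (sum(w) == 0) next
    ml <- modularity_louvain(connectome(w), seed = i)
    expect_equal(ml$modularity,
                 siteharm:::modularity_value(w, ml$partition$assignment),
                 tolerance = 1e-12)
    expect_true(ml$modularity >= -1 && ml$modularity <= 1)
    # and matches the independent igraph modularity implementation
    g <- igraph::graph_from_adjacency_matrix(w, "undirected", weighted = TRUE)
    expect_equal(ml$modularity,
                 igraph::modularity(g, ml$partition$assignment,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
  expect_true(is.na(modularity_louvain(connectome(matrix(0, 4, 4)))$modularity))
})

test_that("participation coefficient reflects intermodular diversity", {
  tri <- complete_graph(3)
  expect_equal(avg_participation(tri, list(assignment = c(1, 1, 1))), 0)
  # node 1 splits its strength equally across two modules: P = 1 - 2*(1/2)^2
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 1
  p <- avg_participation(connectome(m), list(assignment = c(1, 1, 2)))
  # node 1: 0.5; node 2: inside own module 0; node 3: all into module 1 -> P=0
  expect_equal(p, mean(c(0.5, 0, 0)))
})

test_that("rich club curve follows the BCT convention", {
  rc <- rich_club(complete_graph(6))
  expect_equal(as.numeric(rc), 1)
  expect_true(all(attr(rc, "curve")[!is.na(attr(rc, "curve"))] == 1))

  # no node of degree > 1: undefined
  expect_true(is.na(rich_club(path_graph(2))))

  # 5-node fixture: K3 {1,2,3} plus pendants 4-1, 5-2; oracle by hand:
  # degrees (3,3,2,1,1); k=1: subgraph {1,2,3}, E=3, W=3, top-3 weights sum 3
  # -> phi(1)=1; k=2: subgraph {1,2}, E=1, W=1 -> phi(2)=1; k=3: empty.
  w <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 1), c(5, 2))) {
    w[e[1], e[2]] <- w[e[2], e[1]] <- 1
  }
  rc5 <- rich_club(connectome(w))
  expect_equal(as.numeric(rc5), 1)
  # weighted variant: downweight one K3 edge; top-E weights now exclude it
  w[1, 2] <- w[2, 1] <- 0.5
  rc5w <- rich_club(connectome(w))
  curve <- attr(rc5w, "curve")
  expect_equal(unname(curve["1"]), 2.5 / 3)    # W=2.5 over top-3 = {1,1,1}
  expect_equal(unname(curve["2"]), 0.5 / 1)    # edge 1-2 vs single best weight
  expect_equal(as.numeric(rc5w), mean(c(2.5 / 3, 0.5)))
})

test_that("all measures agree with enumeration oracles on random graphs", {
  set.seed(2024)
  checked <- 0
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    w <- random_graph(n, runif(1, 0.3, 0.8), 3)
    if (sum(w) == 0) next
    cn <- connectome(w)
    expect_equal(global_efficiency(cn), oracle_global_efficiency(w),
                 tolerance = 1e-9)
    expect_equal(unname(char_path_and_edge_count(cn)), oracle_char_path(w),
                 tolerance = 1e-9)
    expect_equal(avg_betweenness(cn), mean(oracle_betweenness(w)),
                 tolerance = 1e-9)
    expect_equal(avg_clustering(cn), oracle_clustering(w), tolerance = 1e-9)
    expect_equal(avg_local_efficiency(cn), oracle_local_efficiency(w),
                 tolerance = 1e-9)
    expect_equal(assortativity_binary(cn), oracle_assortativity(w),
                 tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})

test_that("measures are invariant to node permutation and scale correctly", {
  set.seed(77)
  for (rep in 1:5) {
    w <- random_graph(7, 0.6, 5)
    if (sum(w) == 0) next
    cn <- connectome(w)
    perm <- sample(7)
    cp <- connectome(w[perm, perm])
    m1 <- all_measures(cn, seed = 4)
    m2 <- all_measures(cp, seed = 4)
    expect_equal(m1, m2, tolerance = 1e-9)

    # uniform weight scaling: strength linear; normalized measures unchanged
    cs <- connectome(w * 3.7)
    expect_equal(avg_strength(cs), 3.7 * avg_strength(cn), tolerance = 1e-12)
    expect_equal(net_density(cs), net_density(cn))
    expect_equal(avg_clustering(cs), avg_clustering(cn), tolerance = 1e-12)
    expect_equal(global_efficiency(cs), global_efficiency(cn),
                 tolerance = 1e-12)
    expect_equal(assortativity_binary(cs), assortativity_binary(cn))
  }
})

test_that("all_measures is deterministic and handles degenerate graphs", {
  set.seed(123)
  w <- random_graph(10, 0.4, 6)
  cn <- connectome(w)
  m1 <- all_measures(cn, seed = 7)
  m2 <- all_measures(cn, seed = 7)
  expect_identical(m1, m2)
  expect_named(m1, measure_names())

  empty <- all_measures(connectome(matrix(0, 5, 5)))
  expect_equal(unname(empty["density"]), 0)
  expect_equal(unname(empty["avg_strength"]), 0)
  expect_true(all(is.na(empty[c("modularity", "char_path_length",
                                "edge_count", "rich_club")])))

  k4 <- complete_graph(4)
  mk <- all_measures(k4)
  expect_equal(unname(mk[c("density", "global_efficiency",
                           "char_path_length", "avg_clustering")]),
               c(1, 1, 1, 1))
})

test_that("measures_table returns the documented schema", {
  gcfg <- tiny_generator(n_per_site = 3)
  gen <- generate_cohort(gcfg)
  tab <- measures_table(gen$cohort)
  expect_equal(names(tab), c("subject_id", "site", measure_names()))
  expect_equal(nrow(tab), 6)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_measures_tsv(tab, p)
  back <- read.delim(p)
  expect_equal(back$subject_id, tab$subject_id)
})
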