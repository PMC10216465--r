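test_that("complete and path graphs hit their closed-form values", {
  k4 <- as_net(k_graph(4), binary = TRUE)
  expect_equal(clustering_coefficient(k4)$Cp, 1)
  expect_equal(characteristic_path_length(k4)$Lp, 1)
  eff <- efficiencies(k4)
  expect_equal(eff$Eg, 1)
  expect_equal(eff$Eloc, 1)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  expect_equal(unname(degree_centrality(k4)), rep(3, 4))

  abc <- as_net(path_graph(3), binary = TRUE)
  d <- shortest_path_lengths(abc)
  expect_equal(d[1, 2], 1)
  expect_equal(d[2, 3], 1)
  expect_equal(d[1, 3], 2)
  expect_equal(characteristic_path_length(abc)$Lp, 4 / 3)
  expect_equal(clustering_coefficient(abc)$Cp, 0)
})

test_that("star graphs isolate the hub's role", {
  star <- as_net(star_graph(3), binary = TRUE)
  bc <- betweenness_centrality(star)
  expect_equal(unname(bc), c(3, 0, 0, 0)) # C(3,2) leaf pairs through the hub
  expect_equal(clustering_coefficient(star)$Cp, 0)
  ne <- efficiencies(star)$Ne_i
  expect_equal(unname(ne[1]), 1)
  expect_equal(unname(ne[2]), (1 + 1 / 2 + 1 / 2) / 3)
})

test_that("one triangle plus a pendant matches the triangle-enumeration oracle", {
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1 # triangle 1-2-3
  a[3, 4] <- 1 # pendant chain
  a[4, 5] <- 1
  a <- a + t(a)
  net <- as_net(a, binary = TRUE)
  cc <- clustering_coefficient(net)
  expect_equal(unname(cc$C_i), oracle_clustering(a, binary = TRUE))
  expect_equal(cc$Cp, mean(oracle_clustering(a, binary = TRUE)))
})

test_that("weighted degree sums incident weights", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.9
  a[1, 3] <- a[3, 1] <- 0.8
  net <- as_net(a, binary = FALSE)
  expect_equal(unname(degree_centrality(net)), c(1.7, 0.9, 0.8))
  expect_equal(unname(degree_centrality(as_net((a > 0) + 0, TRUE))), c(2, 1, 1))
})

test_that("all metrics agree with enumeration oracles on random graphs", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    weighted <- i %% 2 == 0
    a <- random_test_graph(n, p = runif(1, 0.35, 0.8), weighted = weighted)
    net <- as_net(a, binary = !weighted)
    tol <- if (weighted) 1e-9 else 1e-12
    expect_equal(unname(shortest_path_lengths(net)), oracle_distances(a, !weighted),
      tolerance = tol
    )
    expect_equal(unname(clustering_coefficient(net)$C_i), oracle_clustering(a, !weighted),
      tolerance = tol
    )
    expect_equal(characteristic_path_length(net)$Lp, oracle_lp(a, !weighted),
      tolerance = tol
    )
    eff <- efficiencies(net)
    expect_equal(unname(eff$Ne_i), oracle_nodal_efficiency(a, !weighted), tolerance = tol)
    expect_equal(unname(eff$Eloc_i), oracle_local_efficiency(a, !weighted), tolerance = tol)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(a, !weighted),
      tolerance = 1e-6
    )
    expect_equal(unname(degree_centrality(net)), rowSums(a), tolerance = tol)
  }
})

test_that("local efficiency equals global efficiency of the neighbour subgraph", {
  set.seed(123)
  a <- random_test_graph(8, p = 0.5, weighted = FALSE)
  net <- as_net(a, binary = TRUE)
  eloc <- efficiencies(net)$Eloc_i
  for (i in 1:8) {
    nb <- which(a[i, ] > 0)
    expected <- if (length(nb) < 2) 0 else {
      efficiencies(as_net(a[nb, nb, drop = FALSE], binary = TRUE))$Eg
    }
    expect_equal(unname(eloc[i]), expected)
  }
})

test_that("metrics are permutation-equivariant under node relabelling", {
  set.seed(31)
  a <- random_test_graph(7, p = 0.5, weighted = TRUE)
  perm <- sample(7)
  ap <- a[perm, perm]
  net <- as_net(a, binary = FALSE)
  netp <- as_net(ap, binary = FALSE)
  expect_equal(
    unname(clustering_coefficient(netp)$C_i),
    unname(clustering_coefficient(net)$C_i[perm])
  )
  expect_equal(
    unname(betweenness_centrality(netp)),
    unname(betweenness_centrality(net)[perm]),
    tolerance = 1e-9
  )
  expect_equal(
    unname(efficiencies(netp)$Ne_i),
    unname(efficiencies(net)$Ne_i[perm])
  )
  expect_equal(global_metrics(netp, n_random = 0), global_metrics(net, n_random = 0))
})

test_that("adding an edge never worsens integration", {
  set.seed(44)
  for (i in 1:10) {
    a <- random_test_graph(7, p = 0.4, weighted = FALSE)
    absent <- which(upper.tri(a) & a == 0)
    if (length(absent) == 0) next
    a2 <- a
    a2[absent[1]] <- 1
    a2 <- pmax(a2, t(a2))
    n1 <- as_net(a, TRUE)
    n2 <- as_net(a2, TRUE)
    expect_lte(characteristic_path_length(n2)$Lp, characteristic_path_length(n1)$Lp)
    expect_gte(efficiencies(n2)$Eg, efficiencies(n1)$Eg)
  }
})

test_that("an edgeless graph has no characteristic path length", {
  net <- as_net(matrix(0, 4, 4), binary = TRUE)
  expect_error(characteristic_path_length(net), "no finite paths")
  d <- shortest_path_lengths(net)
  expect_true(all(is.infinite(d[row(d) != col(d)])))
  expect_equal(unname(diag(d)), rep(0, 4))
})
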