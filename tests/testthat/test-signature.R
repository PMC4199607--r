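test_that("signatures of small named graphs match the dense eigen oracle", {
  cases <- list(
    list(g = k2(), values = c(1, 1) / sqrt(2), lambda = 1),
    list(g = k3(), values = rep(1 / sqrt(3), 3), lambda = 2),
    list(g = p3(), values = c(sqrt(2) / 2, 0.5, 0.5), lambda = sqrt(2)),
    list(g = star4(), values = c(1 / sqrt(2), rep(1 / sqrt(6), 3)), lambda = sqrt(3))
  )
  for (cs in cases) {
    sig <- pf_vector(cs$g)
    expect_equal(sig$values, cs$values, tolerance = 1e-8)
    expect_equal(sig$eigenvalue, cs$lambda, tolerance = 1e-8)
    orc <- eigen_oracle(cs$g)
    expect_equal(sig$values, orc$values, tolerance = 1e-8)
    expect_equal(sig$eigenvalue, orc$lambda, tolerance = 1e-8)
  }
  # P3's centre node takes rank 1
  expect_equal(pf_vector(p3())$order[1L], 2L)
})

test_that("signature invariants hold on random graphs", {
  for (seed in 1:25) {
    n <- 5L + (seed %% 20L)
    g <- rand_connected(n, 0.35, seed)
    sig <- pf_vector(g)
    expect_true(all(diff(sig$values) <= 1e-12))
    expect_true(all(sig$values >= 0))
    expect_equal(sum(sig$values^2), 1, tolerance = 1e-9)
    # residual ||A u - lambda u|| on the unsorted vector
    u <- numeric(n)
    u[sig$order] <- sig$values
    a <- adjacency_matrix(g)
    expect_lt(sqrt(sum((a %*% u - sig$eigenvalue * u)^2)), 1e-8)
    # oracle agreement
    expect_equal(sig$values, eigen_oracle(g)$values, tolerance = 1e-7)
  }
})

test_that("bipartite and disconnected graphs are handled", {
  # even cycle (bipartite): plain iteration on A would oscillate
  c6 <- evsa_graph(cbind(1:6, c(2:6, 1)))
  sig <- pf_vector(c6)
  expect_equal(sig$values, rep(1 / sqrt(6), 6), tolerance = 1e-8)
  expect_equal(sig$eigenvalue, 2, tolerance = 1e-8)

  # dominant component wins; the rest decays to zero
  g <- evsa_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)))
  sig <- pf_vector(g)
  u <- numeric(5)
  u[sig$order] <- sig$values
  expect_lt(max(u[4:5]), 1e-6)
  expect_equal(sig$eigenvalue, 2, tolerance = 1e-6)

  # tied spectral radii: reproducible mixture with a warning
  two_k2 <- evsa_graph(rbind(c(1, 2), c(3, 4)))
  expect_warning(sig <- pf_vector(two_k2), "tied")
  expect_equal(sig$values, rep(0.5, 4), tolerance = 1e-8)

  expect_error(pf_vector(evsa_graph(matrix(integer(0), ncol = 2), n_nodes = 3L)),
               "no edges")
  expect_error(pf_vector(evsa_graph(matrix(integer(0), ncol = 2), n_nodes = 1L)),
               "2 nodes")
})

test_that("evsd/evsa match hand-computed values and bounds", {
  s_k3 <- pf_vector(k3())
  s_p3 <- pf_vector(p3())
  expect_equal(evsd(s_k3, s_k3), 0)
  expect_equal(evsa(s_k3, s_k3), 1)
  # frozen from the closed-form vectors above:
  # ||(.57735,.57735,.57735)-(.70711,.5,.5)|| / sqrt(2)
  expect_equal(evsd(s_k3, s_p3), 0.120006, tolerance = 1e-5)
  expect_equal(evsa(s_k3, s_p3), 0.879994, tolerance = 1e-5)

  # unequal sizes: shorter signature zero-padded
  s_k2 <- pf_vector(k2())
  d <- evsd(s_k2, s_p3)
  byhand <- sqrt(sum((c(1 / sqrt(2), 1 / sqrt(2), 0) - c(sqrt(2) / 2, .5, .5))^2)) / sqrt(2)
  expect_equal(d, byhand, tolerance = 1e-8)

  for (seed in 1:10) {
    g1 <- rand_connected(4L + seed %% 5L, 0.5, seed)
    g2 <- rand_connected(6L + seed %% 4L, 0.5, seed + 100L)
    d <- network_evsd(g1, g2)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(network_evsa(g1, g2), 1 - d)
  }
})

test_that("signatures are invariant under graph isomorphism", {
  for (seed in 1:20) {
    n <- 6L + (seed %% 10L)
    g <- rand_connected(n, 0.4, seed)
    sigma <- evsa:::with_seed(seed + 500L, sample.int(n))
    h <- permute_graph(g, sigma)
    expect_lt(network_evsd(g, h), 1e-8)
    expect_equal(network_evsa(g, h), 1, tolerance = 1e-8)
  }
})

test_that("alignment pairs ranks and satisfies the inner-product identity", {
  al <- align_networks(k3(), k3())
  expect_equal(al$objective, 1, tolerance = 1e-10)

  al <- align_networks(k3(), p3())
  # 0.57735 * (0.70711 + 0.5 + 0.5), rank 1 of P3 is its centre
  expect_equal(al$objective, 0.985599, tolerance = 1e-5)
  expect_equal(al$mapping$node2[1L], 2L)
  expect_equal(nrow(al$mapping), 3L)

  # relabeled copy: objective 1, mapping recovers the permutation up to ties
  sigma <- c(3L, 1L, 4L, 2L, 5L)
  g <- rand_connected(5, 0.6, 7)
  al <- align_networks(g, permute_graph(g, sigma))
  expect_equal(al$objective, 1, tolerance = 1e-8)

  # <s1,s2> = 1 - ||s1 - s2||^2 / 2 for unit vectors (padded)
  for (seed in 1:10) {
    g1 <- rand_connected(5L + seed %% 4L, 0.5, seed + 30L)
    g2 <- rand_connected(5L + (seed + 2L) %% 4L, 0.5, seed + 60L)
    al <- align_networks(g1, g2)
    expect_equal(al$objective, 1 - (sqrt(2) * al$evsd)^2 / 2, tolerance = 1e-12)
  }
})
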