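test_that("entropy and mutual information match hand-computable cases", {
  expect_equal(joint_entropy(c("A", "A", "A"), c("X", "X", "X")), 0)
  expect_equal(joint_entropy(c("A", "A", "B", "B"), c("X", "Y", "X", "Y")),
               log(4))
  expect_equal(mutual_information(c("A", "A", "B", "B"), c("X", "X", "Y", "Y")),
               log(2))
  expect_equal(mutual_information(c("A", "A", "B", "B"), c("X", "Y", "X", "Y")),
               0)
  expect_error(joint_entropy(c("A", "B"), c("X")), "differ")
  expect_error(mutual_information(c("A", "B"), c("X")), "differ")
})

test_that("finite-size correction follows the occupied-cell closed form", {
  # fully occupied 2x2 joint at T = 4: (4 - 2 - 2 + 1) / 8
  expect_equal(finite_size_correction(c("A", "A", "B", "B"),
                                      c("X", "Y", "X", "Y")), 0.125)
  expect_equal(finite_size_correction(rep("A", 10), rep("X", 10)), 0)
  # never negative (floored)
  expect_gte(finite_size_correction(c("A", "B", "C"), c("X", "Y", "Z")), 0)
})

test_that("normalized MI saturates for identical columns, vanishes for independent", {
  set.seed(101)
  col <- random_column(10000, 3)
  expect_equal(normalized_mi(col, col)$illn, 1)
  r <- normalized_mi(random_column(10000, 3), random_column(10000, 3))
  expect_lt(r$illn, 0.02)
  expect_equal(normalized_mi(rep("A", 50), rep("X", 50))$illn, 0)
  # symmetry
  a <- random_column(200, 4); b <- random_column(200, 4)
  expect_equal(normalized_mi(a, b)$illn, normalized_mi(b, a)$illn)
})

test_that("illn matrix is symmetric, consistent with pairwise calls, diagonal-ruled", {
  ch <- gen_coupled_state_chain(n_fragments = 6, chain = 1:4, n_frames = 150,
                                seed = 3)
  L <- ch$alignment$letters
  M <- illn_matrix(ch$alignment)
  expect_true(isSymmetric(unname(M)))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(M[i, j], normalized_mi(L[, i], L[, j])$illn)
  expect_true(all(diag(M) == 1))
  # constant column gets a zero diagonal and zero coupling
  L2 <- cbind(L, rep("A", nrow(L)))
  al2 <- string_alignment(data.frame(fragment = 1:7, chain = "A"), L2)
  M2 <- illn_matrix(al2)
  expect_equal(unname(diag(M2)[7]), 0)
  expect_true(all(M2[7, -7] == 0))
})

test_that("network gating reproduces the fraction-of-max operating point", {
  # a maximum off-diagonal I_LLn of 0.403 with mi_frac 0.33 puts the
  # cutoff at 0.133
  illn <- diag(3)
  illn[1, 2] <- illn[2, 1] <- 0.403
  illn[1, 3] <- illn[3, 1] <- 0.14
  illn[2, 3] <- illn[3, 2] <- 0.12
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  net <- build_network(illn, coords)
  expect_equal(net$mi_cut, 0.33 * 0.403)
  expect_equal(sort(paste(net$edges$i, net$edges$j)), c("1 2", "1 3"))
  # distance gate: high-MI pair beyond 30 A gets no edge
  coords2 <- rbind(c(0, 0, 0), c(31, 0, 0), c(0, 10, 0))
  net2 <- build_network(illn, coords2)
  expect_false(any(net2$edges$i == "1" & net2$edges$j == "2"))
})

test_that("network edges equal a brute-force double-loop filter", {
  set.seed(104)
  n <- 12
  illn <- matrix(0, n, n)
  illn[upper.tri(illn)] <- runif(n * (n - 1) / 2)
  illn <- illn + t(illn); diag(illn) <- 1
  coords <- matrix(runif(n * 3, 0, 40), n, 3)
  for (mi_frac in c(0.2, 0.33, 0.6)) {
    net <- build_network(illn, coords, d_cut = 30, mi_frac = mi_frac)
    mi_cut <- mi_frac * max(illn[upper.tri(illn)])
    want <- character()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= 30 && illn[i, j] >= mi_cut) want <- c(want, paste(i, j))
    }
    expect_setequal(paste(net$edges$i, net$edges$j), want)
  }
  # monotone in mi_frac: raising the cutoff never adds edges
  e1 <- build_network(illn, coords, mi_frac = 0.3)$edges
  e2 <- build_network(illn, coords, mi_frac = 0.5)$edges
  expect_true(all(paste(e2$i, e2$j) %in% paste(e1$i, e1$j)))
})

test_that("all-zero coupling yields a valid flagged empty network", {
  illn <- diag(0, 4)
  coords <- matrix(runif(12, 0, 5), 4, 3)
  net <- build_network(illn, coords)
  expect_true(net$empty)
  expect_equal(nrow(net$edges), 0L)
  p <- shortest_allosteric_path(net, "1", "4")
  expect_true(p$no_path)
})

test_that("shortest paths honor weights, sites, and tie-breaks", {
  W <- matrix(NA_real_, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.2; W[2, 3] <- W[3, 2] <- 0.2
  net <- network_from_weights(W)
  p <- shortest_allosteric_path(net, "1", "3")
  expect_equal(p$fragments, c("1", "2", "3"))
  expect_equal(p$total_weight, 0.4)
  expect_equal(p$edge_illn, c(0.8, 0.8))

  # disconnected sites
  W2 <- matrix(NA_real_, 4, 4); W2[1, 2] <- W2[2, 1] <- 0.2
  p2 <- shortest_allosteric_path(network_from_weights(W2), "1", c("3", "4"))
  expect_true(p2$no_path)

  expect_error(shortest_allosteric_path(net, "1", "9"), "9")

  # equal-weight alternatives resolve to the lexicographically smallest
  W3 <- matrix(NA_real_, 4, 4)
  W3[1, 3] <- W3[3, 1] <- 0.2; W3[3, 4] <- W3[4, 3] <- 0.2
  W3[1, 2] <- W3[2, 1] <- 0.2; W3[2, 4] <- W3[4, 2] <- 0.2
  p3 <- shortest_allosteric_path(network_from_weights(W3), "1", "4")
  expect_equal(p3$fragments, c("1", "2", "4"))
})

test_that("removing an optimal-path edge never shortens the path", {
  set.seed(105)
  for (rep in 1:20) {
    W <- random_graph(7, 0.5)
    net <- network_from_weights(W)
    p <- shortest_allosteric_path(net, "1", "7")
    if (p$no_path) next
    for (k in seq_len(length(p$fragments) - 1)) {
      Wc <- W
      i <- as.integer(p$fragments[k]); j <- as.integer(p$fragments[k + 1])
      Wc[i, j] <- Wc[j, i] <- NA
      pc <- shortest_allosteric_path(network_from_weights(Wc), "1", "7")
      expect_true(pc$no_path || pc$total_weight >= p$total_weight - 1e-12)
    }
  }
})

test_that("centrality matches analytic cases and flags top nodes", {
  # star: center dominates
  W <- matrix(NA_real_, 5, 5)
  for (j in 2:5) { W[1, j] <- W[j, 1] <- 0.4 }
  cs <- eigenvector_centrality(network_from_weights(W))
  expect_equal(cs$score[1], 1)
  expect_true(all(cs$score[-1] < 1))
  expect_equal(cs$score[-1], rep(cs$score[2], 4))

  # even cycle (bipartite): equal scores, all 1 after normalization
  W2 <- matrix(NA_real_, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; W2[i, j] <- W2[j, i] <- 0.4 }
  cs2 <- eigenvector_centrality(network_from_weights(W2))
  expect_equal(cs2$score, rep(1, 6), tolerance = 1e-8)

  net_empty <- build_network(diag(0, 3), matrix(0, 3, 3))
  expect_error(eigenvector_centrality(net_empty), "no edges")
})

test_that("global motion states are deterministic, balanced, and track motion", {
  # monotone translation along x -> monotone state sequence
  n_fr <- 60; n_at <- 5
  co <- array(0, c(n_fr, n_at, 3))
  base <- matrix(rnorm(n_at * 3), n_at, 3)
  for (f in seq_len(n_fr)) co[f, , ] <- base + c(f * 0.5, 0, 0)
  tr <- trajectory(co, toy_topology(n_at))
  gs <- global_motion_states(tr, n_states = 6)
  expect_true(all(diff(as.integer(gs)) >= 0) || all(diff(as.integer(gs)) <= 0))
  expect_equal(as.integer(gs[1]), 1L)  # first frame projects negative
  # equal-frequency binning
  expect_true(all(abs(table(as.integer(gs)) - n_fr / 6) <= 1))

  # two well-separated clusters, n_states = 2 -> states equal cluster labels
  set.seed(106)
  lab <- rep(c(1L, 2L), each = 30)
  co2 <- array(rnorm(60 * n_at * 3, 0, 0.05), c(60, n_at, 3))
  for (f in 1:60) co2[f, , 1] <- co2[f, , 1] + ifelse(lab[f] == 1, 0, 8)
  tr2 <- trajectory(co2, toy_topology(n_at))
  gs2 <- as.integer(global_motion_states(tr2, 2))
  expect_true(identical(gs2, lab) || identical(gs2, 3L - lab))

  expect_error(global_motion_states(trajectory(array(0, c(30, 4, 3)) + 1,
                                               toy_topology(4)), 5),
               "static")
})

test_that("local-global coupling uses the identical I_LLn estimator", {
  ch <- gen_coupled_state_chain(n_fragments = 5, chain = 1:3, n_frames = 300,
                                seed = 9)
  gs <- structure(as.integer(factor(ch$alignment$letters[, 1])),
                  class = "global_state_series")
  tab <- ilgn(ch$alignment, gs)
  # fragment 1 IS the global series: maximal coupling
  expect_equal(which.max(tab$ilgn), 1L)
  expect_equal(tab$ilgn[1],
               normalized_mi(ch$alignment$letters[, 1], as.integer(gs))$illn)
  expect_error(ilgn(ch$alignment, gs[-1]), "mismatch")
})
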