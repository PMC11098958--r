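test_that("planted chain generator honors its coupling contract", {
  # gamma = 1: downstream chain columns copy the root exactly
  ch1 <- gen_coupled_state_chain(n_fragments = 8, chain = 1:4, gamma = 1,
                                 n_frames = 100, seed = 4)
  L <- ch1$alignment$letters
  expect_equal(L[, 2], L[, 1]); expect_equal(L[, 4], L[, 3])
  M <- illn_matrix(ch1$alignment)
  for (k in 1:3) expect_equal(M[k, k + 1], max(M[upper.tri(M)]))

  # gamma = 0: all columns independent; corrected coupling near zero
  ch0 <- gen_coupled_state_chain(n_fragments = 8, chain = 1:4, gamma = 0,
                                 n_frames = 400, seed = 5)
  M0 <- illn_matrix(ch0$alignment)
  expect_lt(mean(M0[upper.tri(M0)]), 0.02)
})

test_that("chain geometry gates second-neighbor shortcuts, keeps neighbors", {
  ch <- gen_coupled_state_chain(seed = 6)
  co <- ch$coords
  idx <- as.integer(ch$chain)
  d1 <- sqrt(rowSums((co[idx[-1], ] - co[idx[-length(idx)], ])^2))
  expect_true(all(d1 <= 30))
  d2 <- sqrt(rowSums((co[idx[-(1:2)], ] - co[idx[1:(length(idx) - 2)], ])^2))
  expect_true(all(d2 > 30))
})

test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(gen_coupled_state_chain(seed = 11)$alignment$letters,
                   gen_coupled_state_chain(seed = 11)$alignment$letters)
  a <- gen_two_state_polymer(n_frames = 30, seed = 12)
  b <- gen_two_state_polymer(n_frames = 30, seed = 12)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$labels, b$labels)
  expect_identical(gen_decay(data.frame(amplitude = 1, tau_ns = 3),
                             1e5, seed = 13)$histogram$counts,
                   gen_decay(data.frame(amplitude = 1, tau_ns = 3),
                             1e5, seed = 13)$histogram$counts)
  p <- data.frame(condition = "c", start = 10, end = 18, n = 1, k = 1e-6)
  expect_identical(gen_titration(p, seed = 14)$data,
                   gen_titration(p, seed = 14)$data)
  # and the global RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_coupled_state_chain(n_frames = 10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("jitter-free polymer sits exactly at the two target distances", {
  pg <- gen_two_state_polymer(jitter_sd = 0, n_frames = 60, seed = 15)
  ds <- pair_distance_series(pg$trajectory, pg$probe[1], pg$probe[2])
  vals <- sort(unique(round(ds$values, 6)))
  expect_equal(vals, c(15, 20), tolerance = 1e-6)
  expect_equal(ds$values[pg$labels == 1], rep(15, sum(pg$labels == 1)),
               tolerance = 1e-6)
})

test_that("polymer switching follows the requested Markov kinetics", {
  pg <- gen_two_state_polymer(switch_prob = c(0.08, 0.16), n_frames = 4000,
                              seed = 16)
  p_open <- mean(pg$labels == 2)
  stat <- 0.08 / (0.08 + 0.16)     # stationary open fraction
  rho <- 1 - 0.08 - 0.16           # lag-1 autocorrelation of the chain
  se <- sqrt(stat * (1 - stat) / 4000 * (1 + rho) / (1 - rho))
  expect_lt(abs(p_open - stat), 4 * se)
})

test_that("decay generator matches its Poisson contract", {
  comp <- data.frame(amplitude = c(0.6, 0.4), tau_ns = c(3.5, 1.5))
  totals <- vapply(1:100, function(s)
    sum(gen_decay(comp, 1e5, seed = s)$histogram$counts), numeric(1))
  expect_lt(abs(mean(totals) / 1e5 - 1), 0.01)
  # large-photon limit approaches the analytic curve
  g <- gen_decay(comp, 1e8, seed = 17)
  t <- g$histogram$time_ns
  mu <- colSums(comp$amplitude * exp(-outer(1 / comp$tau_ns, t)))
  mu <- mu / sum(mu)
  expect_lt(max(abs(g$histogram$counts / 1e8 - mu)), 5e-5)
  expect_warning(gen_decay(data.frame(amplitude = 1, tau_ns = 30),
                           1e4, window_ns = 50), "window")
})

test_that("titration generator is exact at zero noise", {
  p <- data.frame(condition = c("a", "b"), start = c(10, 12),
                  end = c(18, 18), n = c(1.2, 1.2), k = c(1e-6, 3e-7))
  tt <- gen_titration(p, noise_sd = 0, replicates = 2, seed = 18)
  for (i in 1:2) {
    sub <- tt$data[tt$data$condition == p$condition[i], ]
    expect_equal(sub$fret_percent,
                 hill_curve(sub$ca_free_molar, p$start[i], p$end[i],
                            p$n[i], p$k[i]), tolerance = 1e-12)
  }
})

test_that("fixture writer emits readable files plus a truth sidecar", {
  dir <- withr::local_tempdir()
  ch <- gen_coupled_state_chain(n_fragments = 6, chain = 1:3, n_frames = 25,
                                seed = 19)
  paths <- write_fixture(ch, dir, "chain")
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(file.path(dir, "chain_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$spec$seed, 19)
  expect_equal(as.character(truth$chain), c("1", "2", "3"))
  al <- read_alignment(file.path(dir, "chain_strings.txt"))
  expect_equal(al$letters, ch$alignment$letters)
})
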