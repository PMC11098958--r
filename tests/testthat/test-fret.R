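test_that("decay fitting recovers a noiseless single exponential exactly", {
  t <- (seq_len(3125) - 0.5) * 16 / 1000
  mu <- exp(-t / 3.52); mu <- mu / sum(mu) * 2e6
  h <- decay_histogram(mu, 16)    # noiseless, non-integer counts are fine
  f1 <- fit_decay(h, n_components = 1)
  expect_equal(f1$components$tau_ns, 3.52, tolerance = 1e-6)
  f2 <- fit_decay(h, n_components = 2)
  expect_equal(f2$tau_amp, 3.52, tolerance = 1e-4)
  expect_error(fit_decay(decay_histogram(rep(0, 100), 16)), "photons")
})

test_that("decay histogram IO round-trips through two-column text", {
  g <- gen_decay(data.frame(amplitude = 1, tau_ns = 2), 5e4, seed = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_decay(g$histogram, f)
  back <- read_decay(f)
  expect_equal(back$counts, g$histogram$counts)
  expect_equal(back$bin_width_ps, 16)
})

test_that("amplitude-weighted lifetime follows its definition", {
  expect_equal(amplitude_weighted_lifetime(
    data.frame(amplitude = c(0.5, 0.5), tau_ns = c(2, 4))), 3)
  expect_equal(amplitude_weighted_lifetime(
    data.frame(amplitude = 7, tau_ns = 1.23)), 1.23)
  set.seed(51)
  a <- runif(3); tau <- runif(3, 1, 5)
  expect_equal(amplitude_weighted_lifetime(
    data.frame(amplitude = a, tau_ns = tau)), sum(a * tau) / sum(a))
  expect_error(amplitude_weighted_lifetime(
    data.frame(amplitude = c(0, 0), tau_ns = c(1, 2))), "zero")
})

test_that("FRET efficiency analytic cases and the low-Ca inversion", {
  expect_equal(fret_efficiency(3.52, 3.52), 0)
  expect_equal(fret_efficiency(1.76, 3.52), 50)
  # donor lifetime implied by a 13.6% efficiency at tau_D = 3.52 ns
  expect_equal(fret_efficiency(3.0413, 3.52), 13.6, tolerance = 1e-2)
  expect_warning(fret_efficiency(3.6, 3.52), "negative")
  expect_error(fret_efficiency(1, 0), "positive")
})

test_that("Hill curve has the defining plateau/midpoint/monotonicity structure", {
  expect_equal(hill_curve(0, 10, 20, 1.7, 1e-6), 10)
  for (n in c(0.5, 1, 2.5))
    expect_equal(hill_curve(1e-6, 10, 20, n, 1e-6), 15)
  x <- 10^seq(-9, -3, 0.25)
  y <- hill_curve(x, 10, 20, 1.3, 5e-7)
  expect_true(all(diff(y) > 0))
  expect_equal(hill_curve(x, 10, 20, 1, 5e-7),
               10 + 10 * x / (5e-7 + x), tolerance = 1e-12)
})

test_that("global Hill fit recovers noiseless parameters and nests correctly", {
  pars <- data.frame(condition = "one", start = 12, end = 19, n = 1.4,
                     k = 6e-7)
  tt <- gen_titration(pars, noise_sd = 0, replicates = 2, seed = 1)
  fit <- fit_hill_global(tt$data)
  expect_equal(fit$n, 1.4, tolerance = 1e-5)
  expect_equal(fit$conditions$k, 6e-7, tolerance = 1e-5)
  expect_equal(fit$conditions$start, 12, tolerance = 1e-5)
  expect_equal(fit$conditions$end, 19, tolerance = 1e-5)

  # a single condition: shared-n fit and free-n fit coincide
  pars2 <- data.frame(condition = "one", start = 12, end = 19, n = 1.1, k = 6e-7)
  tt2 <- gen_titration(pars2, noise_sd = 0.4, replicates = 3, seed = 2)
  fs <- fit_hill_global(tt2$data, shared_n = TRUE)
  ff <- fit_hill_global(tt2$data, shared_n = FALSE)
  expect_equal(fs$loss, ff$loss, tolerance = 1e-6)

  expect_error(fit_hill_global(data.frame(condition = "c", ca_free_molar = 1:3,
                                          fret_percent = 1:3)),
               "fewer than 5")
})

test_that("normalization maps the fitted span onto [0, 1] reversibly", {
  expect_equal(normalize_curve(13.6, 18, 13.6), 0)
  expect_equal(normalize_curve(13.6, 18, 18), 1)
  expect_equal(normalize_curve(10, 20, hill_curve(2e-6, 10, 20, 1, 2e-6)), 0.5)
  y <- runif(5, 10, 20)
  expect_equal(normalize_curve(10, 20, y) * 10 + 10, y, tolerance = 1e-12)
  expect_error(normalize_curve(5, 5, 1), "undefined")
})

test_that("K_Ca comparison matches independent statistics", {
  g_same <- list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1))
  expect_equal(compare_kca(g_same)$f_statistic, 0, tolerance = 1e-12)

  # two groups: F = t^2 of the pooled t statistic
  set.seed(61)
  g2 <- list(a = rnorm(6, 1), b = rnorm(5, 1.5))
  cmp <- compare_kca(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(cmp$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-10)
  # single pair: Sidak with m = 1 leaves p unchanged
  expect_equal(cmp$pairwise$p_sidak, cmp$pairwise$p_raw)

  # three groups against a closed-form one-way ANOVA oracle
  g3 <- list(a = rnorm(5, 0), b = rnorm(6, 0.8), c = rnorm(4, -0.5))
  cmp3 <- compare_kca(g3)
  ns <- lengths(g3); mus <- vapply(g3, mean, 0); gm <- mean(unlist(g3))
  ssb <- sum(ns * (mus - gm)^2); k <- 3; N <- sum(ns)
  ssw <- sum(vapply(g3, function(v) sum((v - mean(v))^2), 0))
  f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(cmp3$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(cmp3$p_value, pf(f_oracle, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(cmp3$pairwise$p_sidak, 1 - (1 - cmp3$pairwise$p_raw)^3,
               tolerance = 1e-12)
  expect_error(compare_kca(list(a = 1:3)), "2 groups")
  expect_error(compare_kca(list(a = 1:3, b = 2)), "replicates")
})
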