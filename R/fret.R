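# TCSPC decay fitting, FRET efficiencies, Hill titration fitting (global
# shared cooperativity), and K_Ca group comparison.

#' Construct a TCSPC decay histogram
#'
#' @param counts Non-negative integer photon counts per time bin.
#' @param bin_width_ps Bin width in picoseconds (default 16).
#' @return An object of class `"decay_histogram"` with `counts`,
#'   `bin_width_ps` and `time_ns` (bin-center times in ns).
#' @export
decay_histogram <- function(counts, bin_width_ps = 16) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (bin_width_ps <= 0) stop("bin width must be positive")
  counts <- as.numeric(counts)
  time_ns <- (seq_along(counts) - 0.5) * bin_width_ps / 1000
  structure(list(counts = counts, bin_width_ps = bin_width_ps,
                 time_ns = time_ns), class = "decay_histogram")
}

#' Read / write a decay histogram as two-column text
#'
#' Columns: time (ps) and photon counts, whitespace- or comma-delimited.
#'
#' @param path File path.
#' @return `read_decay()`: a `"decay_histogram"`.
#' @export
read_decay <- function(path) {
  if (!file.exists(path)) stop("decay file not found: ", path)
  d <- utils::read.table(path, header = FALSE, sep = "",
                         col.names = c("time_ps", "counts"))
  if (nrow(d) < 2L) stop("decay file too short: ", path)
  bw <- stats::median(diff(d$time_ps))
  decay_histogram(d$counts, bin_width_ps = bw)
}

#' @rdname read_decay
#' @param histogram A `"decay_histogram"`.
#' @return `write_decay()`: `path`, invisibly.
#' @export
write_decay <- function(histogram, path) {
  utils::write.table(
    data.frame(time_ps = histogram$time_ns * 1000, counts = histogram$counts),
    path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fit a multi-exponential decay to a TCSPC histogram
#'
#' Tail fit of `sum_k a_k exp(-t / tau_k)` starting at the histogram peak
#' bin (or an explicit bin), with Poisson weighting (`1 / max(counts, 1)`).
#' No instrument-response deconvolution is performed; with nanosecond
#' lifetimes and 16 ps binning, tail fitting is adequate. Components are
#' returned ordered by descending lifetime. The fit is deterministic given
#' the data: starting values are derived from log-linear regression on the
#' tail.
#'
#' @param histogram A `"decay_histogram"` with at least 50 bins after the
#'   fit start and at least 1000 total counts.
#' @param n_components 1 or 2 exponential components.
#' @param fit_start `"peak"` (default) or an explicit bin index.
#' @return An object of class `"lifetime_fit"`: `components` (data.frame
#'   `amplitude`, `tau_ns`), `tau_amp` (amplitude-weighted mean lifetime,
#'   ns), `chisq_red`, `fit_start_bin`, `flags`.
#' @export
fit_decay <- function(histogram, n_components = 2, fit_start = "peak") {
  stopifnot(inherits(histogram, "decay_histogram"))
  if (!n_components %in% c(1, 2)) stop("n_components must be 1 or 2")
  if (sum(histogram$counts) < 1000) stop("too few photons (< 1000 counts)")
  start_bin <- if (identical(fit_start, "peak"))
    which.max(histogram$counts) else as.integer(fit_start)
  t <- histogram$time_ns[start_bin:length(histogram$counts)] -
       histogram$time_ns[start_bin]
  y <- histogram$counts[start_bin:length(histogram$counts)]
  if (length(y) < 50L) stop("fewer than 50 bins after fit start")
  # Poisson weighting: start from observed-count weights, then re-weight by
  # the fitted model (IRLS); model-based weights avoid the low-count bias of
  # weighting by observed counts.
  w <- 1 / pmax(y, 1)

  # log-linear slope of the late tail for the long lifetime start value
  pos <- which(y > 0)
  late <- pos[pos > length(y) * 0.3]
  if (length(late) < 10L) late <- pos
  sl <- stats::lm.fit(cbind(1, t[late]), log(y[late]))$coefficients
  tau_long0 <- max(0.05, -1 / sl[2])
  a0 <- max(y[1], 1)

  model <- function(par) {
    k <- n_components
    a <- exp(par[seq_len(k)]); tau <- exp(par[k + seq_len(k)])
    colSums(a * exp(-outer(1 / tau, t)))
  }
  resid_fn <- function(par) (model(par) - y) * sqrt(w)
  p0 <- if (n_components == 1L) c(log(a0), log(tau_long0)) else
    c(log(a0 * 0.6), log(a0 * 0.4), log(tau_long0), log(tau_long0 / 3))
  fit <- NULL
  for (irls in 1:4) {
    fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
    mu <- model(fit$par)
    w_new <- 1 / pmax(mu, 1)
    if (max(abs(w_new - w) / w) < 1e-8) { w <- w_new; break }
    w <- w_new
    p0 <- fit$par
  }
  if (fit$info == 0)
    stop("decay fit did not converge (residual ", signif(fit$deviance, 6), ")")
  k <- n_components
  a <- exp(fit$par[seq_len(k)]); tau <- exp(fit$par[k + seq_len(k)])
  ord <- order(tau, decreasing = TRUE)
  a <- a[ord]; tau <- tau[ord]
  flags <- character()
  window_ns <- max(histogram$time_ns)
  if (any(tau > 3 * window_ns)) flags <- c(flags, "tau_at_upper_bound")
  if (any(tau < histogram$bin_width_ps / 1000)) flags <- c(flags, "tau_below_bin")
  structure(list(
    components = data.frame(amplitude = a, tau_ns = tau),
    tau_amp = sum(a * tau) / sum(a),
    chisq_red = fit$deviance / (length(y) - length(fit$par)),
    fit_start_bin = start_bin, flags = flags),
    class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("Lifetime fit:", nrow(x$components), "component(s)\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  a = %.4g, tau = %.4f ns\n",
                x$components$amplitude[i], x$components$tau_ns[i]))
  cat(sprintf("  amplitude-weighted tau = %.4f ns (reduced chi^2 %.3f)\n",
              x$tau_amp, x$chisq_red))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' `sum(a_k tau_k) / sum(a_k)`, the donor lifetime summary used for FRET
#' efficiency when the decay is multi-exponential.
#'
#' @param components Data.frame with columns `amplitude`, `tau_ns` (or a
#'   `"lifetime_fit"`).
#' @return Lifetime in ns.
#' @export
amplitude_weighted_lifetime <- function(components) {
  if (inherits(components, "lifetime_fit")) components <- components$components
  a <- components$amplitude; tau <- components$tau_ns
  if (any(a < 0)) stop("amplitudes must be non-negative")
  if (sum(a) <= 0) stop("all amplitudes are zero")
  sum(a * tau) / sum(a)
}

#' FRET efficiency from donor lifetime quenching
#'
#' `E = 100 * (1 - tau_DA / tau_D)` percent, where `tau_DA` is the
#' (amplitude-weighted) donor lifetime in the presence of acceptor and
#' `tau_D` the donor-only lifetime. Values slightly below 0 (tau_DA >
#' tau_D) are reported as-is with a warning.
#'
#' @param tau_da Donor-acceptor lifetime, ns.
#' @param tau_d Donor-only lifetime, ns (must be positive).
#' @return Efficiency in percent.
#' @export
fret_efficiency <- function(tau_da, tau_d) {
  if (tau_d <= 0) stop("tau_D must be positive")
  if (any(tau_da > tau_d)) warning("tau_DA exceeds tau_D; negative FRET reported")
  100 * (1 - tau_da / tau_d)
}

#' Hill dose-response curve
#'
#' `y = START + (END - START) * x^n / (K^n + x^n)`: `START` is the response
#' at zero ligand, `END` the response at saturation, `n` the Hill
#' (cooperativity) coefficient and `K` the ligand concentration at
#' half-maximal response (e.g. K_Ca for a Ca2+ titration).
#'
#' @param x Ligand concentration(s), same units as `k` (>= 0).
#' @param start,end Response at zero / saturating ligand (e.g. FRET %).
#' @param n Hill coefficient (> 0).
#' @param k Half-maximal constant (> 0).
#' @return Response value(s).
#' @export
hill_curve <- function(x, start, end, n, k) {
  if (k <= 0) stop("K must be positive")
  if (n <= 0) stop("Hill coefficient must be positive")
  if (any(x < 0)) stop("concentrations must be non-negative")
  xn <- (x / k)^n
  start + (end - start) * xn / (1 + xn)
}

#' Global Hill fit with a shared cooperativity coefficient
#'
#' Fits all conditions of a titration simultaneously by least squares, with
#' one shared Hill coefficient `n` and independent `START`, `END` and `K`
#' per condition. `K` is parameterized on the log10 scale; bounds are
#' `n` in \[0.3, 5\] and `K` in \[1 nM, 1 mM\]. Five multi-start repeats
#' (deterministic, seeded) guard against local minima; per-parameter
#' standard errors come from the curvature (Jacobian) at the optimum.
#'
#' @param data Data.frame with columns `condition`, `ca_free_molar`,
#'   `fret_percent` (a `replicate` column is allowed and ignored by the
#'   fit: all points enter with equal weight).
#' @param shared_n Fit one shared Hill coefficient (default TRUE); with
#'   FALSE each condition gets its own `n` (used e.g. for nested-model
#'   comparison).
#' @param n_starts Number of multi-start repeats (default 5).
#' @param seed Seed for the deterministic start jitter (default 1).
#' @return An object of class `"hill_global_fit"`: `n` (shared coefficient,
#'   with `n_se`), `conditions` (data.frame with START/END/K estimates and
#'   standard errors), `loss` (residual sum of squares), `residuals`,
#'   `flags`.
#' @export
fit_hill_global <- function(data, shared_n = TRUE, n_starts = 5, seed = 1) {
  req <- c("condition", "ca_free_molar", "fret_percent")
  if (!all(req %in% names(data))) stop("data needs columns: ",
                                       paste(req, collapse = ", "))
  conds <- unique(as.character(data$condition))
  nc <- length(conds)
  x <- data$ca_free_molar; y <- data$fret_percent
  ci <- match(as.character(data$condition), conds)
  for (cc in seq_len(nc)) {
    if (length(unique(x[ci == cc])) < 5L)
      stop("condition '", conds[cc], "' has fewer than 5 distinct concentrations")
  }
  # parameter vector: [n (1 or nc)] + per condition (start, end, log10K)
  nn <- if (shared_n) 1L else nc
  unpack <- function(p) {
    list(n = p[seq_len(nn)],
         start = p[nn + 3 * (seq_len(nc) - 1) + 1],
         end = p[nn + 3 * (seq_len(nc) - 1) + 2],
         lk = p[nn + 3 * (seq_len(nc) - 1) + 3])
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    n_c <- if (shared_n) rep(q$n, nc) else q$n
    k <- 10^q$lk
    xn <- (x / k[ci])^n_c[ci]
    yy <- q$start[ci] + (q$end[ci] - q$start[ci]) * xn / (1 + xn)
    yy - y
  }
  # data-driven starts
  s0 <- e0 <- k0 <- numeric(nc)
  for (cc in seq_len(nc)) {
    xs <- x[ci == cc]; ys <- y[ci == cc]
    s0[cc] <- mean(ys[xs <= stats::quantile(xs, 0.2)])
    e0[cc] <- mean(ys[xs >= stats::quantile(xs, 0.8)])
    half <- (s0[cc] + e0[cc]) / 2
    k0[cc] <- xs[which.min(abs(ys - half))]
  }
  lower <- c(rep(0.3, nn), rep(c(-100, -100, -9), nc))
  upper <- c(rep(5, nn), rep(c(200, 200, -3), nc))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    jit_n <- if (s == 1) 0 else stats::runif(nn, -0.3, 0.3)
    jit_k <- if (s == 1) 0 else stats::runif(nc, -0.5, 0.5)
    p0 <- c(pmin(5, pmax(0.3, rep(1, nn) + jit_n)),
            as.vector(rbind(s0, e0, pmin(-3, pmax(-9, log10(k0) + jit_k)))))
    ft <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(ft) || ft$info == 0) next
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  if (is.null(best)) stop("global Hill fit failed to converge from all starts")
  q <- unpack(best$par)
  dof <- max(1L, length(y) - length(best$par))
  sigma2 <- best$deviance / dof
  covm <- tryCatch(solve(best$hessian) * sigma2, error = function(e)
    matrix(NA_real_, length(best$par), length(best$par)))
  se <- sqrt(pmax(0, diag(covm)))
  k_hat <- 10^q$lk
  k_se <- k_hat * log(10) * se[nn + 3 * (seq_len(nc) - 1) + 3]
  flags <- character()
  if (any(abs(q$lk - (-9)) < 1e-6 | abs(q$lk - (-3)) < 1e-6))
    flags <- c(flags, "K_at_bound")
  if (any(abs(q$n - 0.3) < 1e-6 | abs(q$n - 5) < 1e-6))
    flags <- c(flags, "n_at_bound")
  structure(list(
    n = if (shared_n) q$n else stats::setNames(q$n, conds),
    n_se = if (shared_n) se[1] else stats::setNames(se[seq_len(nn)], conds),
    conditions = data.frame(
      condition = conds, start = q$start, end = q$end, k = k_hat,
      start_se = se[nn + 3 * (seq_len(nc) - 1) + 1],
      end_se = se[nn + 3 * (seq_len(nc) - 1) + 2],
      k_se = k_se, stringsAsFactors = FALSE),
    loss = best$deviance,
    residuals = resid_fn(best$par),
    shared_n = shared_n, flags = flags),
    class = "hill_global_fit")
}

#' @export
print.hill_global_fit <- function(x, ...) {
  if (x$shared_n)
    cat(sprintf("Global Hill fit: shared n = %.3f +/- %.3f\n", x$n, x$n_se))
  else cat("Hill fit with per-condition n\n")
  for (i in seq_len(nrow(x$conditions)))
    cat(sprintf("  %-16s START %.2f  END %.2f  K %.4g M (+/- %.2g)\n",
                x$conditions$condition[i], x$conditions$start[i],
                x$conditions$end[i], x$conditions$k[i], x$conditions$k_se[i]))
  cat(sprintf("  residual sum of squares %.4g\n", x$loss))
  invisible(x)
}

#' Fit a single titration with a fixed Hill coefficient
#'
#' Least-squares fit of START, END and K for one condition with `n` held
#' fixed (e.g. at a globally fitted value); used to extract per-replicate K
#' values for group comparison.
#'
#' @param x,y Concentration (M) and response (FRET %).
#' @param n Fixed Hill coefficient.
#' @return A list with `start`, `end`, `k`, `loss`.
#' @export
fit_hill_fixed_n <- function(x, y, n) {
  resid_fn <- function(p) {
    xn <- (x / 10^p[3])^n
    p[1] + (p[2] - p[1]) * xn / (1 + xn) - y
  }
  half <- (min(y) + max(y)) / 2
  p0 <- c(min(y), max(y), log10(max(1e-9, x[which.min(abs(y - half))])))
  ft <- minpack.lm::nls.lm(p0, fn = resid_fn, lower = c(-100, -100, -9),
                           upper = c(200, 200, -3),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  list(start = ft$par[1], end = ft$par[2], k = 10^ft$par[3],
       loss = ft$deviance)
}

#' Normalize a response to the fitted Hill span
#'
#' `(y - START) / (END - START)`: maps the fitted zero-ligand response to 0
#' and the saturating response to 1, so titrations with different absolute
#' FRET plateaus can be compared on one affinity axis.
#'
#' @param start,end Fitted plateaus (must differ).
#' @param y Response value(s).
#' @return Normalized fraction(s).
#' @export
normalize_curve <- function(start, end, y) {
  if (end == start) stop("END equals START; normalization undefined")
  (y - start) / (end - start)
}

#' Compare K_Ca values across conditions
#'
#' One-way ANOVA across groups of replicate `K` values, followed by all
#' pairwise two-sample t tests with Sidak adjustment
#' `p_adj = 1 - (1 - p)^m` over the `m` pairs.
#'
#' @param groups Named list of numeric vectors (replicate K values per
#'   condition), each of length >= 2.
#' @return An object of class `"kca_comparison"`: `f_statistic`, `p_value`,
#'   `pairwise` (data.frame `group1`, `group2`, `p_raw`, `p_sidak`),
#'   `group_means`.
#' @export
compare_kca <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 replicates")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(k = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  av <- stats::anova(stats::lm(k ~ g, data = df))
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p_raw = NA_real_, p_sidak = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    tt <- stats::t.test(groups[[pairs[1, i]]], groups[[pairs[2, i]]],
                        var.equal = TRUE)
    pw$p_raw[i] <- tt$p.value
  }
  pw$p_sidak <- 1 - (1 - pw$p_raw)^m
  structure(list(f_statistic = av$`F value`[1], p_value = av$`Pr(>F)`[1],
                 pairwise = pw,
                 group_means = vapply(groups, mean, numeric(1)),
                 post_hoc = "all-pairs t tests with Sidak adjustment"),
            class = "kca_comparison")
}

#' @export
print.kca_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g\n", x$f_statistic, x$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
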