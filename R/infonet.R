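# Mutual-information coupling between fragment state columns, the
# distance/MI-gated network, shortest allosteric paths, eigenvector
# centrality, and local-global coupling.

as_codes <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  match(x, sort(unique(x)))
}

entropy_from_counts <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log(p))
}

joint_counts <- function(ci, cj) {
  a <- as_codes(ci); b <- as_codes(cj)
  ka <- max(a)
  tabulate(a + ka * (b - 1L), nbins = ka * max(b))
}

#' Entropies and mutual information of fragment state columns
#'
#' Plug-in (empirical histogram) estimators, computed in nats.
#' `joint_entropy()` is the entropy of the empirical joint distribution of
#' two columns; `mutual_information()` is `I = H_i + H_j - H_ij`, symmetric
#' and non-negative up to rounding.
#'
#' @param column_i,column_j Equal-length vectors of state symbols
#'   (character, factor or integer).
#' @return Entropy / information in nats.
#' @export
joint_entropy <- function(column_i, column_j) {
  if (length(column_i) != length(column_j)) stop("column lengths differ")
  if (length(column_i) < 2L) stop("need at least 2 observations")
  entropy_from_counts(joint_counts(column_i, column_j))
}

#' @rdname joint_entropy
#' @export
mutual_information <- function(column_i, column_j) {
  if (length(column_i) != length(column_j)) stop("column lengths differ")
  hi <- entropy_from_counts(tabulate(as_codes(column_i)))
  hj <- entropy_from_counts(tabulate(as_codes(column_j)))
  hi + hj - joint_entropy(column_i, column_j)
}

#' Finite-size bias correction for plug-in mutual information
#'
#' First-order correction for the positive bias of histogram mutual
#' information at finite sample size: `eps = (B_ij - B_i - B_j + 1) / (2 T)`
#' nats, where the B are the numbers of occupied joint and marginal
#' histogram cells and T the number of frames; floored at 0.
#'
#' @inheritParams joint_entropy
#' @return Correction in nats (non-negative).
#' @export
finite_size_correction <- function(column_i, column_j) {
  if (length(column_i) != length(column_j)) stop("column lengths differ")
  T <- length(column_i)
  bij <- sum(joint_counts(column_i, column_j) > 0)
  bi <- length(unique(column_i))
  bj <- length(unique(column_j))
  max(0, (bij - bi - bj + 1) / (2 * T))
}

#' Normalized mutual information between two fragment columns
#'
#' The coupling score of the allosteric analysis:
#' `I_LLn = (I - eps) / H_joint`, clamped to \[0, 1\], with `I` the plug-in
#' mutual information, `eps` the finite-size correction and `H_joint` the
#' joint entropy. Defined as 0 when the joint entropy is 0 (both columns
#' constant). The ratio is invariant to the logarithm base.
#'
#' @inheritParams joint_entropy
#' @return A list of class `"mi_result"` with fields `I`, `H_joint`,
#'   `epsilon` (nats) and `illn` (dimensionless, in \[0, 1\]).
#' @export
normalized_mi <- function(column_i, column_j) {
  if (length(column_i) != length(column_j)) stop("column lengths differ")
  nj <- joint_counts(column_i, column_j)
  hj <- entropy_from_counts(nj)
  hi1 <- entropy_from_counts(tabulate(as_codes(column_i)))
  hi2 <- entropy_from_counts(tabulate(as_codes(column_j)))
  I <- max(0, hi1 + hi2 - hj)
  T <- length(column_i)
  eps <- max(0, (sum(nj > 0) - length(unique(column_i)) -
                   length(unique(column_j)) + 1) / (2 * T))
  illn <- if (hj <= 0) 0 else min(1, max(0, (I - eps) / hj))
  structure(list(I = I, H_joint = hj, epsilon = eps, illn = illn),
            class = "mi_result")
}

#' Pairwise normalized mutual-information matrix
#'
#' `I_LLn` for all fragment pairs of a string alignment. The diagonal is set
#' to 1 for non-constant columns (self-information) and 0 for constant ones;
#' diagonal entries are excluded from cutoff statistics downstream.
#'
#' @param alignment A `"string_alignment"`.
#' @return A symmetric numeric matrix with one row/column per fragment,
#'   dimnames set to the fragment indices.
#' @export
illn_matrix <- function(alignment) {
  L <- alignment$letters
  nf <- ncol(L)
  T <- nrow(L)
  codes <- matrix(0L, T, nf)
  nlev <- integer(nf)
  for (j in seq_len(nf)) {
    cj <- as_codes(L[, j])
    codes[, j] <- cj
    nlev[j] <- max(cj)
  }
  hmarg <- vapply(seq_len(nf), function(j)
    entropy_from_counts(tabulate(codes[, j])), numeric(1))
  M <- diag(ifelse(nlev > 1L, 1, 0))
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      nij <- tabulate(codes[, i] + nlev[i] * (codes[, j] - 1L),
                      nbins = nlev[i] * nlev[j])
      hj <- entropy_from_counts(nij)
      I <- max(0, hmarg[i] + hmarg[j] - hj)
      eps <- max(0, (sum(nij > 0) - nlev[i] - nlev[j] + 1) / (2 * T))
      v <- if (hj <= 0) 0 else min(1, max(0, (I - eps) / hj))
      M[i, j] <- M[j, i] <- v
    }
  }
  dimnames(M) <- list(alignment$fragments$fragment,
                      alignment$fragments$fragment)
  M
}

#' Time-averaged first-CA node coordinates
#'
#' Representative coordinates for each fragment node: the time-averaged
#' position of the fragment's first CA atom, used by the network's physical
#' distance gate.
#'
#' @param trajectory A CA-only `"trajectory"`.
#' @param fragments Fragment table from [fragmentize()].
#' @param frame Optional single frame index to use instead of the time mean.
#' @return Numeric matrix, one row per fragment, columns x/y/z (Angstrom).
#' @export
node_coordinates <- function(trajectory, fragments, frame = NULL) {
  at <- trajectory$topology$atoms
  idx <- match(paste(fragments$chain, fragments$fragment),
               paste(at$chain, at$resno))
  co <- trajectory$coords
  if (!is.null(frame)) {
    m <- co[frame, idx, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  } else {
    m <- apply(co[, idx, , drop = FALSE], c(2, 3), mean)
  }
  rownames(m) <- fragments$fragment
  m
}

#' Build the allosteric coupling network
#'
#' Fragments become nodes; a pair (i, j) is joined by an edge when the
#' physical distance between the fragments' representative coordinates is at
#' most `d_cut` and `I_LLn(i, j)` is at least the information cutoff. The
#' cutoff is `mi_abs` if given, otherwise `mi_frac` times the maximum
#' off-diagonal `I_LLn`. Edge weight is the communication cost
#' `w = 1 - I_LLn`; each edge also retains its `I_LLn` and distance.
#'
#' @param illn Symmetric `I_LLn` matrix from [illn_matrix()].
#' @param node_coords Matrix of node coordinates (one row per fragment,
#'   Angstrom), e.g. from [node_coordinates()].
#' @param d_cut Distance cutoff in Angstrom (default 30).
#' @param mi_frac Information cutoff as a fraction of the maximum
#'   off-diagonal `I_LLn` (default 0.33).
#' @param mi_abs Optional absolute information cutoff overriding `mi_frac`.
#' @return An object of class `"mi_network"`: list with `nodes` (data.frame
#'   fragment/x/y/z), `edges` (data.frame i/j/illn/weight/distance), `graph`
#'   (igraph), `mi_cut`, `d_cut` and `empty` flag.
#' @export
build_network <- function(illn, node_coords, d_cut = 30, mi_frac = 0.33,
                          mi_abs = NULL) {
  if (!isSymmetric(unname(illn), tol = 1e-8)) stop("illn matrix must be symmetric")
  n <- nrow(illn)
  if (nrow(node_coords) != n) stop("one coordinate row per node required")
  frag <- rownames(illn)
  if (is.null(frag)) frag <- as.character(seq_len(n))
  off <- illn; diag(off) <- NA
  maxmi <- suppressWarnings(max(off, na.rm = TRUE))
  if (!is.finite(maxmi)) maxmi <- 0
  mi_cut <- if (!is.null(mi_abs)) mi_abs else mi_frac * maxmi
  D <- as.matrix(stats::dist(node_coords))
  edges <- NULL
  if (maxmi > 0) {
    sel <- which(upper.tri(illn) & D <= d_cut & illn >= mi_cut, arr.ind = TRUE)
    if (nrow(sel)) {
      edges <- data.frame(
        i = frag[sel[, 1]], j = frag[sel[, 2]],
        illn = illn[sel], weight = 1 - illn[sel], distance = D[sel],
        stringsAsFactors = FALSE)
    }
  }
  empty <- is.null(edges)
  if (empty)
    edges <- data.frame(i = character(), j = character(), illn = numeric(),
                        weight = numeric(), distance = numeric())
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j", "weight", "illn", "distance")],
    directed = FALSE,
    vertices = data.frame(name = frag, stringsAsFactors = FALSE))
  nodes <- data.frame(fragment = frag, node_coords, stringsAsFactors = FALSE)
  names(nodes)[2:4] <- c("x", "y", "z")
  structure(list(nodes = nodes, edges = edges, graph = g,
                 mi_cut = mi_cut, d_cut = d_cut, max_illn = maxmi,
                 empty = empty),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat("MI network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(d_cut %.3g A, mi_cut %.4g)", x$d_cut, x$mi_cut))
  if (x$empty) cat(" [no edges passed the cutoffs]")
  cat("\n")
  invisible(x)
}

#' Minimum-weight allosteric path between two site fragment sets
#'
#' Dijkstra shortest path over edge weights `w = 1 - I_LLn`, minimized over
#' all combinations of start fragments (site A) and end fragments (site B).
#' Ties are broken by fewer edges, then by the lexicographically smallest
#' fragment sequence, making the result deterministic. Returns a `"no path"`
#' result when the two sites lie in different components.
#'
#' @param network An `"mi_network"`.
#' @param site_a,site_b Character or numeric vectors of fragment names
#'   (non-empty, must exist in the network).
#' @return An object of class `"allosteric_path"` with fields `fragments`
#'   (ordered character vector; `NULL` if no path), `total_weight`,
#'   `edge_illn` (per-edge `I_LLn`), `no_path` flag.
#' @export
shortest_allosteric_path <- function(network, site_a, site_b) {
  site_a <- as.character(site_a); site_b <- as.character(site_b)
  if (!length(site_a) || !length(site_b)) stop("site sets must be non-empty")
  known <- network$nodes$fragment
  bad <- setdiff(c(site_a, site_b), known)
  if (length(bad)) stop("site fragment(s) not in network: ",
                        paste(bad, collapse = ", "))
  g <- network$graph
  w <- igraph::E(g)$weight
  best <- NULL
  for (a in site_a) {
    d <- igraph::distances(g, v = a, to = site_b, weights = w)
    for (bi in seq_along(site_b)) {
      if (!is.finite(d[1, bi])) next
      ps <- igraph::all_shortest_paths(g, from = a, to = site_b[bi],
                                       weights = w)$res
      for (p in ps) {
        fr <- names(p)
        cand <- list(fragments = fr, total_weight = unname(d[1, bi]),
                     n_edges = length(fr) - 1L)
        if (is.null(best) || better_path(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(fragments = NULL, total_weight = Inf,
                          edge_illn = NULL, no_path = TRUE),
                     class = "allosteric_path"))
  }
  ed <- network$edges
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ekey <- key(ed$i, ed$j)
  illn <- vapply(seq_len(best$n_edges), function(k) {
    ed$illn[match(key(best$fragments[k], best$fragments[k + 1]), ekey)]
  }, numeric(1))
  structure(list(fragments = best$fragments,
                 total_weight = best$total_weight,
                 edge_illn = illn, no_path = FALSE),
            class = "allosteric_path")
}

# TRUE if candidate path x beats incumbent y under (weight, edges, lex) order.
better_path <- function(x, y, tol = 1e-12) {
  if (x$total_weight < y$total_weight - tol) return(TRUE)
  if (x$total_weight > y$total_weight + tol) return(FALSE)
  if (x$n_edges != y$n_edges) return(x$n_edges < y$n_edges)
  xs <- suppressWarnings(as.numeric(x$fragments))
  ys <- suppressWarnings(as.numeric(y$fragments))
  if (anyNA(xs) || anyNA(ys)) { xs <- x$fragments; ys <- y$fragments }
  for (k in seq_along(xs)) {
    if (xs[k] < ys[k]) return(TRUE)
    if (xs[k] > ys[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.allosteric_path <- function(x, ...) {
  if (x$no_path) {
    cat("No allosteric path between the site sets.\n")
  } else {
    cat("Allosteric path:", paste0("f", x$fragments, collapse = " -> "), "\n")
    cat(sprintf("  total weight %.4f over %d edges; per-edge I_LLn: %s\n",
                x$total_weight, length(x$fragments) - 1L,
                paste(sprintf("%.3f", x$edge_illn), collapse = ", ")))
  }
  invisible(x)
}

#' Eigenvector centrality of the coupling network
#'
#' Relative importance of each fragment node, computed by power iteration on
#' the strength-weighted adjacency matrix (strength = `I_LLn`, so high
#' information exchange means strong connection; `"unweighted"` uses the
#' binary adjacency). A unit diagonal shift is applied during iteration --
#' this leaves the principal eigenvector unchanged while guaranteeing
#' convergence on bipartite graphs. Scores are normalized to max = 1.
#'
#' @param network An `"mi_network"` with at least one edge.
#' @param edge_strength `"illn"` (default) or `"unweighted"`.
#' @param tol Convergence tolerance on the iterate (default 1e-10).
#' @param max_iter Maximum iterations (default 10000).
#' @param top_frac Fraction defining the "top" membership flag (default 0.12).
#' @return A data.frame of class `"centrality_scores"` with columns
#'   `fragment`, `score` (max 1), `percentile` and `top` (logical, score in
#'   the top `top_frac` fraction).
#' @export
eigenvector_centrality <- function(network, edge_strength = c("illn", "unweighted"),
                                   tol = 1e-10, max_iter = 10000,
                                   top_frac = 0.12) {
  edge_strength <- match.arg(edge_strength)
  if (network$empty || nrow(network$edges) == 0L)
    stop("network has no edges; centrality undefined")
  frag <- network$nodes$fragment
  n <- length(frag)
  A <- matrix(0, n, n, dimnames = list(frag, frag))
  s <- if (edge_strength == "illn") network$edges$illn else
    rep(1, nrow(network$edges))
  ii <- match(network$edges$i, frag); jj <- match(network$edges$j, frag)
  A[cbind(ii, jj)] <- s; A[cbind(jj, ii)] <- s
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v2 <- A %*% v + v            # diagonal shift; same principal eigenvector
    v2 <- as.vector(v2) / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) { v <- v2; converged <- TRUE; break }
    v <- v2
  }
  if (!converged)
    stop(sprintf("power iteration did not converge (residual %.3g)",
                 max(abs(A %*% v + v - v * as.numeric(crossprod(v, A %*% v + v))))))
  v <- abs(v)
  score <- v / max(v)
  pct <- rank(score, ties.method = "average") / n * 100
  cutoff <- stats::quantile(score, 1 - top_frac, names = FALSE)
  structure(data.frame(fragment = frag, score = score, percentile = pct,
                       top = score >= cutoff, stringsAsFactors = FALSE),
            class = c("centrality_scores", "data.frame"))
}

#' Discretized global collective-motion states
#'
#' Projects every frame of a superposed CA trajectory onto the first
#' principal component of the coordinate covariance and discretizes the
#' projection into `n_states` equal-frequency bins. The principal-component
#' sign is fixed so that frame 1 projects non-positive, making the series
#' deterministic.
#'
#' @param trajectory A superposed CA-only `"trajectory"` with more frames
#'   than `n_states`.
#' @param n_states Number of global states (default 25).
#' @return An integer vector of class `"global_state_series"` (values in
#'   `1..n_states`, length F).
#' @export
global_motion_states <- function(trajectory, n_states = 25) {
  f <- n_frames(trajectory)
  if (f <= n_states) stop("need more frames than states")
  X <- coords_to_xyz(trajectory$coords)
  X <- sweep(X, 2, colMeans(X))
  if (sum(X^2) < 1e-12) stop("static (rank-deficient) trajectory")
  sv <- svd(X, nu = 1, nv = 1)
  proj <- as.vector(X %*% sv$v[, 1])
  if (proj[1] > 0) proj <- -proj
  states <- as.integer(ceiling(rank(proj, ties.method = "first") * n_states / f))
  structure(states, class = "global_state_series", n_states = n_states)
}

#' Local-global coupling I_LGn
#'
#' Normalized mutual information between each fragment's local state column
#' and the global collective-motion state series, using the identical
#' `I_LLn` estimator (finite-size corrected, joint-entropy normalized).
#'
#' @param alignment A `"string_alignment"`.
#' @param global_states A `"global_state_series"` (or integer vector) with
#'   one state per frame.
#' @return A data.frame with columns `fragment` and `ilgn`.
#' @export
ilgn <- function(alignment, global_states) {
  gs <- as.integer(global_states)
  if (length(gs) != nrow(alignment$letters))
    stop("frame-count mismatch between alignment and global states")
  vals <- vapply(seq_len(ncol(alignment$letters)), function(j)
    normalized_mi(alignment$letters[, j], gs)$illn, numeric(1))
  data.frame(fragment = alignment$fragments$fragment, ilgn = vals)
}
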