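# Independent oracles and small fixture builders used across the suite.
# Each oracle implements the quantity from its definition, independent of
# the package's computation path.

# --- information theory ------------------------------------------------

# Plug-in entropies/MI from an explicit joint contingency table, in an
# arbitrary log base; epsilon from the occupied-cell counts.
mi_oracle <- function(ci, cj, base = exp(1)) {
  tb <- table(ci, cj)
  p <- tb / sum(tb)
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q, base)) }
  H <- ent(as.vector(p)); Hx <- ent(px); Hy <- ent(py)
  I <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) I <- I + p[i, j] * log(p[i, j] / (px[i] * py[j]), base)
  }
  I <- as.numeric(I)
  Tn <- length(ci)
  eps <- (sum(tb > 0) - sum(px > 0) - sum(py > 0) + 1) / (2 * Tn) / log(base)
  eps <- max(0, eps)
  illn <- if (H <= 0) 0 else min(1, max(0, (max(0, I) - eps) / H))
  list(H_joint = H, H_i = Hx, H_j = Hy, I = I, eps = eps, illn = illn)
}

random_column <- function(T, k) sample(LETTERS[seq_len(k)], T, replace = TRUE)

# --- graphs ------------------------------------------------------------

# Random undirected weighted graph as a symmetric weight matrix with NA for
# absent edges. Weights drawn from a small discrete set to exercise ties.
random_graph <- function(n, p_edge, discrete = TRUE) {
  W <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      w <- if (discrete) sample(c(0.2, 0.4, 0.6, 0.8), 1) else stats::runif(1)
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

path_better <- function(x, y, tol = 1e-12) {
  if (x$total_weight < y$total_weight - tol) return(TRUE)
  if (x$total_weight > y$total_weight + tol) return(FALSE)
  if (x$n_edges != y$n_edges) return(x$n_edges < y$n_edges)
  xs <- as.numeric(x$fragments); ys <- as.numeric(y$fragments)
  for (k in seq_along(xs)) {
    if (xs[k] < ys[k]) return(TRUE)
    if (xs[k] > ys[k]) return(FALSE)
  }
  FALSE
}

# Exhaustive enumeration of all simple paths from any a in A to any b in B,
# returning the minimum-weight path under the package's tie-break order.
enum_min_path <- function(W, site_a, site_b) {
  best <- NULL
  n <- nrow(W)
  adj <- lapply(seq_len(n), function(v) which(is.finite(W[v, ])))
  visit <- function(path, w) {
    v <- path[length(path)]
    if (length(path) > 1 && v %in% site_b) {
      cand <- list(fragments = as.character(path), total_weight = w,
                   n_edges = length(path) - 1L)
      if (is.null(best) || path_better(cand, best)) best <<- cand
    }
    for (u in adj[[v]]) if (!(u %in% path)) visit(c(path, u), w + W[v, u])
  }
  for (a in site_a) visit(a, 0)
  best
}

# Package-facing wrapper: build an mi_network whose edges reproduce W
# exactly (distance gate satisfied, mi cutoff 0 via mi_abs).
network_from_weights <- function(W) {
  n <- nrow(W)
  illn <- 1 - W
  illn[is.na(illn)] <- 0        # absent edges: illn 0
  diag(illn) <- 1
  dimnames(illn) <- list(seq_len(n), seq_len(n))
  coords <- cbind(seq_len(n), 0, 0)  # all within any distance cutoff
  # mi_abs slightly above 0 so only true edges (illn >= 1 - max w = 0) stay:
  # encode absent edges as illn 0 and use mi_abs equal to the smallest
  # present illn value.
  present <- 1 - W[is.finite(W)]
  build_network(illn, coords, d_cut = 1e9,
                mi_abs = if (length(present)) min(present) - 1e-9 else 0.5)
}

# --- geometry ----------------------------------------------------------

# Minimum RMSD over proper rotations via Horn's quaternion method.
horn_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  S <- crossprod(A, B)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

# Brute-force superposition RMSD by direct minimization over Euler angles.
euler_rmsd <- function(mobile, ref) {
  A <- sweep(mobile, 2, colMeans(mobile)); B <- sweep(ref, 2, colMeans(ref))
  rot <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1,0,0, 0,cx,-sx, 0,sx,cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy,0,sy, 0,1,0, -sy,0,cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz,-sz,0, sz,cz,0, 0,0,1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) sqrt(mean(rowSums((A %*% t(rot(p)) - B)^2)))
  best <- Inf
  for (s in 1:8) {
    p0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# --- toy structures ----------------------------------------------------

toy_topology <- function(n_residues, atoms_per_res = c("CA")) {
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(r)
    data.frame(atom = atoms_per_res, resno = r, resid = "ALA", chain = "A",
               stringsAsFactors = FALSE)))
  allopath:::topology_from_atoms(atoms)
}

# Non-degenerate helix-like CA trajectory with optional per-frame jitter.
toy_trajectory <- function(n_residues, n_frames, jitter = 0) {
  t0 <- seq_len(n_residues)
  base <- cbind(2.3 * cos(t0), 2.3 * sin(t0), 1.5 * t0)
  co <- array(0, c(n_frames, n_residues, 3))
  for (f in seq_len(n_frames))
    co[f, , ] <- base + matrix(stats::rnorm(n_residues * 3, 0, jitter),
                               n_residues, 3)
  trajectory(co, toy_topology(n_residues))
}

write_toy_pdb <- function(path, n_residues = 4, atoms_per_res = c("CA"),
                          drop_ca_in = integer()) {
  lines <- character(); serial <- 0
  for (r in seq_len(n_residues)) {
    for (a in atoms_per_res) {
      if (a == "CA" && r %in% drop_ca_in) next
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, a, r, r * 3.8, (serial %% 3) * 1.1, 0))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
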