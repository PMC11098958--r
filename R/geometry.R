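# Rigid-body superposition, RMSF, residue-pair distances, 2D occupancy maps.

# Kabsch: optimal rotation R (det +1) and translation mapping mobile onto ref.
# Both inputs are n x 3 matrices. Returns list(R, t, rmsd).
kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))            # t(A) %*% B
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)            # mobile %*% R approx ref
  fit <- sweep(A %*% R, 2, cr, `+`)
  list(R = R, t = cr - cm %*% R, rmsd = sqrt(mean(rowSums((fit - ref)^2))),
       fitted = fit)
}

#' Superpose trajectory frames onto a reference
#'
#' Least-squares rigid-body superposition (Kabsch algorithm; rotations are
#' proper, determinant +1) of every frame onto a reference frame or an
#' explicit reference coordinate set.
#'
#' @param trajectory A `"trajectory"`.
#' @param reference Frame index (default 1) or an A x 3 coordinate matrix.
#' @param fit_atoms Optional integer vector of atom indices used to compute
#'   the transform (the whole frame is always moved). Default: all atoms.
#' @return A list of class `"superposition"`:
#'   \describe{
#'     \item{aligned}{the superposed `"trajectory"`.}
#'     \item{per_frame_rmsd}{numeric vector, RMSD of each aligned frame to the
#'       reference over `fit_atoms` (Angstrom).}
#'   }
#' @export
superpose <- function(trajectory, reference = 1L, fit_atoms = NULL) {
  co <- trajectory$coords
  f <- dim(co)[1]; a <- dim(co)[2]
  if (is.null(fit_atoms)) fit_atoms <- seq_len(a)
  ref <- if (is.matrix(reference)) reference else co[reference, , , drop = TRUE]
  if (!is.matrix(ref)) ref <- matrix(ref, ncol = 3)
  refsel <- ref[fit_atoms, , drop = FALSE]
  if (length(fit_atoms) < 3L) stop("need at least 3 atoms to superpose")
  cc <- sweep(refsel, 2, colMeans(refsel))
  if (qr(cc)$rank < 2L) stop("degenerate (collinear) reference coordinates")
  out <- co
  rmsd <- numeric(f)
  for (i in seq_len(f)) {
    fr <- co[i, , , drop = TRUE]
    k <- kabsch(fr[fit_atoms, , drop = FALSE], refsel)
    moved <- sweep(sweep(fr, 2, colMeans(fr[fit_atoms, , drop = FALSE])) %*% k$R,
                   2, colMeans(refsel), `+`)
    out[i, , ] <- moved
    rmsd[i] <- sqrt(mean(rowSums((moved[fit_atoms, , drop = FALSE] - refsel)^2)))
  }
  structure(list(aligned = trajectory(out, trajectory$topology,
                                      trajectory$frame_times),
                 per_frame_rmsd = rmsd),
            class = "superposition")
}

#' Per-residue root mean square fluctuation
#'
#' RMSF of each selected atom about its time-mean position. By default the
#' trajectory is first superposed with a two-pass scheme: one pass onto frame
#' 1, then a second pass onto the time-mean structure, which removes the
#' dependence of the fluctuation estimate on the arbitrary initial reference.
#'
#' @param trajectory A `"trajectory"` (typically CA-only).
#' @param residues Optional residue numbers to report (default: all).
#' @param atom Atom name used for the profile (default `"CA"`).
#' @param auto_superpose Superpose (two-pass) before computing? Default TRUE;
#'   set FALSE if the trajectory is already aligned.
#' @return A data.frame of class `"rmsf_profile"` with columns `resno`,
#'   `rmsf` (Angstrom).
#' @export
rmsf <- function(trajectory, residues = NULL, atom = "CA", auto_superpose = TRUE) {
  if (n_frames(trajectory) < 2L) stop("RMSF needs at least 2 frames")
  tr <- trajectory
  if (auto_superpose) {
    tr <- superpose(tr, 1L)$aligned
    mean_xyz <- apply(tr$coords, c(2, 3), mean)
    tr <- superpose(tr, mean_xyz)$aligned
  }
  at <- tr$topology$atoms
  idx <- which(at$atom == atom)
  if (!is.null(residues)) {
    missing <- setdiff(residues, at$resno[idx])
    if (length(missing))
      stop("atom '", atom, "' absent for residue(s): ",
           paste(missing, collapse = ", "))
    idx <- idx[at$resno[idx] %in% residues]
  }
  co <- tr$coords[, idx, , drop = FALSE]
  mu <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), mu)^2
  val <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & xyz, times 3 dims
  structure(data.frame(resno = at$resno[idx], rmsf = val),
            class = c("rmsf_profile", "data.frame"))
}

#' Residue-pair distance time series
#'
#' Euclidean distance per frame between one named atom in each of two
#' residues (default CA), e.g. the Ca2+-gate distance between the pump's
#' gating glutamate and the residues across the binding pocket.
#'
#' @param trajectory A `"trajectory"`.
#' @param residue_i,residue_j Residue numbers of the pair.
#' @param atom Atom name used in both residues (default `"CA"`).
#' @return A list of class `"distance_series"` with fields `pair`
#'   (residue_i, residue_j, atom) and `values` (numeric, Angstrom, length F).
#' @export
pair_distance_series <- function(trajectory, residue_i, residue_j, atom = "CA") {
  at <- trajectory$topology$atoms
  ii <- which(at$resno == residue_i & at$atom == atom)
  jj <- which(at$resno == residue_j & at$atom == atom)
  if (length(ii) == 0L) stop("atom '", atom, "' not found in residue ", residue_i)
  if (length(jj) == 0L) stop("atom '", atom, "' not found in residue ", residue_j)
  di <- trajectory$coords[, ii[1], , drop = TRUE] -
        trajectory$coords[, jj[1], , drop = TRUE]
  if (is.null(dim(di))) di <- matrix(di, ncol = 3)
  structure(list(pair = list(residue_i = residue_i, residue_j = residue_j,
                             atom = atom),
                 values = sqrt(rowSums(di^2))),
            class = "distance_series")
}

#' Two-dimensional occupancy density map
#'
#' Bins two equal-length distance series into a 2D grid and reports percent
#' occupancy per cell (cells sum to 100%). Used to visualize joint sampling
#' of two inter-residue distances, with rendering conventionally saturated at
#' 21% occupancy.
#'
#' @param series_x,series_y `"distance_series"` objects (or numeric vectors)
#'   of equal length.
#' @param bin_width Bin width in Angstrom (default 0.25).
#' @return A list of class `"density_map_2d"` with `x_edges`, `y_edges`
#'   (bin boundaries, Angstrom) and `occupancy` (matrix, percent; rows index
#'   x bins).
#' @export
density_map_2d <- function(series_x, series_y, bin_width = 0.25) {
  x <- if (inherits(series_x, "distance_series")) series_x$values else series_x
  y <- if (inherits(series_y, "distance_series")) series_y$values else series_y
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) == 0L) stop("empty series")
  xe <- seq(floor(min(x) / bin_width) * bin_width,
            ceiling(max(x) / bin_width) * bin_width + bin_width, by = bin_width)
  ye <- seq(floor(min(y) / bin_width) * bin_width,
            ceiling(max(y) / bin_width) * bin_width + bin_width, by = bin_width)
  xi <- findInterval(x, xe, rightmost.closed = TRUE)
  yi <- findInterval(y, ye, rightmost.closed = TRUE)
  occ <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  tab <- table(factor(xi, levels = seq_len(nrow(occ))),
               factor(yi, levels = seq_len(ncol(occ))))
  occ[] <- 100 * as.numeric(tab) / length(x)
  structure(list(x_edges = xe, y_edges = ye, occupancy = occ,
                 saturation = 21), class = "density_map_2d")
}

#' @export
print.density_map_2d <- function(x, ...) {
  cat("2D density map:", nrow(x$occupancy), "x", ncol(x$occupancy),
      "cells; max occupancy", sprintf("%.2f%%", max(x$occupancy)), "\n")
  invisible(x)
}

#' Write a distance/RMSF series or density map to CSV
#'
#' @param x An `"rmsf_profile"`, `"distance_series"` or `"density_map_2d"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  if (inherits(x, "rmsf_profile")) {
    utils::write.csv(data.frame(index = x$resno, value = x$rmsf), path,
                     row.names = FALSE)
  } else if (inherits(x, "distance_series")) {
    utils::write.csv(data.frame(index = seq_along(x$values), value = x$values),
                     path, row.names = FALSE)
  } else if (inherits(x, "density_map_2d")) {
    m <- x$occupancy
    dimnames(m) <- list(x_mid = x$x_edges[-length(x$x_edges)] + diff(x$x_edges) / 2,
                        y_mid = x$y_edges[-length(x$y_edges)] + diff(x$y_edges) / 2)
    utils::write.csv(m, path)
  } else stop("unsupported object")
  invisible(path)
}

#' Plot a 2D occupancy map
#'
#' Heat map with the occupancy color scale saturating at `x$saturation`
#' percent (default 21%), so dense conformational basins render comparably
#' across conditions.
#'
#' @param x A `"density_map_2d"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_map_2d <- function(x, ...) {
  z <- pmin(x$occupancy, x$saturation)
  graphics::image(x = x$x_edges, y = x$y_edges, z = z,
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = "distance x (A)", ylab = "distance y (A)", ...)
  invisible(x)
}
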