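# Structural alphabets: canonical four-point CA fragment conformations used
# to encode local backbone states as letters.

#' Construct a structural alphabet
#'
#' An alphabet is an ordered set of named canonical states for four-residue
#' CA fragments. Each state carries canonical 4 x 3 coordinates (Angstrom)
#' and/or a canonical internal-angle triple (theta1, theta2, tau in degrees).
#'
#' @param letters Character vector of distinct single symbols.
#' @param coords Optional list (one per letter) of 4 x 3 coordinate matrices.
#' @param angles Optional data.frame with columns `theta1`, `theta2`, `tau`.
#' @return An object of class `"structural_alphabet"`.
#' @export
structural_alphabet <- function(letters, coords = NULL, angles = NULL) {
  letters <- as.character(letters)
  if (length(letters) < 2L) stop("alphabet needs at least 2 states")
  if (anyDuplicated(letters)) stop("alphabet symbols must be unique")
  if (is.null(coords) && is.null(angles))
    stop("provide canonical coords and/or angles")
  if (!is.null(coords)) {
    if (length(coords) != length(letters)) stop("one coordinate set per letter")
    for (i in seq_along(coords)) {
      m <- coords[[i]]
      if (!is.matrix(m) || !all(dim(m) == c(4L, 3L)))
        stop("canonical coords must be 4 x 3 matrices (state ", letters[i], ")")
      if (any(dist(m) < 1e-6))
        stop("degenerate canonical coordinates in state ", letters[i])
      dimnames(m) <- NULL
      coords[[i]] <- m
    }
  }
  if (!is.null(angles)) {
    stopifnot(all(c("theta1", "theta2", "tau") %in% names(angles)),
              nrow(angles) == length(letters))
  }
  structure(list(letters = letters, coords = coords, angles = angles),
            class = "structural_alphabet")
}

#' @export
print.structural_alphabet <- function(x, ...) {
  cat("Structural alphabet:", length(x$letters), "states (",
      paste(x$letters[seq_len(min(6, length(x$letters)))], collapse = ""),
      if (length(x$letters) > 6) "..." else "", ")\n")
  invisible(x)
}

# Place atom D given A, B, C with bond length r, angle theta (B-C-D, deg)
# and dihedral tau (A-B-C-D, deg, IUPAC cis = 0).
place_atom <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("collinear reference atoms; dihedral frame undefined")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * cos(ta) * m + sin(th) * sin(ta) * n)
}

#' Build canonical 4-point coordinates from an internal-angle triple
#'
#' Places four pseudo-atoms with uniform bond length so that the pseudo-bond
#' angles are `theta1` (atoms 1-2-3) and `theta2` (atoms 2-3-4) and the
#' pseudo-torsion 1-2-3-4 equals `tau` (IUPAC sign convention, cis = 0).
#'
#' @param theta1,theta2 Pseudo-bond angles in degrees, in (0, 180).
#' @param tau Pseudo-torsion in degrees, in (-180, 180].
#' @param bond Pseudo-bond length in Angstrom (default 3.8, the canonical
#'   trans CA-CA distance).
#' @return A 4 x 3 coordinate matrix.
#' @export
fragment_from_angles <- function(theta1, theta2, tau, bond = 3.8) {
  t1 <- theta1 * pi / 180
  p1 <- c(0, 0, 0)
  p2 <- c(bond, 0, 0)
  p3 <- p2 + bond * c(-cos(t1), sin(t1), 0)
  p4 <- place_atom(p1, p2, p3, bond, theta2, tau)
  rbind(p1, p2, p3, p4, deparse.level = 0)
}

# Deterministic grid of diverse internal-angle triples; first entries span
# helix-like vs extended-like so small alphabets are maximally separated.
alphabet_angle_grid <- function() {
  base <- rbind(
    c(89, 92, 50),    # alpha-helical
    c(135, 130, 175), # extended
    c(105, 100, -60),
    c(120, 118, 0),
    c(95, 125, -150)
  )
  taus <- c(-155, -65, 25, 105, 180)
  grid <- do.call(rbind, lapply(seq_len(5), function(i) {
    cbind(base[i, 1] + c(0, 4, -4, 8, -8),
          base[i, 2] + c(0, -4, 4, -8, 8),
          taus[c(i:5, seq_len(i - 1))])
  }))
  colnames(grid) <- c("theta1", "theta2", "tau")
  # interleave the 5 families so any prefix is diverse
  grid[as.vector(t(matrix(seq_len(25), 5, 5))), , drop = FALSE]
}

#' Synthetic structural alphabet
#'
#' A deterministic, self-contained alphabet of up to 25 canonical states
#' (letters A-Y) built from a spread of internal-angle triples. This is a
#' synthetic stand-in constructed by this package -- it is not the canonical
#' 25-state alphabet of the structural-alphabet literature -- and is intended
#' for testing and for analyses where any fixed, well-separated state set
#' suffices. A transcription of a published alphabet can be supplied instead
#' via [read_alphabet()].
#'
#' @param n_letters Number of states (2 to 25, default 25).
#' @param bond Pseudo-bond length in Angstrom (default 3.8).
#' @return A `"structural_alphabet"` with both coordinates and angles.
#' @export
synthetic_alphabet <- function(n_letters = 25, bond = 3.8) {
  if (n_letters < 2 || n_letters > 25) stop("n_letters must be in 2..25")
  grid <- alphabet_angle_grid()[seq_len(n_letters), , drop = FALSE]
  coords <- lapply(seq_len(n_letters), function(i)
    fragment_from_angles(grid[i, 1], grid[i, 2], grid[i, 3], bond = bond))
  structural_alphabet(LETTERS[seq_len(n_letters)], coords = coords,
                      angles = as.data.frame(grid))
}

#' Read / write an alphabet as JSON
#'
#' The JSON schema has fields `letters` (array of symbols), optional `coords`
#' (per letter, 4 x 3 nested arrays, Angstrom) and optional `angles` (per
#' letter, objects with theta1/theta2/tau in degrees).
#'
#' @param path JSON file path.
#' @return `read_alphabet()`: a `"structural_alphabet"`.
#' @export
read_alphabet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- NULL
  if (!is.null(j$coords)) {
    coords <- if (is.list(j$coords)) lapply(j$coords, function(m) {
      m <- as.matrix(m); dimnames(m) <- NULL; m
    }) else apply(j$coords, 1, function(v) matrix(v, 4, 3), simplify = FALSE)
  }
  angles <- if (!is.null(j$angles)) as.data.frame(j$angles) else NULL
  structural_alphabet(j$letters, coords = coords, angles = angles)
}

#' @rdname read_alphabet
#' @param alphabet A `"structural_alphabet"`.
#' @return `write_alphabet()`: `path`, invisibly.
#' @export
write_alphabet <- function(alphabet, path) {
  jsonlite::write_json(
    list(letters = alphabet$letters, coords = alphabet$coords,
         angles = alphabet$angles),
    path, digits = NA, auto_unbox = FALSE, pretty = TRUE, null = "null")
  invisible(path)
}
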