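# Encoding CA trajectories as structural strings: overlapping four-residue
# fragments, internal-angle descriptors, and assignment to alphabet states.

#' Enumerate four-residue fragments of a topology
#'
#' Overlapping fragments of four consecutive residues, two consecutive
#' fragments sharing three residues. Each fragment is named by its first
#' residue number (fragment `f115` covers residues 115-118). Fragments never
#' span chain breaks; a chain of n residues yields exactly n - 3 fragments.
#'
#' @param topology A `"topology"`.
#' @return A data.frame with columns `fragment` (first residue number) and
#'   `chain`, one row per fragment, in chain/residue order.
#' @export
fragmentize <- function(topology) {
  res <- topology$residues
  out <- lapply(unique(res$chain), function(ch) {
    rn <- res$resno[res$chain == ch]
    if (length(rn) < 4L)
      stop("chain ", ch, " has fewer than 4 residues; cannot fragmentize")
    data.frame(fragment = rn[seq_len(length(rn) - 3L)], chain = ch,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Internal-angle descriptor of a four-point fragment
#'
#' The three internal angles that uniquely determine the shape of a
#' four-point CA fragment: two pseudo-bond angles (`theta1` over atoms 1-2-3,
#' `theta2` over atoms 2-3-4) and the pseudo-torsion `tau` over atoms
#' 1-2-3-4, reported with the IUPAC biomolecular dihedral convention
#' (cis = 0, range (-180, 180]).
#'
#' @param coords A 4 x 3 coordinate matrix (Angstrom).
#' @return A list with numeric fields `theta1`, `theta2`, `tau` (degrees).
#' @export
fragment_descriptors <- function(coords) {
  if (!is.matrix(coords) || !all(dim(coords) == c(4L, 3L)))
    stop("coords must be a 4 x 3 matrix")
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  b1 <- coords[2, ] - coords[1, ]
  b2 <- coords[3, ] - coords[2, ]
  b3 <- coords[4, ] - coords[3, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("collinear triple: torsion undefined")
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  tau <- atan2(-sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (tau <= -180) tau <- tau + 360
  list(theta1 = ang(coords[1, ], coords[2, ], coords[3, ]),
       theta2 = ang(coords[2, ], coords[3, ], coords[4, ]),
       tau = tau)
}

# Vectorized descriptors for all frames x fragments of a CA trajectory.
# Returns list of F x nfrag matrices theta1, theta2, tau (degrees).
trajectory_descriptors <- function(coords, frag_start_idx) {
  get <- function(off) coords[, frag_start_idx + off, , drop = FALSE]
  p1 <- get(0L); p2 <- get(1L); p3 <- get(2L); p4 <- get(3L)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  dotp <- function(u, v) u[, , 1] * v[, , 1] + u[, , 2] * v[, , 2] + u[, , 3] * v[, , 3]
  crossp <- function(u, v) {
    out <- array(0, dim(u))
    out[, , 1] <- u[, , 2] * v[, , 3] - u[, , 3] * v[, , 2]
    out[, , 2] <- u[, , 3] * v[, , 1] - u[, , 1] * v[, , 3]
    out[, , 3] <- u[, , 1] * v[, , 2] - u[, , 2] * v[, , 1]
    out
  }
  angm <- function(u, v)
    acos(pmin(1, pmax(-1, dotp(u, v) / sqrt(dotp(u, u) * dotp(v, v))))) * 180 / pi
  n1 <- crossp(b1, b2); n2 <- crossp(b2, b3)
  b2n <- sqrt(dotp(b2, b2))
  b2u <- b2; for (k in 1:3) b2u[, , k] <- b2[, , k] / b2n
  m1 <- crossp(n1, b2u)
  tau <- atan2(-dotp(m1, n2), dotp(n1, n2)) * 180 / pi
  tau[tau <= -180] <- tau[tau <= -180] + 360
  list(theta1 = angm(-b1, b2), theta2 = angm(-b2, b3), tau = tau)
}

# Minimum RMSD between two 4x3 point sets over proper rigid motions
# (Kabsch closed form via SVD).
min_rmsd4 <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A, B))
  sg <- s$d; sg[3] <- sg[3] * sign(det(s$u) * det(s$v))
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * sum(sg)) / nrow(A)))
}

#' Construct / validate a string alignment
#'
#' A string alignment is the encoded trajectory: for each frame, one letter
#' per fragment, giving an F x (n - 3) symbol matrix whose columns are the
#' per-fragment state time series consumed by the mutual-information
#' machinery.
#'
#' @param fragments Fragment table as returned by [fragmentize()].
#' @param letters Character matrix, frames x fragments.
#' @param alphabet Optional `"structural_alphabet"`; if given, all symbols
#'   are checked against it.
#' @return An object of class `"string_alignment"`.
#' @export
string_alignment <- function(fragments, letters, alphabet = NULL) {
  if (!is.matrix(letters) || !is.character(letters))
    stop("letters must be a character matrix")
  if (ncol(letters) != nrow(fragments))
    stop("one letter column per fragment required")
  if (!is.null(alphabet)) {
    bad <- setdiff(unique(as.vector(letters)), alphabet$letters)
    if (length(bad))
      stop("symbols not in alphabet: ", paste(bad, collapse = ", "))
  }
  structure(list(fragments = fragments, letters = letters,
                 alphabet = alphabet), class = "string_alignment")
}

#' @export
print.string_alignment <- function(x, ...) {
  cat("String alignment:", nrow(x$letters), "frames x",
      ncol(x$letters), "fragments\n")
  invisible(x)
}

#' Encode a CA trajectory as structural strings
#'
#' Assigns every four-residue fragment in every frame to its most similar
#' alphabet state. With `method = "rmsd_local_fit"` the state minimizing the
#' RMSD after optimal rigid superposition of the canonical fragment onto the
#' observed fragment is chosen (local fit); with `method =
#' "descriptor_nearest"` the state nearest in (theta1, theta2, tau) space is
#' chosen, with a periodic metric on tau. Ties break deterministically to the
#' lowest letter index. Frames are encoded independently (no temporal
#' smoothing), so encoding commutes with trajectory concatenation.
#'
#' @param trajectory A CA-only `"trajectory"`.
#' @param alphabet A `"structural_alphabet"` (canonical coordinates required
#'   for `rmsd_local_fit`, angles for `descriptor_nearest`).
#' @param method Assignment method; see Details.
#' @return A `"string_alignment"`.
#' @export
assign_states <- function(trajectory, alphabet,
                          method = c("rmsd_local_fit", "descriptor_nearest")) {
  method <- match.arg(method)
  at <- trajectory$topology$atoms
  if (!all(at$atom == "CA"))
    stop("trajectory must be CA-only; call select_calpha() first")
  frags <- fragmentize(trajectory$topology)
  start_idx <- match(paste(frags$chain, frags$fragment),
                     paste(at$chain, at$resno))
  co <- trajectory$coords
  f <- dim(co)[1]; nf <- nrow(frags); nl <- length(alphabet$letters)
  out <- matrix("", f, nf)
  if (method == "rmsd_local_fit") {
    if (is.null(alphabet$coords))
      stop("alphabet has no canonical coordinates; rmsd_local_fit unavailable")
    canon <- lapply(alphabet$coords, function(m) sweep(m, 2, colMeans(m)))
    canon_ss <- vapply(canon, function(m) sum(m^2), numeric(1))
    for (i in seq_len(f)) {
      for (j in seq_len(nf)) {
        obs <- co[i, start_idx[j] + 0:3, ]
        obs <- sweep(obs, 2, colMeans(obs))
        obs_ss <- sum(obs^2)
        best <- 1L; bestv <- Inf
        for (k in seq_len(nl)) {
          s <- svd(crossprod(canon[[k]], obs))
          sg <- s$d; sg[3] <- sg[3] * sign(det(s$u) * det(s$v))
          v <- canon_ss[k] + obs_ss - 2 * sum(sg)
          if (v < bestv - 1e-12) { bestv <- v; best <- k }
        }
        out[i, j] <- alphabet$letters[best]
      }
    }
  } else {
    if (is.null(alphabet$angles))
      stop("alphabet has no canonical angles; descriptor_nearest unavailable")
    de <- trajectory_descriptors(co, start_idx)
    ang <- alphabet$angles
    dbest <- matrix(Inf, f, nf)
    kbest <- matrix(1L, f, nf)
    for (k in seq_len(nl)) {
      dtau <- abs(de$tau - ang$tau[k]) %% 360
      dtau <- pmin(dtau, 360 - dtau)
      d2 <- (de$theta1 - ang$theta1[k])^2 + (de$theta2 - ang$theta2[k])^2 + dtau^2
      upd <- d2 < dbest - 1e-12
      dbest[upd] <- d2[upd]; kbest[upd] <- k
    }
    out[] <- alphabet$letters[kbest]
  }
  string_alignment(frags, out, alphabet)
}

#' Read / write string alignments as plain text
#'
#' Format: a header line `# fragments: i1 i2 ...` with the fragment first
#' residue numbers, then one string per frame (one character per fragment).
#'
#' @param path Text file path.
#' @return `read_alignment()`: a `"string_alignment"`.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# fragments:", lines[1])) stop("missing fragment header line")
  fr <- as.integer(strsplit(sub("^# fragments:\\s*", "", lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  body <- body[nzchar(body)]
  letters <- do.call(rbind, strsplit(body, ""))
  string_alignment(data.frame(fragment = fr, chain = "A",
                              stringsAsFactors = FALSE), letters)
}

#' @rdname read_alignment
#' @param alignment A `"string_alignment"`.
#' @return `write_alignment()`: `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  header <- paste("# fragments:",
                  paste(alignment$fragments$fragment, collapse = " "))
  body <- apply(alignment$letters, 1, paste, collapse = "")
  writeLines(c(header, body), path)
  invisible(path)
}
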