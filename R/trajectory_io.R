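#' Read a PDB topology
#'
#' Parses a PDB file with [bio3d::read.pdb()] and returns the residue/atom
#' bookkeeping used by all downstream analyses. Residue numbering and chain
#' identifiers are preserved verbatim from the file (1-based author
#' numbering), so fragment names map directly onto published residue spans.
#'
#' @param path Path to a PDB file containing `ATOM` records with CA atoms.
#' @return An object of class `"topology"`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with columns `atom`, `resno`, `resid`, `chain`,
#'       one row per atom, in file order.}
#'     \item{residues}{data.frame with columns `resno`, `resid`, `chain`, one
#'       row per residue that carries a CA atom, in file order.}
#'   }
#' @details Every residue in the file must carry a CA atom; residues lacking
#'   one trigger an error naming the offenders. Residue indices must be
#'   strictly increasing within a chain.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  atoms <- data.frame(
    atom  = at$elety,
    resno = at$resno,
    resid = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    stringsAsFactors = FALSE
  )
  topology_from_atoms(atoms)
}

#' @keywords internal
topology_from_atoms <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  ukey <- unique(key)
  first <- match(ukey, key)
  residues <- data.frame(
    resno = atoms$resno[first],
    resid = atoms$resid[first],
    chain = atoms$chain[first],
    stringsAsFactors = FALSE
  )
  has_ca <- vapply(ukey, function(k) any(atoms$atom[key == k] == "CA"), logical(1))
  if (!all(has_ca)) {
    bad <- residues[!has_ca, ]
    stop("residues lacking a CA atom: ",
         paste(sprintf("%s%d/%s", bad$chain, bad$resno, bad$resid), collapse = ", "))
  }
  for (ch in unique(residues$chain)) {
    rn <- residues$resno[residues$chain == ch]
    if (any(diff(rn) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology:", nrow(x$residues), "residues,", nrow(x$atoms), "atoms,",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' Construct a trajectory object
#'
#' @param coords Numeric array of dimension F x A x 3 (frames x atoms x xyz),
#'   in Angstrom.
#' @param topology A `"topology"` whose atom count equals `dim(coords)[2]`.
#' @param frame_times Optional numeric vector of frame times (ns).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(coords, topology, frame_times = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an F x A x 3 array")
  if (dim(coords)[1] < 1L) stop("trajectory needs at least one frame")
  if (dim(coords)[2] < 4L) stop("trajectory needs at least 4 atoms")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  if (!inherits(topology, "topology")) stop("topology must be a 'topology' object")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("atom-count mismatch: coords have ", dim(coords)[2],
         " atoms, topology has ", nrow(topology$atoms))
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    stop("frame_times length must equal frame count")
  structure(list(coords = coords, topology = topology, frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param trajectory A `"trajectory"`.
#' @return Integer count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(trajectory) dim(trajectory$coords)[2]

# F x A x 3 array <-> bio3d xyz matrix (F x 3A, x1 y1 z1 x2 ...)
coords_to_xyz <- function(coords) {
  f <- dim(coords)[1]; a <- dim(coords)[2]
  m <- matrix(0, f, 3L * a)
  m[, seq(1L, 3L * a, 3L)] <- coords[, , 1]
  m[, seq(2L, 3L * a, 3L)] <- coords[, , 2]
  m[, seq(3L, 3L * a, 3L)] <- coords[, , 3]
  m
}

xyz_to_coords <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  a <- ncol(xyz) / 3L
  arr <- array(0, c(nrow(xyz), a, 3L))
  arr[, , 1] <- xyz[, seq(1L, 3L * a, 3L)]
  arr[, , 2] <- xyz[, seq(2L, 3L * a, 3L)]
  arr[, , 3] <- xyz[, seq(3L, 3L * a, 3L)]
  arr
}

#' Read trajectory frames
#'
#' Reads coordinate frames from a DCD file (via [bio3d::read.dcd()]) or a
#' multi-model PDB and attaches them to a topology. Coordinates are Angstrom
#' internally; both supported formats are natively Angstrom.
#'
#' @param topology A `"topology"` describing the atoms in each frame.
#' @param path Path to the frames file.
#' @param format One of `"dcd"`, `"multi_model_pdb"`.
#' @return A `"trajectory"` with all frames in file order.
#' @export
read_frames <- function(topology, path, format = c("dcd", "multi_model_pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("frames file not found: ", path)
  xyz <- switch(format,
    dcd = bio3d::read.dcd(path, verbose = FALSE),
    multi_model_pdb = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      pdb$xyz
    }
  )
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  found <- ncol(xyz) / 3L
  if (found != nrow(topology$atoms))
    stop("atom-count mismatch: expected ", nrow(topology$atoms),
         " atoms, found ", found)
  trajectory(xyz_to_coords(xyz), topology)
}

#' Write trajectory frames
#'
#' Writes a trajectory to DCD (CHARMM-style binary) or multi-model PDB.
#' Intended for round-trip interchange and cache files.
#'
#' @param trajectory A `"trajectory"`.
#' @param path Output path.
#' @param format One of `"dcd"`, `"multi_model_pdb"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(trajectory, path, format = c("dcd", "multi_model_pdb")) {
  format <- match.arg(format)
  xyz <- coords_to_xyz(trajectory$coords)
  if (format == "multi_model_pdb") {
    at <- trajectory$topology$atoms
    bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resid,
                     elety = at$atom, chain = at$chain)
  } else {
    write_dcd(path, xyz)
  }
  invisible(path)
}

# Minimal CHARMM-format DCD writer (single-precision, no unit cell).
write_dcd <- function(path, xyz) {
  nf <- nrow(xyz); na <- ncol(xyz) / 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "written by allopath"), con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(na), con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- as.integer(4L * na)
  ix <- seq(1L, 3L * na, 3L)
  for (f in seq_len(nf)) {
    for (d in 0:2) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(xyz[f, ix + d]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}

#' Select atoms from a trajectory
#'
#' `select_calpha()` restricts a trajectory to its CA atoms (one per residue);
#' `select_atoms()` restricts to a named atom within chosen residues. Both
#' return a new `"trajectory"` with a matching reduced topology.
#'
#' @param trajectory A `"trajectory"`.
#' @return A `"trajectory"` containing only the selected atoms.
#' @export
select_calpha <- function(trajectory) {
  select_atoms(trajectory, atom = "CA")
}

#' @rdname select_calpha
#' @param residues Optional integer vector of residue numbers to keep
#'   (default: all).
#' @param atom Atom name to select (default `"CA"`).
#' @export
select_atoms <- function(trajectory, residues = NULL, atom = "CA") {
  at <- trajectory$topology$atoms
  keep <- at$atom == atom
  if (!is.null(residues)) {
    missing <- setdiff(residues, at$resno)
    if (length(missing))
      stop("residues not in topology: ", paste(missing, collapse = ", "))
    keep <- keep & at$resno %in% residues
    sel_res <- unique(at$resno[at$resno %in% residues])
    no_atom <- setdiff(residues, at$resno[at$atom == atom])
    if (length(no_atom))
      stop("atom '", atom, "' absent in residue(s): ",
           paste(no_atom, collapse = ", "))
  } else {
    res_all <- unique(paste(at$chain, at$resno))
    res_hit <- unique(paste(at$chain, at$resno)[keep])
    miss <- setdiff(res_all, res_hit)
    if (length(miss))
      stop("atom '", atom, "' absent in residue(s): ", paste(miss, collapse = ", "))
  }
  idx <- which(keep)
  new_atoms <- at[idx, , drop = FALSE]
  rownames(new_atoms) <- NULL
  trajectory(trajectory$coords[, idx, , drop = FALSE],
             topology_from_atoms_relaxed(new_atoms),
             trajectory$frame_times)
}

# Like topology_from_atoms but tolerates non-CA selections (e.g. named atoms).
topology_from_atoms_relaxed <- function(atoms) {
  if (all(atoms$atom == "CA")) return(topology_from_atoms(atoms))
  key <- paste(atoms$chain, atoms$resno)
  first <- match(unique(key), key)
  residues <- data.frame(resno = atoms$resno[first], resid = atoms$resid[first],
                         chain = atoms$chain[first], stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues), class = "topology")
}
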