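# Synthetic-data generators with known ground truth for every input class
# the pipeline consumes. All generators are deterministic for a fixed seed
# and return their ground truth alongside the data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a planted-chain coupled state alignment
#'
#' A synthetic stand-in for the coupled fragment dynamics underlying an
#' allosteric path. A designated ordered chain of fragments carries the
#' signal: the chain's root fragment flips between the alphabet's first two
#' letters as a Markov process (flip probability `flip_prob` per frame);
#' each downstream chain fragment copies its upstream neighbor's state with
#' probability `gamma` and otherwise draws uniformly from the alphabet.
#' Off-chain fragments are independent uniform noise. Node coordinates are
#' laid out so consecutive chain fragments are `chain_spacing` apart
#' (within a 30 A gate) while second-neighbors on the chain are beyond it,
#' and off-chain fragments sit on a parallel line `offchain_offset` away.
#'
#' @param n_fragments Total number of fragments (default 16).
#' @param chain Ordered integer vector of chain fragment indices (default
#'   `1:7`).
#' @param gamma Copy probability along the chain, in \[0, 1\] (default 0.9).
#' @param alphabet_size Number of letters used (default 2).
#' @param n_frames Number of frames T (default 2000).
#' @param flip_prob Root-state flip probability per frame (default 0.3).
#' @param chain_spacing Distance between consecutive chain nodes, Angstrom
#'   (default 20).
#' @param offchain_offset Perpendicular offset of the off-chain line,
#'   Angstrom (default 25).
#' @param seed Random seed.
#' @return A list with `alignment` (`"string_alignment"`), `coords`
#'   (fragment node coordinates), `chain` (the planted path, as character
#'   fragment names), and `spec` (the generating parameters).
#' @export
gen_coupled_state_chain <- function(n_fragments = 16, chain = 1:7,
                                    gamma = 0.9, alphabet_size = 2,
                                    n_frames = 2000, flip_prob = 0.3,
                                    chain_spacing = 20, offchain_offset = 25,
                                    seed = 1) {
  stopifnot(gamma >= 0, gamma <= 1, alphabet_size >= 2,
            all(chain %in% seq_len(n_fragments)), !anyDuplicated(chain))
  with_seed(seed, {
    L <- matrix("", n_frames, n_fragments)
    letters_used <- LETTERS[seq_len(alphabet_size)]
    # root: two-letter Markov flip chain
    root <- integer(n_frames)
    root[1] <- 1L
    flips <- stats::runif(n_frames - 1) < flip_prob
    for (t in 2:n_frames) root[t] <- if (flips[t - 1]) 3L - root[t - 1] else root[t - 1]
    L[, chain[1]] <- letters_used[root]
    # downstream chain fragments copy upstream with prob gamma
    for (m in seq_along(chain)[-1]) {
      copy <- stats::runif(n_frames) < gamma
      rnd <- sample(letters_used, n_frames, replace = TRUE)
      L[, chain[m]] <- ifelse(copy, L[, chain[m - 1]], rnd)
    }
    offchain <- setdiff(seq_len(n_fragments), chain)
    for (j in offchain)
      L[, j] <- sample(letters_used, n_frames, replace = TRUE)
    # geometry: chain on y = 0, off-chain staggered on y = offset
    coords <- matrix(0, n_fragments, 3)
    coords[chain, 1] <- chain_spacing * (seq_along(chain) - 1)
    if (length(offchain)) {
      coords[offchain, 1] <- chain_spacing * (seq_along(offchain) - 1) +
        chain_spacing / 2
      coords[offchain, 2] <- offchain_offset
    }
    rownames(coords) <- seq_len(n_fragments)
    frags <- data.frame(fragment = seq_len(n_fragments), chain = "A",
                        stringsAsFactors = FALSE)
    list(alignment = string_alignment(frags, L),
         coords = coords,
         chain = as.character(chain),
         spec = list(n_fragments = n_fragments, chain = chain, gamma = gamma,
                     alphabet_size = alphabet_size, n_frames = n_frames,
                     flip_prob = flip_prob, chain_spacing = chain_spacing,
                     offchain_offset = offchain_offset, seed = seed))
  })
}

# Zigzag arm of CA pseudo-atoms in the xy plane starting at `origin`,
# heading `dir0` (unit 2-vector), alternating +/- `zig` degrees.
zigzag_arm <- function(n, origin, angle0, bond = 3.8, zig = 30) {
  pts <- matrix(0, n, 3)
  ang <- angle0
  p <- origin
  for (i in seq_len(n)) {
    a <- ang + (if (i %% 2 == 0) zig else -zig) * pi / 180
    p <- p + bond * c(cos(a), sin(a), 0)
    pts[i, ] <- p
  }
  pts
}

#' Generate a two-state switching polymer trajectory
#'
#' Emulates rapid interconversion of a binding pocket between two major
#' geometries: a toy CA polymer whose distal arm hinges between a "closed"
#' and an "open" conformer, tuned so that a designated probe residue pair
#' sits at `d_closed` (default 15 A) and `d_open` (default 20 A)
#' respectively. Frames follow a two-state Markov chain (closed/open) with
#' isotropic Gaussian coordinate jitter; the per-frame ground-truth state
#' labels are returned.
#'
#' @param n_residues Number of residues (default 100).
#' @param hinge Residue index at which the mobile arm starts (default 61;
#'   residues `hinge..n_residues` form the switch region).
#' @param probe Length-2 integer vector: probe residue pair, one on each
#'   arm (default `c(55, 66)`).
#' @param d_closed,d_open Target probe distances, Angstrom (defaults 15, 20).
#' @param switch_prob Length-2 numeric: per-frame transition probabilities
#'   (closed to open, open to closed); default `c(0.1, 0.1)`.
#' @param jitter_sd Gaussian coordinate jitter SD per axis, Angstrom
#'   (default 0.3).
#' @param n_frames Frame count (default 2000).
#' @param seed Random seed.
#' @return A list with `trajectory` (`"trajectory"`, CA-only), `labels`
#'   (integer per frame: 1 = closed, 2 = open), `probe`, `conformers`
#'   (the two jitter-free coordinate sets), and `spec`.
#' @export
gen_two_state_polymer <- function(n_residues = 100, hinge = 61,
                                  probe = c(55, 66), d_closed = 15,
                                  d_open = 20, switch_prob = c(0.1, 0.1),
                                  jitter_sd = 0.3, n_frames = 2000, seed = 1) {
  stopifnot(hinge > 4, hinge < n_residues - 3, probe[1] < hinge,
            probe[2] >= hinge, all(switch_prob > 0), all(switch_prob < 1))
  bond <- 3.8
  n1 <- hinge - 1L
  arm1 <- zigzag_arm(n1, c(0, 0, 0), angle0 = 0, bond = bond)
  pivot <- arm1[n1, ]
  n2 <- n_residues - n1
  build <- function(phi) {
    arm2 <- zigzag_arm(n2, pivot, angle0 = phi, bond = bond)
    rbind(arm1, arm2)
  }
  probe_dist <- function(phi) {
    m <- build(phi)
    sqrt(sum((m[probe[1], ] - m[probe[2], ])^2))
  }
  solve_phi <- function(target) {
    grid <- seq(0.05, pi - 0.05, length.out = 200)
    vals <- vapply(grid, probe_dist, numeric(1)) - target
    sgn <- which(diff(sign(vals)) != 0)
    if (!length(sgn)) stop("probe distance ", target,
                           " A unreachable with this arm geometry")
    stats::uniroot(function(p) probe_dist(p) - target,
                   c(grid[sgn[1]], grid[sgn[1] + 1]), tol = 1e-10)$root
  }
  closed <- build(solve_phi(d_closed))
  open <- build(solve_phi(d_open))
  for (m in list(closed, open)) {
    step <- sqrt(rowSums((m[-1, ] - m[-n_residues, ])^2))
    if (any(step < 1)) stop("conformer has clashing consecutive CA spacing")
  }
  with_seed(seed, {
    labels <- integer(n_frames)
    labels[1] <- 1L
    u <- stats::runif(n_frames - 1)
    for (t in 2:n_frames) {
      p_switch <- if (labels[t - 1] == 1L) switch_prob[1] else switch_prob[2]
      labels[t] <- if (u[t - 1] < p_switch) 3L - labels[t - 1] else labels[t - 1]
    }
    co <- array(0, c(n_frames, n_residues, 3))
    jit <- array(stats::rnorm(n_frames * n_residues * 3, 0, jitter_sd),
                 c(n_frames, n_residues, 3))
    for (t in seq_len(n_frames))
      co[t, , ] <- (if (labels[t] == 1L) closed else open) + jit[t, , ]
    atoms <- data.frame(atom = "CA", resno = seq_len(n_residues),
                        resid = "ALA", chain = "A", stringsAsFactors = FALSE)
    tr <- trajectory(co, topology_from_atoms(atoms))
    list(trajectory = tr, labels = labels, probe = probe,
         conformers = list(closed = closed, open = open),
         spec = list(n_residues = n_residues, hinge = hinge, probe = probe,
                     d_closed = d_closed, d_open = d_open,
                     switch_prob = switch_prob, jitter_sd = jitter_sd,
                     n_frames = n_frames, seed = seed))
  })
}

#' Generate a Poisson TCSPC decay histogram
#'
#' Per-bin Poisson draws with mean proportional to the multi-exponential
#' decay `sum_k a_k exp(-t / tau_k)`, scaled so the expected total count
#' equals `total_photons`. Binning defaults to 16 ps.
#'
#' @param components Data.frame with columns `amplitude` (>= 0, not all 0)
#'   and `tau_ns` (> 0).
#' @param total_photons Expected total photon count (default 1e6).
#' @param bin_width_ps Bin width, ps (default 16).
#' @param window_ns Acquisition window, ns (default 50). A window shorter
#'   than 3x the longest lifetime triggers a warning.
#' @param seed Random seed.
#' @return A list with `histogram` (`"decay_histogram"`) and `spec`.
#' @export
gen_decay <- function(components, total_photons = 1e6, bin_width_ps = 16,
                      window_ns = 50, seed = 1) {
  a <- components$amplitude; tau <- components$tau_ns
  stopifnot(all(a >= 0), sum(a) > 0, all(tau > 0))
  if (window_ns < 3 * max(tau))
    warning("acquisition window shorter than 3x the longest lifetime")
  nbins <- floor(window_ns * 1000 / bin_width_ps)
  t <- (seq_len(nbins) - 0.5) * bin_width_ps / 1000
  mu <- colSums(a * exp(-outer(1 / tau, t)))
  mu <- mu / sum(mu) * total_photons
  counts <- with_seed(seed, stats::rpois(nbins, mu))
  list(histogram = decay_histogram(counts, bin_width_ps),
       spec = list(components = components, total_photons = total_photons,
                   bin_width_ps = bin_width_ps, window_ns = window_ns,
                   seed = seed))
}

#' Generate a synthetic Ca2+ titration table
#'
#' Hill-shaped FRET responses on a log-spaced concentration grid with
#' additive Gaussian noise, replicated independently, for any number of
#' conditions.
#'
#' @param params Data.frame with one row per condition and columns
#'   `condition`, `start`, `end`, `n`, `k` (K in molar).
#' @param x Concentration grid in molar (default: 12 points log-spaced from
#'   10 nM to 100 uM).
#' @param noise_sd Gaussian noise SD in FRET percentage points (default 0.5).
#' @param replicates Replicates per condition (default 6, matching the
#'   typical number of independent microsomal preparations in a titration
#'   study of this design).
#' @param seed Random seed.
#' @return A list with `data` (data.frame `condition`, `ca_free_molar`,
#'   `replicate`, `fret_percent`) and `spec`.
#' @export
gen_titration <- function(params,
                          x = 10^seq(log10(1e-8), log10(1e-4), length.out = 12),
                          noise_sd = 0.5, replicates = 6, seed = 1) {
  stopifnot(all(c("condition", "start", "end", "n", "k") %in% names(params)),
            all(x > 0), noise_sd >= 0)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(params))) {
      mu <- hill_curve(x, params$start[i], params$end[i], params$n[i],
                       params$k[i])
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = params$condition[i], ca_free_molar = x, replicate = r,
          fret_percent = mu + stats::rnorm(length(x), 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    list(data = do.call(rbind, rows),
         spec = list(params = params, x = x, noise_sd = noise_sd,
                     replicates = replicates, seed = seed))
  })
}

#' Write a generated fixture set to disk
#'
#' Emits the standard file forms of a generated dataset plus a JSON
#' ground-truth sidecar: for a planted chain, the strings text file and a
#' node-coordinate CSV; for a polymer, a topology PDB and multi-model PDB
#' frames; for decays and titrations, delimited text / CSV.
#'
#' @param x Output of one of the `gen_*()` generators.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(x, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)
  if (!is.null(x$alignment)) {
    p <- file.path(dir, paste0(name, "_strings.txt"))
    write_alignment(x$alignment, p); add(p)
    p <- file.path(dir, paste0(name, "_coords.csv"))
    utils::write.csv(data.frame(fragment = rownames(x$coords),
                                x = x$coords[, 1], y = x$coords[, 2],
                                z = x$coords[, 3]), p, row.names = FALSE)
    add(p)
  }
  if (!is.null(x$trajectory)) {
    p <- file.path(dir, paste0(name, "_traj.pdb"))
    write_frames(x$trajectory, p, format = "multi_model_pdb"); add(p)
  }
  if (!is.null(x$histogram)) {
    p <- file.path(dir, paste0(name, "_decay.txt"))
    write_decay(x$histogram, p); add(p)
  }
  if (!is.null(x$data)) {
    p <- file.path(dir, paste0(name, "_titration.csv"))
    utils::write.csv(x$data, p, row.names = FALSE); add(p)
  }
  truth <- x[setdiff(names(x), c("alignment", "trajectory", "histogram",
                                 "data"))]
  p <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, p, digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  add(p)
  invisible(paths)
}
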