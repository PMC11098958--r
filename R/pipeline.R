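# End-to-end orchestration: trajectory/strings -> network -> path report,
# and decays/titration -> global Hill fit -> K_Ca comparison. Every run
# writes a manifest sufficient to reproduce it byte-for-byte.

path_config_keys <- c("strings", "coords", "topology", "frames",
                      "frames_format", "alphabet", "assign_method",
                      "site_a", "site_b", "d_cut", "mi_frac", "mi_abs",
                      "n_global_states", "seed", "out_dir", "label")
fret_config_keys <- c("titration", "decays", "decay_index", "tau_d",
                      "n_starts", "seed", "out_dir", "label")

#' Build / read a run configuration
#'
#' A run configuration is a named list validated against the known keys of
#' the two pipelines; unknown keys are rejected so typos in cutoffs cannot
#' silently change an analysis. Defaults follow the standard operating
#' points of the method: `d_cut = 30` A, `mi_frac = 0.33`, `tau_d = 3.52`
#' ns.
#'
#' @param ... Named configuration entries (see [run_path_analysis()] and
#'   [run_fret_analysis()] for the keys each pipeline uses).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (is.null(names(cfg)) || any(names(cfg) == ""))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(cfg), union(path_config_keys, fret_config_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(d_cut = 30, mi_frac = 0.33, tau_d = 3.52,
                   n_global_states = 25, assign_method = "rmsd_local_fit",
                   frames_format = "dcd", n_starts = 5, seed = 1,
                   label = "run")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of configuration entries.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

write_manifest <- function(cfg, inputs, stage_log, out_dir, extra = list()) {
  hashes <- lapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL)
  manifest <- c(list(
    config = unclass(cfg),
    input_md5 = hashes,
    stages = stage_log,
    package_version = as.character(utils::packageVersion("allopath"))),
    extra)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, digits = 12, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", force = TRUE)
  p
}

#' Run the allosteric path analysis pipeline
#'
#' Executes encode -> I_LLn matrix -> network -> shortest path ->
#' centrality (-> I_LGn when a trajectory is available) and writes all
#' intermediate artifacts plus a manifest. Inputs are either a precomputed
#' string alignment (`strings` + `coords` paths) or a trajectory
#' (`topology` + `frames` + `alphabet`).
#'
#' Config keys: `strings`, `coords` (CSV fragment/x/y/z) *or* `topology`,
#' `frames`, `frames_format`, `alphabet` (JSON path) and `assign_method`;
#' plus `site_a`, `site_b` (fragment name vectors), `d_cut`, `mi_frac`,
#' optional `mi_abs`, `n_global_states`, `out_dir`, `label`.
#'
#' @param cfg A `"run_config"`.
#' @return An object of class `"path_report"`: list with `path`
#'   (`"allosteric_path"`), `centrality`, `ilgn` (or NULL), `network`,
#'   `mi_cut`, `no_path` flag, `artifacts` (paths written).
#' @export
run_path_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  if (is.null(cfg$site_a) || is.null(cfg$site_b))
    stop("config needs site_a and site_b")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    # timings go to the message stream, never into the manifest, so reruns
    # of the same config/seed produce byte-identical artifacts
    message(sprintf("[allopath] stage %s: %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    stage_log[[name]] <<- "completed"
    r
  }
  traj <- NULL
  if (!is.null(cfg$strings)) {
    alignment <- stage("load_strings", read_alignment(cfg$strings))
    cv <- utils::read.csv(cfg$coords)
    coords <- as.matrix(cv[, c("x", "y", "z")])
    rownames(coords) <- cv$fragment
  } else {
    topo <- stage("read_topology", read_topology(cfg$topology))
    traj <- stage("read_frames",
                  read_frames(topo, cfg$frames, cfg$frames_format))
    traj <- select_calpha(traj)
    alphabet <- stage("read_alphabet", read_alphabet(cfg$alphabet))
    alignment <- stage("encode",
                       assign_states(traj, alphabet, cfg$assign_method))
    coords <- node_coordinates(traj, alignment$fragments)
  }
  illn <- stage("illn_matrix", illn_matrix(alignment))
  net <- stage("build_network",
               build_network(illn, coords, d_cut = cfg$d_cut,
                             mi_frac = cfg$mi_frac, mi_abs = cfg$mi_abs))
  path <- stage("shortest_path",
                shortest_allosteric_path(net, cfg$site_a, cfg$site_b))
  # near-degenerate noise networks (e.g. a handful of disconnected edges
  # with almost equal strength) can defeat power iteration; report the
  # failure instead of aborting the run
  cent_err <- NULL
  cent <- if (nrow(net$edges) > 0) {
    tryCatch(stage("centrality", eigenvector_centrality(net)),
             error = function(e) { cent_err <<- conditionMessage(e); NULL })
  } else NULL
  ilgn_tab <- NULL
  if (!is.null(traj)) {
    gs <- stage("global_states",
                global_motion_states(superpose(traj)$aligned,
                                     cfg$n_global_states))
    ilgn_tab <- stage("ilgn", ilgn(alignment, gs))
  }
  # artifacts
  art <- character()
  put <- function(p) { art <<- c(art, p); p }
  utils::write.csv(round(illn, 10),
                   put(file.path(cfg$out_dir, "illn_matrix.csv")))
  ed <- net$edges
  ed$illn <- round(ed$illn, 10); ed$weight <- round(ed$weight, 10)
  ed$distance <- round(ed$distance, 6)
  utils::write.csv(ed, put(file.path(cfg$out_dir, "edges.csv")),
                   row.names = FALSE)
  if (!is.null(cent)) {
    cs <- as.data.frame(cent)
    cs$score <- round(cs$score, 10); cs$percentile <- round(cs$percentile, 6)
    utils::write.csv(cs, put(file.path(cfg$out_dir, "centrality.csv")),
                     row.names = FALSE)
  }
  if (!is.null(ilgn_tab)) {
    it <- ilgn_tab; it$ilgn <- round(it$ilgn, 10)
    utils::write.csv(it, put(file.path(cfg$out_dir, "ilgn.csv")),
                     row.names = FALSE)
  }
  top_frags <- if (!is.null(cent)) cent$fragment[cent$top] else character()
  report <- list(
    label = cfg$label,
    no_path = path$no_path,
    path_fragments = path$fragments,
    total_weight = if (path$no_path) NULL else round(path$total_weight, 10),
    edge_illn = if (path$no_path) NULL else round(path$edge_illn, 10),
    mi_cut = round(net$mi_cut, 10), d_cut = cfg$d_cut,
    max_illn = round(net$max_illn, 10),
    n_edges = nrow(net$edges),
    centrality_top = top_frags,
    centrality_error = cent_err,
    path_in_top = if (!path$no_path && !is.null(cent))
      all(path$fragments[c(-1, -length(path$fragments))] %in% top_frags)
      else NULL)
  jsonlite::write_json(report, put(file.path(cfg$out_dir, "path_report.json")),
                       digits = 12, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", force = TRUE)
  put(write_manifest(cfg, list(strings = cfg$strings, coords = cfg$coords,
                               topology = cfg$topology, frames = cfg$frames,
                               alphabet = cfg$alphabet),
                     stage_log, cfg$out_dir,
                     extra = list(mi_cut = round(net$mi_cut, 10))))
  structure(list(path = path, centrality = cent, ilgn = ilgn_tab,
                 network = net, mi_cut = net$mi_cut, no_path = path$no_path,
                 artifacts = art),
            class = "path_report")
}

#' @export
print.path_report <- function(x, ...) {
  print(x$path)
  cat(sprintf("mi_cut = %.4g; %d network edges; %d artifacts written\n",
              x$mi_cut, nrow(x$network$edges), length(x$artifacts)))
  invisible(x)
}

#' Run the FRET titration analysis pipeline
#'
#' Either starts from a titration table (`titration` CSV with columns
#' condition, ca_free_molar, replicate, fret_percent) or derives one from a
#' directory of TCSPC decay files: `decays` (directory) plus `decay_index`
#' (CSV with columns file, condition, ca_free_molar, replicate), fitting
#' each decay with a two-exponential model and converting the
#' amplitude-weighted lifetime to FRET percent using `tau_d` (donor-only
#' lifetime, default 3.52 ns). The titration is then fit globally with one
#' shared Hill coefficient; per-replicate K values (fit with n fixed at the
#' shared estimate) are compared by one-way ANOVA with Sidak-adjusted
#' pairwise tests when every condition carries at least two replicates.
#'
#' @param cfg A `"run_config"`.
#' @return An object of class `"fret_report"`: `fit`
#'   (`"hill_global_fit"`), `comparison` (`"kca_comparison"` or NULL),
#'   `replicate_k` (data.frame), `decay_failures`, `artifacts`.
#' @export
run_fret_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- list()
  if (!is.null(cfg$titration)) {
    tab <- utils::read.csv(cfg$titration)
  } else {
    if (is.null(cfg$decays) || is.null(cfg$decay_index))
      stop("config needs either titration, or decays + decay_index")
    idx <- utils::read.csv(cfg$decay_index)
    rows <- list()
    for (i in seq_len(nrow(idx))) {
      f <- file.path(cfg$decays, idx$file[i])
      r <- tryCatch({
        fit <- fit_decay(read_decay(f), n_components = 2)
        fret_efficiency(fit$tau_amp, cfg$tau_d)
      }, error = function(e) e)
      if (inherits(r, "error")) {
        failures[[idx$file[i]]] <- conditionMessage(r)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = idx$condition[i], ca_free_molar = idx$ca_free_molar[i],
          replicate = idx$replicate[i], fret_percent = r,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) stop("all decay fits failed")
    tab <- do.call(rbind, rows)
  }
  fit <- fit_hill_global(tab, shared_n = TRUE, n_starts = cfg$n_starts,
                         seed = cfg$seed)
  # per-replicate K at the shared n, for the group comparison
  rep_k <- list()
  for (cc in unique(tab$condition)) {
    for (r in unique(tab$replicate[tab$condition == cc])) {
      sub <- tab[tab$condition == cc & tab$replicate == r, ]
      if (length(unique(sub$ca_free_molar)) < 5L) next
      fk <- tryCatch(fit_hill_fixed_n(sub$ca_free_molar, sub$fret_percent,
                                      n = fit$n), error = function(e) NULL)
      if (!is.null(fk))
        rep_k[[length(rep_k) + 1L]] <- data.frame(
          condition = cc, replicate = r, k = fk$k, stringsAsFactors = FALSE)
    }
  }
  rep_k <- if (length(rep_k)) do.call(rbind, rep_k) else NULL
  comparison <- NULL
  if (!is.null(rep_k)) {
    groups <- split(rep_k$k, rep_k$condition)
    if (length(groups) >= 2 && all(vapply(groups, length, integer(1)) >= 2))
      comparison <- compare_kca(groups)
  }
  art <- character()
  put <- function(p) { art <<- c(art, p); p }
  ctab <- fit$conditions
  for (col in c("start", "end", "k", "start_se", "end_se", "k_se"))
    ctab[[col]] <- signif(ctab[[col]], 10)
  utils::write.csv(ctab, put(file.path(cfg$out_dir, "hill_fit.csv")),
                   row.names = FALSE)
  if (!is.null(rep_k)) {
    rk <- rep_k; rk$k <- signif(rk$k, 10)
    utils::write.csv(rk, put(file.path(cfg$out_dir, "replicate_k.csv")),
                     row.names = FALSE)
  }
  report <- list(
    label = cfg$label,
    shared_n = signif(fit$n, 10), shared_n_se = signif(fit$n_se, 10),
    conditions = ctab, loss = signif(fit$loss, 10),
    tau_d_ns = cfg$tau_d,
    anova = if (!is.null(comparison)) list(
      f_statistic = signif(comparison$f_statistic, 10),
      p_value = signif(comparison$p_value, 10),
      pairwise = comparison$pairwise) else NULL,
    flags = fit$flags,
    decay_failures = failures)
  jsonlite::write_json(report, put(file.path(cfg$out_dir, "fret_report.json")),
                       digits = 12, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", force = TRUE)
  put(write_manifest(cfg, list(titration = cfg$titration,
                               decay_index = cfg$decay_index),
                     list(), cfg$out_dir))
  structure(list(fit = fit, comparison = comparison, replicate_k = rep_k,
                 decay_failures = failures, artifacts = art),
            class = "fret_report")
}

#' @export
print.fret_report <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$comparison)) print(x$comparison)
  if (length(x$decay_failures))
    cat(length(x$decay_failures), "decay file(s) failed to fit\n")
  invisible(x)
}
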