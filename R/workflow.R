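# Configuration and the end-to-end per-state analysis pipeline:
# persistence table -> threshold scan / p_T -> PSN -> hubs -> CR matrix,
# SB maps and max-SB paths -> convergence report -> clustering, with a
# manifest recording parameters, seeds and formula variants, plus the
# cross-state CR comparison.

#' Read a run configuration (YAML)
#'
#' Expected layout:
#' ```yaml
#' states:
#'   apo: {topology: top.pdb, trajectories: [r1.pdb, r2.pdb]}
#' sources: ["A:GLU:5"]
#' sinks: ["A:LEU:9"]
#' cutoffs: {hbond_distance: 3.5, hbond_angle: 120,
#'           saltbridge: 4.5, hydrophobic: 5.5}
#' p_T: null          # override; otherwise estimated
#' stride: 1
#' cluster_stride: 4
#' scan_step: 5
#' n_pcs: 20
#' min_degree: 3
#' cluster_algorithm: gromos
#' seed: 1
#' ```
#'
#' @param path YAML file
#' @return a `RunConfig` list with defaults filled in
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' Build a run configuration from a list
#'
#' Fills in the standard defaults (H-bond 3.5 A / 120 deg, salt bridge
#' 4.5 A, hydrophobic 5.5 A, 5% scan step, 20 PCs, clustering stride 4,
#' minimum hub degree 3).
#'
#' @param cfg named list (see [read_run_config()])
#' @return a `RunConfig`
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(states = list(), sources = character(0),
                   sinks = character(0),
                   cutoffs = list(), p_T = NULL, stride = 1L,
                   cluster_stride = 4L, scan_step = 5, n_pcs = 20L,
                   min_degree = 3L, cluster_algorithm = "gromos",
                   min_seq_sep = 2L, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  cut <- utils::modifyList(list(hbond_distance = 3.5, hbond_angle = 120,
                                saltbridge = 4.5, hydrophobic = 5.5),
                           as.list(cfg$cutoffs))
  cfg$detector_config <- interaction_config(
    saltbridge_cutoff = cut$saltbridge, hbond_distance = cut$hbond_distance,
    hbond_angle = cut$hbond_angle, hydrophobic_cutoff = cut$hydrophobic,
    min_seq_sep = cfg$min_seq_sep)
  class(cfg) <- "RunConfig"
  cfg
}

.validate_state <- function(config, state) {
  st <- config$states[[state]]
  if (is.null(st)) stop("state '", state, "' not in config")
  if (is.null(st$topology) || !file.exists(st$topology))
    stop("state '", state, "': topology path missing or not found")
  for (p in st$trajectories)
    if (!file.exists(p)) stop("state '", state, "': trajectory not found: ", p)
  st
}

.resolve_selectors <- function(structure, selectors, what) {
  ids <- node_id(structure, structure$residues$ri)
  bad <- setdiff(selectors, ids)
  if (length(bad))
    stop(what, " selector(s) not in structure: ", paste(bad, collapse = ", "))
  invisible(selectors)
}

#' Run the full per-state analysis
#'
#' Loads the state's topology and trajectories, superposes, computes the
#' persistence table, threshold scan and p_T (unless overridden), builds
#' the PSN, classifies hubs, computes the CR matrix, SB maps and max-SB
#' paths for every (source, sink) pair, a convergence report (when the
#' state has at least two replicas) and an RMSD-matrix clustering at the
#' data-driven cutoff.  All tables are written as TSV under
#' `out_dir/state/`, the PSN as GML and edge list, plus a YAML manifest.
#'
#' @param config a `RunConfig`
#' @param state state label (must be a key of `config$states`)
#' @param out_dir output directory (created if needed)
#' @return the report bundle, invisibly (list of all computed objects)
#' @export
run_state_analysis <- function(config, state, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  st <- .validate_state(config, state)
  dir <- file.path(out_dir, state)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  structure <- load_structure(st$topology, config = st$structure_config %||% list())
  .resolve_selectors(structure, config$sources, "source")
  .resolve_selectors(structure, config$sinks, "sink")
  trajectory <- load_trajectory(structure, unlist(st$trajectories),
                                stride = config$stride)
  trajectory <- superpose(trajectory)

  stage <- "interactions"
  bundle <- list(state = state)
  res <- tryCatch({
    tab <- persistence_table(trajectory, config = config$detector_config)
    write_persistence_table(tab, file.path(dir, "persistence.tsv"))
    bundle$persistence <- tab

    stage <- "psn"
    scan <- threshold_scan(tab, step = config$scan_step)
    write_tsv(as.data.frame(scan), file.path(dir, "threshold_scan.tsv"))
    if (!is.null(config$p_T)) {
      p_T <- config$p_T
      pt_method <- "override"
    } else {
      est <- estimate_pt(scan)
      p_T <- est$p_T
      pt_method <- est$method
    }
    psn <- build_psn(tab, p_T)
    export_graph(psn, file.path(dir, "psn.gml"), "gml")
    export_graph(psn, file.path(dir, "psn_edges.tsv"), "edgelist")
    hubs <- find_hubs(psn, min_degree = config$min_degree)
    write_tsv(hubs, file.path(dir, "hubs.tsv"))
    bundle$scan <- scan; bundle$p_T <- p_T; bundle$psn <- psn
    bundle$hubs <- hubs

    stage <- "pathways"
    crm <- cr_matrix(psn, config$sources, config$sinks, p_T = p_T)
    write_tsv(crm, file.path(dir, "cr_matrix.tsv"))
    paths <- list()
    for (r in seq_len(nrow(crm))) {
      a <- crm$source[r]; b <- crm$sink[r]
      if (!isTRUE(crm$in_graph[r]) || crm$sigma_AB[r] == 0) next
      sb <- selective_betweenness(psn, a, b)
      write_sb_map(sb, file.path(dir, sprintf("sb_%s_%s.tsv",
                                              gsub(":", "-", a), gsub(":", "-", b))))
      paths[[paste(a, b, sep = " -> ")]] <- max_sb_path(psn, a, b)
    }
    if (length(paths)) {
      pdf_ <- data.frame(pair = names(paths),
                         path = vapply(paths, paste, character(1), collapse = " -> "),
                         stringsAsFactors = FALSE)
      write_tsv(pdf_, file.path(dir, "max_sb_paths.tsv"))
    }
    bundle$cr <- crm; bundle$max_sb_paths <- paths

    stage <- "convergence"
    if (nrow(trajectory$replicas) >= 2) {
      reps <- lapply(trajectory$replicas$label, function(l)
        get_replica(trajectory, l))
      names(reps) <- trajectory$replicas$label
      conv <- replica_report(reps, trajectory, n_modes = config$n_pcs)
      write_tsv(cbind(source = rownames(conv$rmsip),
                      as.data.frame(round(conv$rmsip, 8))),
                file.path(dir, "rmsip.tsv"))
      write_tsv(conv$summary, file.path(dir, "convergence_summary.tsv"))
      bundle$convergence <- conv
    }

    stage <- "clustering"
    cutoff <- derive_cutoff(trajectory)
    m <- rmsd_matrix(trajectory, stride = config$cluster_stride)
    cs <- if (identical(config$cluster_algorithm, "linkage"))
      linkage_cluster(m, max(cutoff, 1e-6))
    else gromos_cluster(m, max(cutoff, 1e-6))
    write_tsv(cluster_assignments(cs), file.path(dir, "clusters.tsv"))
    bundle$cluster_cutoff <- cutoff; bundle$clusters <- cs

    manifest <- list(
      package = as.character(utils::packageVersion("psnpath")),
      state = state, seed = config$seed,
      p_T = p_T, p_T_method = pt_method,
      formula = .FORMULA_VERSION,
      cutoffs = list(saltbridge = config$detector_config$saltbridge_cutoff,
                     hbond_distance = config$detector_config$hbond_distance,
                     hbond_angle = config$detector_config$hbond_angle,
                     hydrophobic = config$detector_config$hydrophobic_cutoff,
                     min_seq_sep = config$detector_config$min_seq_sep),
      stride = config$stride, cluster_stride = config$cluster_stride,
      scan_step = config$scan_step, n_pcs = config$n_pcs,
      min_degree = config$min_degree,
      cluster_algorithm = config$cluster_algorithm,
      cluster_cutoff = cutoff,
      n_frames = n_frames(trajectory))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    bundle$manifest <- manifest
    bundle
  }, error = function(e) {
    stop("state '", state, "' failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

#' Cross-state CR comparison
#'
#' Runs (or reuses) the per-state analyses and compares CR across states
#' for all (source, sink) pairs and for all source-source pairs
#' (inter-site communication), writing long-format comparison tables.
#'
#' @param config a `RunConfig` with at least two states
#' @param out_dir output directory
#' @param bundles optional precomputed list of per-state bundles from
#'   [run_state_analysis()]
#' @return list with `sink_comparison` and `source_comparison` tables,
#'   invisibly
#' @export
run_cross_state <- function(config, out_dir, bundles = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  states <- names(config$states)
  if (length(states) < 2) stop("need at least 2 states for comparison")
  if (is.null(bundles)) {
    bundles <- lapply(states, function(s) run_state_analysis(config, s, out_dir))
    names(bundles) <- states
  }
  tabs <- lapply(bundles, `[[`, "cr")
  comp <- compare_states(tabs)
  write_tsv(comp, file.path(out_dir, "cr_comparison.tsv"))
  src_comp <- NULL
  if (length(config$sources) >= 2) {
    src_tabs <- lapply(bundles, function(b)
      cr_matrix(b$psn, config$sources, config$sources, p_T = b$p_T))
    src_comp <- compare_states(src_tabs)
    write_tsv(src_comp, file.path(out_dir, "cr_source_comparison.tsv"))
  }
  invisible(list(sink_comparison = comp, source_comparison = src_comp,
                 bundles = bundles))
}
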