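# End-to-end orchestration: structure + trajectory + node map in, ring
# betweenness profile and classification out, with machine-readable reports.

#' Validated pipeline configuration
#'
#' @param structure Path to the PDB structure (or an `fq_system`).
#' @param trajectory Path to the trajectory (or an `fq_trajectory`).
#' @param node_map Path to the node-map TSV (or an `fq_node_map`).
#' @param trajectory_format `"auto"`, `"dcd"` or `"xyz"`.
#' @param node_point Node representative convention (see
#'   [partition_system()]).
#' @param reference Superposition reference (see [superpose_frames()]).
#' @param distance_cutoff,min_frame_fraction Contact criterion (see
#'   [contact_map()]).
#' @param skip_frames,stride Equilibration discard and frame stride.
#' @param count_mode Betweenness counting mode (see
#'   [network_betweenness()]).
#' @param threshold Classifier cut-off on the ring betweenness sum. The
#'   default 4000 is calibrated for Fab-scale systems (~220 residues); for
#'   small toy systems supply a commensurate value.
#' @param out Optional path for the JSON report.
#' @return A validated `fq_config` list.
#' @export
pipeline_config <- function(structure, trajectory, node_map,
                            trajectory_format = "auto",
                            node_point = "calpha_centroid",
                            reference = "mean_structure",
                            distance_cutoff = 4.5,
                            min_frame_fraction = 0.75,
                            skip_frames = 0L, stride = 1L,
                            count_mode = "fractional",
                            threshold = 4000,
                            out = NULL) {
  fq_assert(is_scalar_number(distance_cutoff) && distance_cutoff > 0,
            "distance_cutoff must be positive", "config")
  fq_assert(is_scalar_number(min_frame_fraction) &&
              min_frame_fraction > 0 && min_frame_fraction <= 1,
            "min_frame_fraction must lie in (0, 1]", "config")
  fq_assert(is_scalar_number(threshold) && threshold >= 0,
            "threshold must be non-negative", "config")
  fq_assert(count_mode %in% c("fractional", "all_paths"),
            "count_mode must be fractional or all_paths", "config")
  fq_assert(node_point %in% c("calpha_centroid", "first_atom"),
            "invalid node_point", "config")
  fq_assert(reference %in% c("mean_structure", "first_frame"),
            "invalid superposition reference", "config")
  structure(list(structure = structure, trajectory = trajectory,
                 node_map = node_map, trajectory_format = trajectory_format,
                 node_point = node_point, reference = reference,
                 distance_cutoff = distance_cutoff,
                 min_frame_fraction = min_frame_fraction,
                 skip_frames = as.integer(skip_frames),
                 stride = as.integer(stride),
                 count_mode = count_mode, threshold = threshold, out = out),
            class = "fq_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fq_abort(paste0("pipeline stage '", name, "' failed: ",
                    conditionMessage(e)), "stage",
             parent = e)
  })
}

#' Run the dynamical-network pipeline
#'
#' Chains structure/trajectory/node-map input, node partitioning,
#' superposition, correlation and contact computation, network construction,
#' edge betweenness, the ring-betweenness descriptor, and the cut-off
#' classification. The run is deterministic for fixed inputs and
#' configuration, and every parameter is echoed into the report.
#'
#' @param config An `fq_config` from [pipeline_config()].
#' @return An `fq_report`: list with `ring_sum`, `classification`,
#'   `ring_profile` (tibble), `n_nodes`, `n_edges`, `params`. Written as
#'   deterministic JSON when `config$out` is set.
#' @export
run_network_pipeline <- function(config) {
  stopifnot(inherits(config, "fq_config"))
  system <- stage("read_structure", {
    if (inherits(config$structure, "fq_system")) config$structure
    else read_structure(config$structure)
  })
  traj <- stage("read_trajectory", {
    if (inherits(config$trajectory, "fq_trajectory")) config$trajectory
    else read_trajectory(config$trajectory, system,
                         format = config$trajectory_format)
  })
  nmap <- stage("read_node_map", {
    if (inherits(config$node_map, "fq_node_map")) config$node_map
    else read_node_map(config$node_map)
  })
  partition <- stage("partition_system",
                     partition_system(system, nmap,
                                      node_point = config$node_point))
  ntraj <- stage("node_trajectory", node_trajectory(traj, partition))
  ntraj <- stage("superpose_frames",
                 superpose_frames(ntraj, reference = config$reference))
  cmat <- stage("correlation_matrix", correlation_matrix(ntraj))
  contacts <- stage("contact_map",
                    contact_map(traj, partition,
                                distance_cutoff = config$distance_cutoff,
                                min_frame_fraction = config$min_frame_fraction,
                                skip_frames = config$skip_frames,
                                stride = config$stride))
  net <- stage("build_network", build_network(cmat, contacts))
  bet <- stage("network_betweenness",
               network_betweenness(net, count_mode = config$count_mode))
  ring <- stage("ring_betweenness", ring_betweenness(bet, partition))
  label <- classify_score(ring$ring_sum, threshold = config$threshold)
  report <- structure(list(
    ring_sum = ring$ring_sum,
    classification = label,
    threshold = config$threshold,
    ring_profile = ring$profile,
    n_nodes = net$n_nodes,
    n_edges = nrow(net$edges),
    params = config[setdiff(names(config),
                            c("structure", "trajectory", "node_map", "out"))]
  ), class = "fq_report")
  if (!is.null(config$out)) {
    write_stable_json(unclass(report), config$out)
  }
  report
}

#' @export
print.fq_report <- function(x, ...) {
  cat("<fq_report> ring_sum = ", format(x$ring_sum, digits = 6), " -> ",
      x$classification, " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Run the competitive-ELISA pipeline
#'
#' @param data Panel data frame (see [cr_table()]) or path to a CSV readable
#'   by [read_elisa_csv()].
#' @param reference Reference analyte name.
#' @param out_tsv,out_json Optional output paths for the CR table and a JSON
#'   report.
#' @return The CR tibble from [cr_table()].
#' @export
run_elisa_pipeline <- function(data, reference, out_tsv = NULL,
                               out_json = NULL) {
  if (is.character(data)) data <- stage("read_elisa_csv", read_elisa_csv(data))
  res <- stage("cr_table", cr_table(data, reference = reference))
  if (!is.null(out_tsv)) readr::write_tsv(res, out_tsv)
  if (!is.null(out_json)) write_stable_json(list(reference = reference,
                                                 records = res), out_json)
  res
}

#' Recompute the headline results from the packaged reference tables
#'
#' Runs the cross-reactivity arithmetic, the 4000-cut-off classifier, the
#' score histogram, and the docking-separability analysis over the packaged
#' reference measurements.
#'
#' @param threshold Classifier cut-off (default 4000).
#' @return List with `cr` (recomputed CR percentages for the measurable
#'   compounds, 3 significant figures), `classification`
#'   (`fq_classification` over the betweenness table), `histogram`,
#'   `n_noncross_below_1000`, `min_cross_reactive_score`,
#'   `n_measurable_cr_compounds`, and `docking` (descriptor-overlap report).
#' @export
run_table_reproduction <- function(threshold = 4000) {
  act <- reference_activity()
  ref_ic50 <- act$ic50_ng_ml[act$compound == "GAT"]
  meas <- act[act$censored == 0 & act$compound != "GAT", ]
  cr <- tibble(
    compound = meas$compound,
    ic50 = meas$ic50_ng_ml,
    cr_computed = vapply(meas$ic50_ng_ml,
                         function(x) signif(cross_reactivity(ref_ic50, x)$cr,
                                            3),
                         numeric(1)),
    cr_reported = meas$cr_percent
  )
  bet <- reference_betweenness()
  cls <- classify_haptens(
    tibble(name = bet$hapten, ring_sum = bet$ring_sum, label = bet$label),
    threshold = threshold
  )
  hist <- score_histogram(bet, bin_width = 1000)
  low <- hist$n[hist$bin_lower == 0 & hist$label == "non_cross_reactive"]
  dock <- descriptor_overlap(reference_docking(), "lowest_energy_kcal")
  list(
    cr = cr,
    classification = cls,
    histogram = hist,
    n_noncross_below_1000 = if (length(low)) low else 0L,
    min_cross_reactive_score = min(bet$ring_sum[bet$label == "cross_reactive"]),
    n_measurable_cr_compounds = nrow(meas),
    docking = dock
  )
}
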