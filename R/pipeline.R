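#' Validate a pipeline configuration
#'
#' Parses a YAML config (path or literal text), applies defaults
#' (clustering cutoff 0.6 nm, 1-ns blocks, 298 K heat bath, and the standard
#' system sizes), rejects unknown keys by name, and range-checks every
#' physical parameter.
#'
#' Recognised keys (all optional):
#' \preformatted{
#' seed:        integer
#' out_dir:     path for report outputs
#' clustering:  {cutoff, block, contact_tol}
#' membrane:    {grid_n, bin_width}
#' simulation:  {n_particles, temperature, friction, timestep, n_steps,
#'               stride, box, with_membrane_well, well_depth,
#'               interface_barrier}
#' bilayer:     {n_lipids_per_leaflet, target_area_per_lipid,
#'               target_thickness, tail_beads_per_lipid, tilt_concentration}
#' potential:   {n_orientations}
#' }
#'
#' @param raw path to a YAML file, or YAML text, or an empty string for all
#'   defaults.
#' @return object of class `pipeline_config` (a named list).
#' @export
validate_config <- function(raw = "") {
  parsed <- if (file.exists(raw)) yaml::read_yaml(raw) else
    yaml::yaml.load(raw)
  if (is.null(parsed)) parsed <- list()

  defaults <- list(
    seed = 1L,
    out_dir = "fullermem-report",
    clustering = list(cutoff = 0.6, block = 1000, contact_tol = 0.1),
    membrane = list(grid_n = 20L, bin_width = 0.2),
    simulation = list(n_particles = 6L, temperature = 298, friction = 6.9,
                      timestep = 0.5, n_steps = 200000L, stride = 2000L,
                      box = c(6.2, 6.2, 9.0), with_membrane_well = FALSE,
                      well_depth = 20, interface_barrier = 1),
    bilayer = list(n_lipids_per_leaflet = 64L, target_area_per_lipid = 0.599,
                   target_thickness = 4.26, tail_beads_per_lipid = 8L,
                   tilt_concentration = 20),
    potential = list(n_orientations = 60L)
  )
  merge1 <- function(def, got, where) {
    unknown <- setdiff(names(got), names(def))
    if (length(unknown)) {
      stop("config error: unknown key(s) ", where,
           paste(unknown, collapse = ", "))
    }
    for (k in names(got)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(got[[k]])) {
        merge1(def[[k]], got[[k]], paste0(where, k, "."))
      } else got[[k]]
    }
    def
  }
  cfg <- merge1(defaults, parsed, "")

  chk <- function(ok, what) if (!ok) stop("config error: ", what)
  chk(cfg$clustering$cutoff > 0, "clustering.cutoff must be > 0")
  chk(cfg$clustering$block > 0, "clustering.block must be > 0")
  chk(cfg$clustering$contact_tol > 0, "clustering.contact_tol must be > 0")
  chk(cfg$membrane$grid_n >= 4, "membrane.grid_n must be >= 4")
  chk(cfg$membrane$bin_width > 0, "membrane.bin_width must be > 0")
  chk(cfg$simulation$temperature >= 0,
      "simulation.temperature must be >= 0")
  chk(cfg$simulation$timestep > 0, "simulation.timestep must be > 0")
  chk(cfg$simulation$friction > 0, "simulation.friction must be > 0")
  chk(cfg$simulation$n_particles >= 1, "simulation.n_particles must be >= 1")
  chk(all(cfg$simulation$box > 0), "simulation.box lengths must be > 0")
  chk(cfg$bilayer$target_thickness > 0,
      "bilayer.target_thickness must be > 0")
  chk(cfg$bilayer$target_area_per_lipid > 0,
      "bilayer.target_area_per_lipid must be > 0")
  chk(cfg$potential$n_orientations >= 1,
      "potential.n_orientations must be >= 1")
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(tf))
}

#' Run the end-to-end analysis pipeline
#'
#' generate -> cluster analysis -> membrane analysis -> report. Simulates an
#' aggregation trajectory under the config, computes the largest-cluster
#' series, nucleus lifetimes and the final-frame motif; builds the synthetic
#' bilayer, injects the energy-minimum cluster of the aggregated size at the
#' preferred 1.0 nm depth, and computes depth series, density profiles, the
#' order parameter and grid thickness / area per lipid. Writes a
#' machine-readable JSON report (plus CSV series) embedding the config hash
#' and seed; identical config + seed reproduce the report byte for byte.
#'
#' @param config a [validate_config()] result (or a YAML path/text handed to
#'   it).
#' @param write_files write report files under `config$out_dir`
#'   (default TRUE); the report list is returned either way.
#' @return the report, invisibly a list with elements `cluster_series`,
#'   `motif`, `nucleus_lifetimes`, `depth_series`, `density_profile`,
#'   `membrane_summary`, `meta`.
#' @export
run_pipeline <- function(config = validate_config(), write_files = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  pot <- stage("potential", build_effective_potential(
    n_orientations = cfg$potential$n_orientations, seed = cfg$seed))

  sim <- cfg$simulation
  box <- simulation_box(as.numeric(sim$box),
                        periodic = c(TRUE, TRUE, !sim$with_membrane_well))
  mw <- NULL
  if (isTRUE(sim$with_membrane_well)) {
    mw <- membrane_well_spec(center_z = sim$box[3] / 2,
                             half_thickness = cfg$bilayer$target_thickness / 2,
                             well_depth = sim$well_depth,
                             interface_barrier = sim$interface_barrier)
  }
  traj <- stage("simulate", simulate_aggregation(
    aggregation_params(n_particles = sim$n_particles, box = box,
                       temperature = sim$temperature,
                       friction = sim$friction, timestep = sim$timestep,
                       n_steps = sim$n_steps, stride = sim$stride,
                       seed = cfg$seed, membrane = mw), pot))

  series <- stage("cluster-analysis", largest_cluster_series(
    traj, cutoff = cfg$clustering$cutoff, block = cfg$clustering$block))
  nuc <- stage("cluster-analysis", nucleus_lifetimes(series))
  final_assign <- stage("cluster-analysis", cluster_frame(
    traj$positions[[length(traj$positions)]], cutoff = cfg$clustering$cutoff,
    box = traj$box, radius = traj$radius))
  big <- final_assign$partition[[which.max(lengths(final_assign$partition))]]
  motif <- if (length(big) >= 2L && length(big) <= 6L) {
    stage("cluster-analysis", motif_classify(
      traj$positions[[length(traj$positions)]][big, , drop = FALSE],
      contact_tol = cfg$clustering$contact_tol))
  } else "singleton"

  bil <- cfg$bilayer
  bspec <- bilayer_spec(n_lipids_per_leaflet = bil$n_lipids_per_leaflet,
                        target_area_per_lipid = bil$target_area_per_lipid,
                        target_thickness = bil$target_thickness,
                        tail_beads_per_lipid = bil$tail_beads_per_lipid,
                        tilt_concentration = bil$tilt_concentration,
                        seed = cfg$seed)
  bframe <- stage("membrane-analysis", build_synthetic_bilayer(bspec))
  mc <- membrane_center(bframe)
  nmin <- min(max(lengths(final_assign$partition)), 6L)
  injected <- stage("membrane-analysis", {
    fr <- bframe
    if (nmin >= 1L) {
      coords <- if (nmin >= 2L) {
        optimize_cluster(max(nmin, 2L), n_restarts = 10L, seed = cfg$seed,
                         potential = pot)$com_coords
      } else matrix(0, 1, 3)
      for (i in seq_len(nrow(coords))) {
        ball <- build_c60(center = coords[i, ], ball_id = i)
        fr <- inject_ball_into_bilayer(fr, ball, depth = 1.0 + coords[i, 3])
      }
    }
    fr
  })
  depth <- stage("membrane-analysis", insertion_depth(
    list(injected), reference_half_thickness = mc$half_thickness))
  prof <- stage("membrane-analysis", density_profile(
    list(injected), bin_width = cfg$membrane$bin_width))
  op <- stage("membrane-analysis", order_parameter(injected))
  grids <- stage("membrane-analysis", grid_thickness_apl(
    injected, grid_n = cfg$membrane$grid_n))

  report <- list(
    meta = list(package_version = as.character(utils::packageVersion("fullermem")),
                seed = cfg$seed, config_hash = .config_hash(cfg),
                config = unclass(cfg)),
    cluster_series = as.list(series),
    nucleus_lifetimes = as.list(nuc),
    motif = motif,
    depth_series = as.list(as.data.frame(depth)),
    density_profile = as.list(as.data.frame(prof)),
    membrane_summary = list(
      thickness_nm = grids$mean_thickness,
      area_per_lipid_top_nm2 = grids$mean_apl_top,
      area_per_lipid_bottom_nm2 = grids$mean_apl_bottom,
      order_parameter_scd = op$S_cd,
      n_lipids = op$n_lipids)
  )
  if (write_files) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10)
    write.csv(as.data.frame(series),
              file.path(cfg$out_dir, "cluster_series.csv"), row.names = FALSE)
    write.csv(as.data.frame(prof),
              file.path(cfg$out_dir, "density_profile.csv"),
              row.names = FALSE)
    writeLines(c(sprintf("fullermem %s", report$meta$package_version),
                 sprintf("seed %d", cfg$seed),
                 sprintf("config_hash %s", report$meta$config_hash)),
               file.path(cfg$out_dir, "run.log"))
  }
  invisible(report)
}
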