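#' Configuration, serialization and command-line entry points
#'
#' A study is fully described by a JSON configuration with the top-level
#' keys `geometry`, `contact`, `drive`, `sim`, `loads`, `scenarios`,
#' `grid`, `output_dir` and `seed`. Unknown keys anywhere in the document
#' are rejected with the offending key named. Every output directory
#' receives a `provenance.json` carrying the configuration hash, seed and
#' package version.
#'
#' @name io-cli
NULL

STUDY_SCHEMA <- list(
  geometry = names(formals(geometry_config)),
  contact = c("kc_uh", "kc_rh", "n", "Bmax", "dmax"),
  drive = c("total_displacement", "duration", "profile"),
  sim = c("solver", "n_steps", "tol", "max_flexion", "max_step_halvings",
          "separation_bound"),
  loads = c("triceps", "brachialis", "gravity"),
  scenarios = NULL, grid = NULL, output_dir = NULL, seed = NULL)

#' Read and validate a study configuration
#'
#' @param path JSON file path, or a list already in memory.
#' @return validated configuration list of class `study_config` with all
#'   defaults filled in.
#' @export
read_study_config <- function(path) {
  cfg <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else path
  unknown <- setdiff(names(cfg), names(STUDY_SCHEMA))
  if (length(unknown))
    stop("unknown configuration key: '", unknown[1], "'")
  for (sec in c("geometry", "contact", "drive", "sim", "loads")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), STUDY_SCHEMA[[sec]])
      if (length(bad))
        stop("unknown configuration key: '", sec, ".", bad[1], "'")
    }
  }
  geo_args <- cfg$geometry %||% list()
  for (f in c("ligament_k", "prestrain"))
    if (is.list(geo_args[[f]])) geo_args[[f]] <- unlist(geo_args[[f]])
  if (!is.null(cfg$seed) && is.null(geo_args$seed))
    geo_args$seed <- cfg$seed
  ct <- cfg$contact %||% list()
  contact <- list(
    uh = contact_parameters(kc = ct$kc_uh %||% 126, n = ct$n %||% 1,
                            Bmax = ct$Bmax %||% 2, dmax = ct$dmax %||% 0.1),
    rh = contact_parameters(kc = ct$kc_rh %||% 105, n = ct$n %||% 1,
                            Bmax = ct$Bmax %||% 2, dmax = ct$dmax %||% 0.1))
  dr <- cfg$drive %||% list()
  drive <- motion_drive(
    total_displacement = dr$total_displacement %||% 345,
    duration = dr$duration %||% 40,
    profile = dr$profile %||% "linear")
  sm <- cfg$sim %||% list()
  sim <- simulation_config(
    solver = sm$solver %||% "quasistatic",
    n_steps = sm$n_steps %||% 160,
    tol = sm$tol %||% 1e-3,
    max_flexion = sm$max_flexion %||% 135,
    max_step_halvings = sm$max_step_halvings %||% 6,
    separation_bound = sm$separation_bound %||% 10,
    seed = cfg$seed %||% 1L)
  ld <- cfg$loads %||% list()
  loads <- external_loads(
    muscle_tensions = c(triceps = ld$triceps %||% 40,
                        brachialis = ld$brachialis %||% 20),
    gravity = ld$gravity %||% TRUE)
  structure(list(
    geometry = do.call(geometry_config, geo_args),
    contact = contact, drive = drive, sim = sim, loads = loads,
    scenarios = cfg$scenarios %||% SCENARIOS,
    grid = cfg$grid %||% c(50, 130, 2),
    output_dir = cfg$output_dir %||% "elbowmbs_out",
    seed = cfg$seed %||% 1L), class = "study_config")
}

#' Serialize a study configuration to JSON
#' @param config a `study_config`.
#' @param path output path.
#' @export
write_study_config <- function(config, path) {
  g <- unclass(config$geometry)
  # named vectors must serialize as JSON objects, not arrays
  g$ligament_k <- as.list(g$ligament_k)
  g$prestrain <- as.list(g$prestrain)
  out <- list(
    geometry = g,
    contact = list(kc_uh = config$contact$uh$kc, kc_rh = config$contact$rh$kc,
                   n = config$contact$uh$n, Bmax = config$contact$uh$Bmax,
                   dmax = config$contact$uh$dmax),
    drive = unclass(config$drive)[c("total_displacement", "duration",
                                    "profile")],
    sim = unclass(config$sim)[c("solver", "n_steps", "tol", "max_flexion",
                                "max_step_halvings", "separation_bound")],
    loads = list(triceps = unname(config$loads$muscle_tensions["triceps"]),
                 brachialis = unname(config$loads$muscle_tensions["brachialis"]),
                 gravity = config$loads$gravity),
    scenarios = config$scenarios, grid = config$grid,
    output_dir = config$output_dir, seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- atlas / landmarks JSON --------------------------------------------

#' Write the ligament attachment atlas and landmarks as JSON
#'
#' Document keys: `bundles` (list with `name`, `complex`, `origin_body`,
#' `origin`, `insertion_body`, `insertion`, `k`, `eps_l`, `l0`, `c`,
#' `active`, `wrap` with primitive `type`/`body`/`center`/`axis`/`radius`)
#' and `landmarks` (per body, named 3-vectors, mm, body frame).
#'
#' @param geo an `elbow_geometry`.
#' @param path output JSON path.
#' @export
write_atlas_json <- function(geo, path) {
  bundles <- lapply(geo$atlas$bundles, function(b) {
    list(name = b$name, complex = b$complex,
         origin_body = b$origin_body, origin = b$origin,
         insertion_body = b$insertion_body, insertion = b$insertion,
         k = b$k, eps_l = b$eps_l, l0 = b$l0, c = b$c, active = b$active,
         wrap = lapply(b$wrap_primitives, function(p)
           list(type = p$type, body = p$body, center = p$center,
                axis = p$axis, radius = p$radius)))
  })
  jsonlite::write_json(list(bundles = bundles, landmarks = geo$landmarks),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an attachment atlas JSON back
#' @param path JSON path.
#' @return list with `atlas` (a `ligament_atlas`) and `landmarks`.
#' @export
read_atlas_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  bundles <- lapply(doc$bundles, function(b) {
    prims <- lapply(b$wrap %||% list(), function(p) {
      if (p$type == "sphere")
        wrap_sphere(p$body, unlist(p$center), p$radius)
      else wrap_cylinder(p$body, unlist(p$center), unlist(p$axis), p$radius)
    })
    ligament_bundle(b$name, b$complex, b$origin_body, unlist(b$origin),
                    b$insertion_body, unlist(b$insertion), k = b$k,
                    eps_l = b$eps_l, l0 = b$l0, c = b$c,
                    wrap_primitives = prims, active = isTRUE(b$active))
  })
  landmarks <- lapply(doc$landmarks, function(lm) lapply(lm, unlist))
  list(atlas = structure(list(bundles = bundles, scenario = "intact"),
                         class = "ligament_atlas"),
       landmarks = landmarks)
}

#' Write geometry files (meshes + atlas + landmarks)
#'
#' Bone meshes as STL, cartilage meshes as OBJ, the atlas/landmark
#' document as JSON.
#' @param geo an `elbow_geometry`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_geometry <- function(geo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bn in names(geo$bone_meshes))
    write_stl(geo$bone_meshes[[bn]], file.path(dir, paste0(bn, ".stl")),
              name = bn)
  for (cn in names(geo$cartilage_meshes))
    write_obj(geo$cartilage_meshes[[cn]],
              file.path(dir, paste0("cartilage_", cn, ".obj")), name = cn)
  write_atlas_json(geo, file.path(dir, "atlas.json"))
  invisible(dir)
}

#' Read user-supplied geometry files back
#'
#' Reads the meshes and atlas document written by [write_geometry()] (or
#' equivalently structured user files). The result carries surfaces and
#' attachments only; running a simulation additionally needs the
#' parametric configuration (see [generate_elbow()]).
#'
#' @param dir directory with `*.stl`, `cartilage_*.obj` and `atlas.json`.
#' @return list with `bone_meshes`, `cartilage_meshes`, `atlas`,
#'   `landmarks`.
#' @export
read_geometry <- function(dir) {
  stls <- list.files(dir, pattern = "\\.stl$", full.names = TRUE)
  objs <- list.files(dir, pattern = "^cartilage_.*\\.obj$", full.names = TRUE)
  bones <- stats::setNames(lapply(stls, read_stl, open = TRUE),
                           sub("\\.stl$", "", basename(stls)))
  carts <- stats::setNames(
    lapply(objs, read_obj, open = TRUE),
    sub("^cartilage_(.*)\\.obj$", "\\1", basename(objs)))
  at <- read_atlas_json(file.path(dir, "atlas.json"))
  list(bone_meshes = bones, cartilage_meshes = carts,
       atlas = at$atlas, landmarks = at$landmarks)
}

# ---- trace CSV export ---------------------------------------------------

#' Write a simulation trace as CSV files
#'
#' `steps.csv` (one row per accepted step), `kinematics.csv` (per step and
#' body JCS samples), `contact.csv` and `ligaments.csv` (per step
#' element/bundle states).
#' @param trace a `simulation_trace`.
#' @param dir output directory.
#' @export
write_trace_csv <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trace$steps, file.path(dir, "steps.csv"),
                   row.names = FALSE)
  poses <- do.call(rbind, Map(function(po, s, t_) {
    do.call(rbind, lapply(names(po), function(bn) {
      q <- matrix_to_quat(po[[bn]]$R)
      data.frame(step = s, time = t_, body = bn,
                 x = po[[bn]]$position[1], y = po[[bn]]$position[2],
                 z = po[[bn]]$position[3],
                 qw = q[1], qx = q[2], qy = q[3], qz = q[4])
    }))
  }, trace$poses, trace$steps$step, trace$steps$time))
  utils::write.csv(poses, file.path(dir, "poses.csv"), row.names = FALSE)
  utils::write.csv(trace$kin, file.path(dir, "kinematics.csv"),
                   row.names = FALSE)
  ct <- do.call(rbind, Map(function(d, s, t_, fl) {
    d$step <- s; d$time <- t_; d$flexion <- fl; d
  }, trace$contact, trace$steps$step, trace$steps$time, trace$steps$flexion))
  utils::write.csv(ct, file.path(dir, "contact.csv"), row.names = FALSE)
  lg <- do.call(rbind, Map(function(d, s, t_, fl) {
    d$step <- s; d$time <- t_; d$flexion <- fl; d
  }, trace$ligament, trace$steps$step, trace$steps$time,
  trace$steps$flexion))
  utils::write.csv(lg, file.path(dir, "ligaments.csv"), row.names = FALSE)
  invisible(dir)
}

write_provenance <- function(dir, config, extra = list()) {
  jsonlite::write_json(
    c(list(package = "elbowmbs",
           version = as.character(utils::packageVersion("elbowmbs")),
           config_hash = config_hash(config),
           seed = config$seed), extra),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
}

# ---- command-line entry points -----------------------------------------

#' Command-line operations
#'
#' Thin entry points for shell use (see `inst/exec/elbowmbs`):
#' `cli_generate` writes the synthetic geometry files, `cli_simulate`
#' runs one scenario and writes its trace, `cli_report` runs the full
#' study and writes the report bundle. All take a JSON study
#' configuration.
#'
#' @param config_path path to the JSON study configuration.
#' @param out_dir output directory (defaults to the configuration's
#'   `output_dir`).
#' @param scenario scenario name for `cli_simulate`.
#' @return the output directory, invisibly.
#' @export
cli_generate <- function(config_path, out_dir = NULL) {
  cfg <- read_study_config(config_path)
  geo <- generate_elbow(cfg$geometry)
  dir <- out_dir %||% file.path(cfg$output_dir, "geometry")
  write_geometry(geo, dir)
  write_provenance(dir, cfg)
  message("geometry written to ", dir)
  invisible(dir)
}

#' @rdname cli_generate
#' @export
cli_simulate <- function(config_path, scenario = "intact", out_dir = NULL) {
  cfg <- read_study_config(config_path)
  if (!scenario %in% SCENARIOS)
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(SCENARIOS, collapse = ", "))
  geo <- generate_elbow(cfg$geometry)
  dir <- out_dir %||% file.path(cfg$output_dir, scenario)
  atlas <- section_bundles(geo$atlas, scenario)
  sys <- assemble_system(geo, atlas = atlas, contact = cfg$contact,
                         loads = cfg$loads)
  trace <- run_flexion_sim(sys, cfg$drive, cfg$sim)
  write_trace_csv(trace, dir)
  write_provenance(dir, cfg, extra = list(
    scenario = scenario, steps = nrow(trace$steps),
    max_residual = max(trace$steps$residual)))
  message("trace written to ", dir, " (", nrow(trace$steps), " steps)")
  invisible(dir)
}

#' @rdname cli_generate
#' @export
cli_report <- function(config_path, out_dir = NULL) {
  cfg <- read_study_config(config_path)
  geo <- generate_elbow(cfg$geometry)
  dir <- out_dir %||% file.path(cfg$output_dir, "report")
  results <- run_study(geo, scenarios = cfg$scenarios, drive = cfg$drive,
                       sim_config = cfg$sim, contact = cfg$contact,
                       loads = cfg$loads, grid = cfg$grid,
                       cache_dir = file.path(cfg$output_dir, "cache"))
  stats <- study_statistics(results)
  build_report(results, stats, dir = dir)
  write_study_config(cfg, file.path(dir, "study_config.json"))
  write_provenance(dir, cfg, extra = list(scenarios = names(results)))
  message("report written to ", dir)
  invisible(dir)
}
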