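#' Default run configuration
#'
#' Nested list of every tunable parameter the pipeline commands accept,
#' with the documented defaults. Unknown keys in a user configuration are
#' rejected, so typos never silently fall back to defaults.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    barrel = list(
      axis_length = 40, inner_radius = 3.3, ring_spacing = 1,
      atoms_per_ring = 16, residues = "ILE", atom_vdw = 1.7
    ),
    # the surrogate ligand arms must reach within the contact cutoff of the
    # default barrel wall (atom centers at inner_radius + atom_vdw = 5 A)
    ligand = list(bond = c("C10", "C19"), bond_length = 2.4, width = 3.0),
    profile = list(
      probe_radius = 3.0, interior_threshold = 1.25, grid = 0.25,
      contact_cutoff = 2.4, sasa_probe = 1.4, sasa_points = 960, step = 1.0
    ),
    kinetics = list(
      A = 475, b = 2.75, forces = 6:23, n_rep = 4, sigma = 0.3,
      weighting = "replicate"
    ),
    langevin = list(
      enabled = FALSE, L = 40, gamma = 1, temperature = 310,
      forces = c(2, 4, 8), dt = 0.002, n_rep = 50, max_steps = 1e6
    ),
    biophysics = list(
      surface_tension = c(0.020, 0.033), r_hdl_A = 50, r_ldl_A = 110,
      tunnel_diameter_A = 6, cetp_mass_Da = 73000, ce_mass_Da = 651
    )
  )
}

# Merge a user config (list or YAML path) over the defaults, rejecting
# unknown keys at any level.
resolve_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merge_over <- function(def, usr, path = character()) {
    extra <- setdiff(names(usr), names(def))
    if (length(extra) > 0) {
      rlang::abort(paste0(
        "unknown config key(s): ",
        paste(paste(c(path, ""), collapse = "."), extra, sep = "", collapse = ", ")
      ))
    }
    for (k in names(usr)) {
      if (is.list(def[[k]]) && is.list(usr[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge_over(def[[k]], usr[[k]], c(path, k))
      } else {
        def[[k]] <- usr[[k]]
      }
    }
    def
  }
  merge_over(default_config(), config)
}

cet_log <- function(log_file, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE, sep = "")
  message(line)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Manifest is deliberately timestamp-free so a rerun with the same
# configuration is byte-identical.
write_manifest <- function(out_dir, command, config, inputs, outputs) {
  manifest <- list(
    package = "cetransit",
    version = as.character(utils::packageVersion("cetransit")),
    command = command,
    config = config,
    inputs = inputs,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Generate a complete synthetic dataset bundle
#'
#' Writes a barrel structure (PDB), a ligand trajectory through it
#' (multi-model PDB), a replicated force-time table (CSV) and, when the
#' Langevin block is enabled, first-passage times, together with a
#' manifest holding the full configuration and output checksums. Reruns
#' with the same configuration are byte-identical.
#'
#' @param config Configuration list or YAML file path; see
#'   [default_config()]. Must contain a `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(config = list(), out_dir) {
  cfg <- resolve_config(config)
  if (is.null(cfg$seed)) rlang::abort("config must provide a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  cet_log(log_file, "simulate: seed ", cfg$seed)

  bar <- do.call(make_barrel, cfg$barrel)
  pdb_path <- file.path(out_dir, "barrel.pdb")
  write_pdb(bar$structure, pdb_path)

  lig <- make_ligand(cfg$ligand$bond, cfg$ligand$bond_length, cfg$ligand$width)
  traj <- make_ligand_trajectory(bar$path, lig, bond = cfg$ligand$bond)
  traj_path <- file.path(out_dir, "trajectory.pdb")
  write_pdb(traj$frames, traj_path)

  kin <- cfg$kinetics
  tbl <- sample_transfer_times(
    kin$A, kin$b, kin$forces,
    n_rep = kin$n_rep, sigma = kin$sigma, seed = cfg$seed
  )
  csv_path <- file.path(out_dir, "force_times.csv")
  utils::write.csv(tbl, csv_path, row.names = FALSE, quote = FALSE)

  outputs <- c(pdb_path, traj_path, csv_path)
  if (isTRUE(cfg$langevin$enabled)) {
    lg <- cfg$langevin
    fp <- dplyr::bind_rows(lapply(lg$forces, function(f) {
      out <- langevin_first_passage(
        L = lg$L, gamma = lg$gamma, temperature = lg$temperature,
        force = f, dt = lg$dt, n_rep = lg$n_rep,
        max_steps = lg$max_steps, seed = cfg$seed + round(f * 1000)
      )
      out$force <- f
      out
    }))
    fp_path <- file.path(out_dir, "langevin_first_passage.csv")
    utils::write.csv(fp, fp_path, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, fp_path)
  }
  cet_log(log_file, "simulate: wrote ", length(outputs), " files")
  invisible(write_manifest(out_dir, "simulate", cfg, inputs = list(), outputs = outputs))
}

#' Profile a tunnel structure against a ligand trajectory
#'
#' Reads a structure PDB and a multi-model trajectory PDB, takes the
#' per-frame ligand centroids as the transfer path, and writes TSV
#' profiles: tunnel diameter, SASA-weighted hydrophobicity, per-frame
#' contact residues, and the bond orientation angle, plus a manifest and
#' run log.
#'
#' @param structure_file Protein/barrel PDB path.
#' @param trajectory_file Multi-model ligand PDB path.
#' @param config Configuration list or YAML path; `profile` and `ligand`
#'   blocks are used.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
run_profile <- function(structure_file, trajectory_file, config = list(), out_dir) {
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")

  structure <- read_pdb(structure_file)
  frames <- read_pdb_trajectory(trajectory_file)
  if (nrow(frames) == 0) rlang::abort("empty trajectory")
  bond <- cfg$ligand$bond
  # fail before any computation if the designated bond is absent
  for (fr in split(frames, frames$frame)) {
    if (!all(bond %in% fr$name)) {
      rlang::abort(paste0(
        "designated bond atoms ", paste(bond, collapse = "-"),
        " missing from trajectory frame ", fr$frame[1]
      ))
    }
  }
  cet_log(
    log_file, "profile: ", nrow(structure), " atoms, ",
    length(unique(frames$frame)), " frames"
  )

  centroids <- dplyr::summarise(
    dplyr::group_by(frames, .data$frame),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z), .groups = "drop"
  )
  seg <- sqrt(diff(centroids$x)^2 + diff(centroids$y)^2 + diff(centroids$z)^2)
  path <- tibble::tibble(
    x = centroids$x, y = centroids$y, z = centroids$z,
    arclength = c(0, cumsum(seg))
  )
  frames$arclength <- path$arclength[match(frames$frame, centroids$frame)]
  traj <- structure(list(frames = frames, bond = bond), class = "ligand_trajectory")

  prof <- cfg$profile
  dia <- diameter_profile(
    structure, path,
    probe_radius = prof$probe_radius,
    interior_threshold = prof$interior_threshold, grid = prof$grid
  )
  hyd <- hydrophobicity_profile(
    structure, traj,
    step = prof$step, cutoff = prof$contact_cutoff,
    probe_radius = prof$sasa_probe, n_points = prof$sasa_points
  )
  contacts <- dplyr::bind_rows(lapply(split(frames, frames$frame), function(f) {
    ct <- contact_residues(structure, f, cutoff = prof$contact_cutoff)
    if (nrow(ct) == 0) return(NULL)
    ct$frame <- f$frame[1]
    ct$arclength <- f$arclength[1]
    ct
  }))
  ori <- orientation_angle(traj)

  paths <- c(
    diameter = file.path(out_dir, "diameter_profile.tsv"),
    hydrophobicity = file.path(out_dir, "hydrophobicity_profile.tsv"),
    contacts = file.path(out_dir, "contact_residues.tsv"),
    orientation = file.path(out_dir, "orientation_angle.tsv")
  )
  write_tsv_file(dia, paths["diameter"])
  write_tsv_file(hyd, paths["hydrophobicity"])
  write_tsv_file(
    if (is.null(contacts)) data.frame(chain = character(), resseq = integer(),
                                      resname = character(), frame = integer(),
                                      arclength = double())
    else contacts,
    paths["contacts"]
  )
  write_tsv_file(ori, paths["orientation"])
  cet_log(log_file, "profile: wrote 4 profile tables")
  invisible(write_manifest(
    out_dir, "profile", cfg,
    inputs = list(structure = basename(structure_file),
                  trajectory = basename(trajectory_file)),
    outputs = unname(paths)
  ))
}

#' Fit transfer kinetics and project to physiological driving forces
#'
#' Reads a force-time CSV (replicate rows `force,replicate,time_ns` or an
#' aggregated table with `mean_ns`), fits the power law, and - using the
#' biophysics block of the configuration - reports the Laplace-pressure
#' driving-force span with the predicted per-molecule transfer times and
#' rates, each flagged as extrapolation when outside the fitted force
#' range.
#'
#' @param table_file CSV path.
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
run_kinetics <- function(table_file, config = list(), out_dir) {
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")

  tbl <- tryCatch(
    utils::read.csv(table_file),
    error = function(e) rlang::abort(paste0("malformed CSV: ", conditionMessage(e)))
  )
  if (!"force" %in% names(tbl)) rlang::abort("CSV lacks a 'force' column")
  tcol <- if ("time_ns" %in% names(tbl)) "time_ns" else "mean_ns"
  if (!tcol %in% names(tbl)) rlang::abort("CSV lacks a time_ns or mean_ns column")
  bad <- which(!is.finite(tbl[[tcol]]) | tbl[[tcol]] <= 0 |
                 !is.finite(tbl$force) | tbl$force <= 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("nonpositive or missing value at CSV row ", bad[1]))
  }

  fit <- fit_power_law(tibble::as_tibble(tbl), weighting = cfg$kinetics$weighting)
  cet_log(log_file, sprintf(
    "kinetics: A = %.4g, b = %.4g, |r| = %.4f (n = %d)", fit$A, fit$b, abs(fit$r), fit$n
  ))

  bio <- cfg$biophysics
  pred <- physiological_prediction(
    fit, bio$surface_tension,
    r_hdl_A = bio$r_hdl_A, r_ldl_A = bio$r_ldl_A,
    tunnel_diameter_A = bio$tunnel_diameter_A
  )

  fit_path <- file.path(out_dir, "power_law_fit.txt")
  g <- glance(fit)
  writeLines(
    c(
      sprintf("A_ns %.10g", g$A),
      sprintf("b %.10g", g$b),
      sprintf("r %.10g", g$r),
      sprintf("n %d", g$n),
      sprintf("force_min %.10g", g$force_min),
      sprintf("force_max %.10g", g$force_max)
    ),
    fit_path
  )
  resid_path <- file.path(out_dir, "residuals.tsv")
  used <- if (fit$weighting == "replicate" && "time_ns" %in% names(tbl)) {
    tibble::tibble(force = tbl$force, time_ns = tbl$time_ns)
  } else {
    s <- if ("mean_ns" %in% names(tbl)) {
      tibble::tibble(force = tbl$force, time_ns = tbl$mean_ns)
    } else {
      dplyr::summarise(dplyr::group_by(tibble::as_tibble(tbl), .data$force),
                       time_ns = mean(.data$time_ns), .groups = "drop")
    }
    s
  }
  used$predicted_ns <- fit$A * used$force^(-fit$b)
  used$log_residual <- log(used$time_ns) - log(used$predicted_ns)
  write_tsv_file(used, resid_path)

  pred_path <- file.path(out_dir, "physiological_prediction.tsv")
  write_tsv_file(pred, pred_path)
  cet_log(log_file, sprintf(
    "kinetics: physiological span %.3g-%.3g s/CE (%.3g-%.3g CE/s)%s",
    min(pred$time_s), max(pred$time_s), min(pred$rate_per_s), max(pred$rate_per_s),
    if (any(pred$extrapolated, na.rm = TRUE)) " [extrapolation]" else ""
  ))
  invisible(write_manifest(
    out_dir, "kinetics", cfg,
    inputs = list(table = basename(table_file)),
    outputs = c(fit_path, resid_path, pred_path)
  ))
}
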