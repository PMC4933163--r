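# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  ct <- 1 - 2 * i / n
  st <- sqrt(pmax(0, 1 - ct^2))
  cbind(st * cos(phi), st * sin(phi), ct)
}

# clearance of a single point: min over atoms of (center distance - vdW radius)
point_clearance <- function(p, xyz, radii) {
  d2 <- (xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2
  min(sqrt(d2) - radii)
}

# Max clearance over candidate centers `cand` (m x 3) against atoms
# `xyz` (k x 3). Returns list(value, center).
best_clearance <- function(cand, xyz, radii) {
  dx <- outer(cand[, 1], xyz[, 1], "-")
  dy <- outer(cand[, 2], xyz[, 2], "-")
  dz <- outer(cand[, 3], xyz[, 3], "-")
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  cl <- d - rep(radii, each = nrow(cand))
  dim(cl) <- dim(d)
  val <- apply(cl, 1, min)
  i <- which.max(val)
  list(value = val[i], center = cand[i, ])
}

# cubic grid offsets with |offset| <= radius
ball_grid <- function(radius, spacing) {
  g <- seq(-radius, radius, by = spacing)
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  off[rowSums(off^2) <= radius^2, , drop = FALSE]
}

#' Tunnel diameter profile along a transfer path
#'
#' At each path point the local clearance is the largest sphere radius
#' achievable by a probe center within `probe_radius` of the point:
#' clearance(c) = min over atoms of (|c - x_i| - r_i), maximised over
#' candidate centers on a `grid`-spaced lattice inside the probe ball and
#' sharpened by one finer local refinement pass. The diameter is twice the
#' clearance (clamped at zero); a point is "open" when the clearance
#' reaches `interior_threshold`, the minimum sphere radius for a position
#' to count as channel interior.
#'
#' @param structure Atom table with vdW radii assigned.
#' @param path Transfer path tibble (`x`, `y`, `z`, `arclength`).
#' @param probe_radius Search radius for the probe center, angstroms.
#' @param interior_threshold Minimum open-channel clearance radius,
#'   angstroms.
#' @param grid Candidate-center lattice spacing, angstroms.
#' @return Tibble with `arclength`, `diameter` (angstroms), `open`
#'   (logical), `outside` (logical: path point farther than 50 angstroms
#'   from every atom).
#' @export
diameter_profile <- function(structure, path, probe_radius = 3.0,
                             interior_threshold = 1.25, grid = 0.25) {
  check_structure(structure)
  stopifnot(probe_radius > 0, interior_threshold > 0, grid > 0)
  xyz <- coords(structure)
  radii <- structure$vdw_radius
  offsets <- ball_grid(probe_radius, grid)
  fine <- ball_grid(grid, grid / 5)

  res <- purrr::map(seq_len(nrow(path)), function(k) {
    p <- c(path$x[k], path$y[k], path$z[k])
    d0 <- point_clearance(p, xyz, radii)
    if (d0 > 50) {
      return(tibble::tibble(
        arclength = path$arclength[k], diameter = 2 * max(d0, 0),
        open = TRUE, outside = TRUE
      ))
    }
    # only atoms that can own the min for any candidate in the ball
    dp <- sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
    sel <- dp - radii <= d0 + 2 * probe_radius
    sub_xyz <- xyz[sel, , drop = FALSE]
    sub_r <- radii[sel]
    cand <- sweep(offsets, 2, p, "+")
    coarse <- best_clearance(cand, sub_xyz, sub_r)
    # local refinement around the best coarse center, kept inside the ball
    cand2 <- sweep(fine, 2, coarse$center, "+")
    keep <- colSums((t(cand2) - p)^2) <= probe_radius^2
    r_best <- coarse$value
    if (any(keep)) {
      refined <- best_clearance(cand2[keep, , drop = FALSE], sub_xyz, sub_r)
      r_best <- max(r_best, refined$value)
    }
    tibble::tibble(
      arclength = path$arclength[k],
      diameter = max(2 * r_best, 0),
      open = r_best >= interior_threshold,
      outside = FALSE
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("cet_diameter_profile", class(out))
  out
}

#' Greedy probe-sphere pathway search
#'
#' Step-by-step tunnel tracing: from the current point, candidate points
#' one `step_length` away within a cone about the previous direction are
#' scored by their clearance (distance to the nearest vdW surface); the
#' walker moves to the best candidate. The search ends when the exit
#' predicate holds, or at a dead end - no candidate keeps clearance at or
#' above `interior_threshold` - in which case the partial path is returned
#' with its `terminated_early` attribute set.
#'
#' @param structure Atom table with vdW radii.
#' @param entry Numeric 3-vector, the entry point (must have positive
#'   clearance).
#' @param exit_fn Predicate on a 3-vector: TRUE when the walker has
#'   reached the exit region.
#' @param step_length Advance per step, angstroms.
#' @param cone_half_angle Maximum turn per step, degrees.
#' @param initial_direction Optional unit 3-vector for the first step;
#'   defaults to the direction from `entry` to the atom centroid.
#' @param interior_threshold Dead-end clearance cutoff, angstroms.
#' @param n_directions Candidate directions sampled on the sphere.
#' @param max_steps Hard cap on steps.
#' @return Transfer path tibble (`x`, `y`, `z`, `arclength`) with
#'   attributes `terminated_early` (logical) and `reached_exit` (logical).
#' @export
path_search <- function(structure, entry, exit_fn,
                        step_length = 1.0, cone_half_angle = 45,
                        initial_direction = NULL,
                        interior_threshold = 1.25,
                        n_directions = 400, max_steps = 500) {
  check_structure(structure)
  stopifnot(length(entry) == 3, step_length > 0)
  xyz <- coords(structure)
  radii <- structure$vdw_radius
  if (point_clearance(entry, xyz, radii) <= 0) {
    rlang::abort("entry point has nonpositive clearance (inside an atom)")
  }
  dirs <- fibonacci_sphere(n_directions)
  cos_cone <- cos(cone_half_angle * pi / 180)

  dir_prev <- initial_direction
  if (is.null(dir_prev)) {
    dir_prev <- colMeans(xyz) - entry
  }
  nrm <- sqrt(sum(dir_prev^2))
  if (nrm < 1e-12) rlang::abort("degenerate initial direction")
  dir_prev <- dir_prev / nrm

  pts <- matrix(entry, nrow = 1)
  p <- entry
  terminated_early <- FALSE
  reached_exit <- FALSE
  for (step in seq_len(max_steps)) {
    ok <- drop(dirs %*% dir_prev) >= cos_cone
    cand_dirs <- dirs[ok, , drop = FALSE]
    cand <- sweep(cand_dirs * step_length, 2, p, "+")
    cl <- apply(
      sqrt(outer(cand[, 1], xyz[, 1], "-")^2 +
             outer(cand[, 2], xyz[, 2], "-")^2 +
             outer(cand[, 3], xyz[, 3], "-")^2) -
        rep(radii, each = nrow(cand)),
      1, min
    )
    i <- which.max(cl)
    if (cl[i] < interior_threshold) {
      terminated_early <- TRUE
      break
    }
    dir_prev <- cand_dirs[i, ]
    p <- cand[i, ]
    pts <- rbind(pts, p)
    if (exit_fn(p)) {
      reached_exit <- TRUE
      break
    }
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  out <- tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    arclength = c(0, cumsum(seg))
  )
  attr(out, "terminated_early") <- terminated_early
  attr(out, "reached_exit") <- reached_exit
  out
}

#' Residues in contact with a ligand frame
#'
#' A residue is in contact when any of its atoms lies strictly within
#' `cutoff` (center-to-center) of any ligand atom. The 2.4-angstrom
#' default is the diameter of a hydrogen vdW surface: two hydrogen
#' surfaces touch when their centers are 2.4 angstroms apart.
#'
#' @param structure Protein atom table.
#' @param ligand Ligand atom table (one frame).
#' @param cutoff Contact distance, angstroms; strict `<` comparison.
#' @param include_hydrogens Count hydrogen atoms on both sides? Default
#'   TRUE, since the cutoff is itself a hydrogen vdW diameter.
#' @return Tibble of contact residues: `chain`, `resseq`, `resname`.
#' @export
contact_residues <- function(structure, ligand, cutoff = 2.4,
                             include_hydrogens = TRUE) {
  check_structure(structure, require_radii = FALSE)
  check_structure(ligand, require_radii = FALSE, arg = "ligand")
  stopifnot(cutoff > 0)
  if (!include_hydrogens) {
    structure <- structure[structure$element != "H", , drop = FALSE]
    ligand <- ligand[ligand$element != "H", , drop = FALSE]
    if (nrow(structure) == 0 || nrow(ligand) == 0) {
      return(dplyr::distinct(structure[integer(0), c("chain", "resseq", "resname")]))
    }
  }
  sx <- coords(structure)
  lx <- coords(ligand)
  # per structure atom: squared distance to nearest ligand atom
  d2min <- rep(Inf, nrow(sx))
  for (j in seq_len(nrow(lx))) {
    d2 <- (sx[, 1] - lx[j, 1])^2 + (sx[, 2] - lx[j, 2])^2 + (sx[, 3] - lx[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  hit <- d2min < cutoff^2
  dplyr::distinct(
    structure[hit, c("chain", "resseq", "resname")]
  )
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's expanded sphere (vdW radius + probe) is sampled with a
#' deterministic Fibonacci-spiral point set; the accessible fraction times
#' the expanded-sphere area gives the atom SASA, summed per residue.
#'
#' @param structure Atom table with vdW radii.
#' @param probe_radius Solvent probe radius, angstroms (1.4 = water).
#' @param n_points Sample points per atom (>= 50).
#' @return Tibble with `chain`, `resseq`, `resname`, `area` (angstroms^2).
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  check_structure(structure)
  if (n_points < 50) rlang::abort("n_points below the accuracy floor of 50")
  xyz <- coords(structure)
  rr <- structure$vdw_radius + probe_radius
  sphere <- fibonacci_sphere(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    pts <- sweep(sphere * rr[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2j <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 + (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2j >= rr[j]^2
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / n_points * 4 * pi * rr[i]^2
  }
  out <- structure[, c("chain", "resseq", "resname")]
  out$area <- area
  dplyr::summarise(
    dplyr::group_by(out, .data$chain, .data$resseq, .data$resname),
    area = sum(.data$area), .groups = "drop"
  )
}

#' SASA-weighted hydrophobicity profile along a ligand trajectory
#'
#' For each arclength bin (default 1 angstrom) the contact residues of the
#' frames in that bin are scored by the Kyte-Doolittle scale and averaged
#' with weights proportional to each residue's solvent-accessible surface
#' area on the ligand-free structure:
#' value = sum_r w_r KD(r), w_r = SASA(r) / sum SASA(contacts).
#' Bins whose frames make no contact are flagged undefined. With several
#' trajectories the per-trajectory bin values are averaged and their
#' spread reported as `sd`.
#'
#' @param structure Protein atom table with vdW radii.
#' @param trajectory A `ligand_trajectory`, or a list of them (repeat
#'   runs).
#' @param scale Hydropathy scale (named vector).
#' @param step Arclength bin width, angstroms.
#' @param cutoff Contact distance, angstroms.
#' @param probe_radius,n_points Passed to [sasa()].
#' @param include_hydrogens Passed to [contact_residues()].
#' @return Tibble with `arclength` (bin midpoint), `value`, `sd`, `n`
#'   (trajectories contributing), `undefined` (logical).
#' @export
hydrophobicity_profile <- function(structure, trajectory,
                                   scale = kyte_doolittle(), step = 1.0,
                                   cutoff = 2.4, probe_radius = 1.4,
                                   n_points = 960, include_hydrogens = TRUE) {
  check_structure(structure)
  trajs <- if (inherits(trajectory, "ligand_trajectory")) list(trajectory) else trajectory
  stopifnot(length(trajs) >= 1, step > 0)
  areas <- sasa(structure, probe_radius = probe_radius, n_points = n_points)

  per_traj <- purrr::imap(trajs, function(tr, ti) {
    fr <- tr$frames
    frame_vals <- purrr::map_dbl(split(fr, fr$frame), function(f) {
      ct <- contact_residues(structure, f, cutoff = cutoff,
                             include_hydrogens = include_hydrogens)
      if (nrow(ct) == 0) return(NA_real_)
      ct <- dplyr::inner_join(ct, areas, by = c("chain", "resseq", "resname"))
      w <- ct$area / sum(ct$area)
      sum(w * hydropathy(ct$resname, scale))
    })
    s_of_frame <- vapply(split(fr$arclength, fr$frame), `[`, numeric(1), 1)
    tibble::tibble(
      traj = ti,
      bin = floor(s_of_frame / step),
      value = frame_vals
    )
  })
  binned <- dplyr::bind_rows(per_traj)
  # frames within a bin averaged first, then across trajectories
  per_tb <- dplyr::summarise(
    dplyr::group_by(binned, .data$traj, .data$bin),
    value = mean(.data$value[!is.na(.data$value)])[1], # NaN when all NA
    .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_tb, .data$bin),
    n = sum(is.finite(.data$value)),
    sd = stats::sd(.data$value[is.finite(.data$value)]),
    value = mean(.data$value[is.finite(.data$value)]),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    arclength = (.data$bin + 0.5) * step,
    undefined = .data$n == 0,
    value = ifelse(.data$undefined, NA_real_, .data$value)
  )
  if (all(out$undefined)) {
    rlang::abort("ligand never contacts structure: all bins undefined")
  }
  out <- dplyr::arrange(
    out[, c("arclength", "value", "sd", "n", "undefined")], .data$arclength
  )
  class(out) <- c("cet_hydrophobicity_profile", class(out))
  out
}

#' Orientation angle of the ligand reference bond along the path
#'
#' The angle between the designated bond and a reference plane:
#' `asin(|v . n|)` in degrees, where `v` is the bond unit vector and `n`
#' the plane's unit normal. 0 degrees means the bond lies in the plane,
#' 90 degrees means it is along the normal. By default the plane normal is
#' the global path direction (last centroid minus first), so the default
#' angle measures how far the bond tilts out of the tunnel cross-section
#' toward the axis.
#'
#' @param trajectory A `ligand_trajectory`.
#' @param normal Unit 3-vector normal of the reference plane, or `NULL`
#'   for the default above.
#' @return Tibble with `frame`, `arclength`, `angle_deg`.
#' @export
orientation_angle <- function(trajectory, normal = NULL) {
  stopifnot(inherits(trajectory, "ligand_trajectory"))
  fr <- trajectory$frames
  bond <- trajectory$bond
  by_frame <- split(fr, fr$frame)
  if (is.null(normal)) {
    ctr <- function(f) c(mean(f$x), mean(f$y), mean(f$z))
    normal <- ctr(by_frame[[length(by_frame)]]) - ctr(by_frame[[1]])
  }
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) rlang::abort("degenerate reference plane normal")
  normal <- normal / nn
  rows <- purrr::map(by_frame, function(f) {
    i1 <- match(bond[1], f$name)
    i2 <- match(bond[2], f$name)
    if (is.na(i1) || is.na(i2)) rlang::abort("bond atoms missing from a frame")
    v <- c(f$x[i2] - f$x[i1], f$y[i2] - f$y[i1], f$z[i2] - f$z[i1])
    vn <- sqrt(sum(v^2))
    if (vn < 1e-12) rlang::abort("zero-length bond vector")
    tibble::tibble(
      frame = f$frame[1],
      arclength = f$arclength[1],
      angle_deg = asin(pmin(1, abs(sum(v / vn * normal)))) * 180 / pi
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$frame)
}
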