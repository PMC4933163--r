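# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Boltzmann thermal energy
#'
#' @param temperature Kelvin.
#' @return kB * T in kcal/mol (kB = 0.0019872041 kcal/mol/K).
#' @export
#' @examples
#' kbt(310) # ~0.616 kcal/mol at body temperature
kbt <- function(temperature) {
  stopifnot(temperature > 0)
  0.0019872041 * temperature
}

#' Build a synthetic barrel structure with a known tunnel
#'
#' Places rings of pseudo-atoms around a straight axis so that the
#' probe-accessible inner radius at the axis equals `inner_radius` exactly:
#' ring atom centers sit at radial distance `inner_radius(s) + atom_vdw`.
#' Alternate rings are staggered azimuthally to close the gaps between
#' atoms. This gives [diameter_profile()] a construction oracle: the
#' recovered diameter must be twice the specified inner radius.
#'
#' @param axis_length Barrel length along z, angstroms.
#' @param inner_radius Either a single number or a function of arclength
#'   (angstroms along the axis) returning the inner (clearance) radius.
#' @param ring_spacing Spacing between atom rings, angstroms.
#' @param atoms_per_ring Number of atoms per ring (>= 3).
#' @param residues 3-letter residue codes assigned per ring, recycled.
#' @param atom_vdw Van der Waals radius of every barrel atom, angstroms.
#' @return List with `structure` (atom tibble, one residue per ring) and
#'   `path` (the axis sampled at 1-angstrom arclength steps: tibble with
#'   `x`, `y`, `z`, `arclength`).
#' @export
#' @examples
#' b <- make_barrel(axis_length = 10, inner_radius = 3.3)
#' nrow(b$path)
make_barrel <- function(axis_length = 60, inner_radius = 3.3,
                        ring_spacing = 1, atoms_per_ring = 16,
                        residues = "ILE", atom_vdw = 1.7) {
  stopifnot(axis_length > 0, ring_spacing > 0, atom_vdw > 0)
  if (atoms_per_ring < 3) rlang::abort("rings need at least 3 atoms")
  rfun <- if (is.function(inner_radius)) inner_radius else function(s) rep(inner_radius, length(s))
  s_rings <- seq(0, axis_length, by = ring_spacing)
  r_in <- rfun(s_rings)
  if (any(!is.finite(r_in)) || any(r_in <= 0)) {
    rlang::abort("inner radius profile must be positive and finite everywhere")
  }
  if (any(r_in < atom_vdw)) {
    rlang::abort("inner radius profile dips below the atom vdW radius")
  }
  residues <- toupper(rep_len(residues, length(s_rings)))

  ang0 <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring + 1)]
  rings <- lapply(seq_along(s_rings), function(i) {
    # stagger alternate rings by half an azimuthal step
    ang <- ang0 + (i %% 2) * pi / atoms_per_ring
    rc <- r_in[i] + atom_vdw
    tibble::tibble(
      name = "C", element = "C", resname = residues[i],
      resseq = i, chain = "A",
      x = rc * cos(ang), y = rc * sin(ang), z = s_rings[i],
      vdw_radius = atom_vdw
    )
  })
  structure <- dplyr::bind_rows(rings)
  structure <- dplyr::mutate(structure, serial = dplyr::row_number(), .before = 1)

  s_path <- seq(0, axis_length, by = 1)
  path <- tibble::tibble(x = 0, y = 0, z = s_path, arclength = s_path)
  list(structure = structure, path = path)
}

#' Place a ligand along a transfer path with a scheduled orientation
#'
#' Produces one frame per path point: the ligand centroid is translated to
#' the path point and the designated reference bond is rotated to the unit
#' vector the schedule prescribes at that arclength.
#'
#' @param path Transfer path tibble (`x`, `y`, `z`, `arclength`).
#' @param ligand Atom table containing the two named bond atoms.
#' @param bond Character vector of two atom names defining the reference
#'   bond (e.g. the steroid-ring long axis).
#' @param orientation Function of arclength returning a unit 3-vector, or a
#'   single unit 3-vector used for every frame.
#' @return A `ligand_trajectory`: list with `frames` (long tibble of atom
#'   records with `frame` and `arclength` columns) and `bond`.
#' @export
make_ligand_trajectory <- function(path, ligand, bond, orientation = c(0, 0, 1)) {
  check_structure(ligand, require_radii = FALSE)
  stopifnot(is.character(bond), length(bond) == 2)
  if (!all(bond %in% ligand$name)) {
    rlang::abort(paste0(
      "ligand lacks designated bond atom(s): ",
      paste(setdiff(bond, ligand$name), collapse = ", ")
    ))
  }
  ofun <- if (is.function(orientation)) orientation else function(s) orientation
  xyz <- coords(ligand)
  ctr <- colMeans(xyz)
  xyz0 <- sweep(xyz, 2, ctr)
  i1 <- match(bond[1], ligand$name)
  i2 <- match(bond[2], ligand$name)
  v0 <- xyz0[i2, ] - xyz0[i1, ]
  if (sqrt(sum(v0^2)) < 1e-12) rlang::abort("reference bond has zero length")
  v0 <- v0 / sqrt(sum(v0^2))

  frames <- purrr::map(seq_len(nrow(path)), function(k) {
    s <- path$arclength[k]
    target <- ofun(s)
    if (abs(sqrt(sum(target^2)) - 1) > 1e-6) {
      rlang::abort(paste0(
        "orientation schedule returned a non-unit vector at arclength ", s
      ))
    }
    R <- rotation_between(v0, target)
    placed <- xyz0 %*% t(R)
    out <- ligand
    out$x <- placed[, 1] + path$x[k]
    out$y <- placed[, 2] + path$y[k]
    out$z <- placed[, 3] + path$z[k]
    out$frame <- k
    out$arclength <- s
    out
  })
  frames <- dplyr::bind_rows(frames)
  frames <- frames[, c("frame", "arclength", setdiff(names(frames), c("frame", "arclength")))]
  structure(list(frames = frames, bond = bond), class = "ligand_trajectory")
}

# Rodrigues rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  v <- c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
  c_ <- sum(a * b)
  s2 <- sum(v^2)
  if (s2 < 1e-16) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * (1 - c_) / s2
}

#' @export
print.ligand_trajectory <- function(x, ...) {
  cat(
    "<ligand_trajectory> ", max(x$frames$frame), " frames, bond ",
    x$bond[1], "-", x$bond[2], "\n",
    sep = ""
  )
  invisible(x)
}

#' Sample replicated transfer times from a power law with multiplicative noise
#'
#' Each replicate time is `A * force^-b * exp(eps)` with
#' `eps ~ Normal(0, sigma^2)`: log-normal scatter, so replicate standard
#' deviations scale with the mean, as steered-transfer replicates do.
#'
#' @param A Prefactor, ns * (kcal/mol/A)^b.
#' @param b Power-law exponent (positive: time falls with force).
#' @param forces Driving forces, kcal/mol/A; must be positive.
#' @param n_rep Replicates per force.
#' @param sigma Log-scale noise standard deviation (>= 0).
#' @param seed Integer seed; the table is reproducible under a fixed seed.
#' @return Tibble with columns `force`, `replicate`, `time_ns`.
#' @export
#' @examples
#' sample_transfer_times(475, 2.75, forces = c(6, 12), n_rep = 2, sigma = 0, seed = 1)
sample_transfer_times <- function(A, b, forces, n_rep = 4, sigma = 0.3, seed = NULL) {
  stopifnot(A > 0, n_rep >= 1, sigma >= 0)
  if (any(forces <= 0)) rlang::abort("forces must be positive")
  with_seed(seed, {
    tbl <- tidyr::expand_grid(force = forces, replicate = seq_len(n_rep))
    eps <- stats::rnorm(nrow(tbl), 0, sigma)
    dplyr::mutate(tbl, time_ns = A * .data$force^(-b) * exp(eps))
  })
}

#' Overdamped Langevin first-passage times through a 1-D tunnel
#'
#' Desk-scale surrogate for steered transfer: a particle obeying
#' `x <- x + (F/gamma) dt + sqrt(2 kB T dt / gamma) N(0,1)` starts at 0
#' with a reflecting boundary there and is absorbed at `L`. In the
#' drift-dominated regime (`F L >> kB T`) the mean passage time approaches
#' `gamma L / F`; at `F = 0` it is the diffusive closed form
#' `L^2 gamma / (2 kB T)`.
#'
#' @param L Tunnel length, angstroms.
#' @param gamma Friction, kcal ps / (mol A^2).
#' @param temperature Kelvin.
#' @param force Constant driving force, kcal/mol/A (>= 0).
#' @param dt Time step, ps.
#' @param n_rep Number of independent walkers.
#' @param max_steps Walkers not absorbed within this many steps are
#'   flagged as non-passages (time `NA`).
#' @param seed Integer seed.
#' @return Tibble with `replicate`, `time_ps`, `passed`; non-passages have
#'   `passed = FALSE` and `time_ps = NA`.
#' @export
langevin_first_passage <- function(L, gamma, temperature, force = 0,
                                   dt = 0.02, n_rep = 100,
                                   max_steps = 1e6, seed = NULL) {
  stopifnot(L > 0, gamma > 0, temperature > 0, force >= 0, dt > 0, n_rep >= 1)
  if (force > 0 && dt >= 0.1 * gamma * L / force) {
    rlang::abort("time step too large for the drift relaxation scale gamma*L/F")
  }
  kT <- kbt(temperature)
  drift <- force / gamma * dt
  sd_step <- sqrt(2 * kT * dt / gamma)
  with_seed(seed, {
    x <- rep(0, n_rep)
    active <- seq_len(n_rep)
    times <- rep(NA_real_, n_rep)
    step <- 0L
    while (length(active) > 0 && step < max_steps) {
      step <- step + 1L
      x[active] <- x[active] + drift + sd_step * stats::rnorm(length(active))
      x[active] <- abs(x[active]) # reflect at 0
      done <- active[x[active] >= L]
      if (length(done) > 0) {
        times[done] <- step * dt
        active <- setdiff(active, done)
      }
    }
    tibble::tibble(
      replicate = seq_len(n_rep),
      time_ps = times,
      passed = !is.na(times)
    )
  })
}

#' Jittered 2-D hexagonal lattice of headgroup-like points
#'
#' Emulates phosphorus positions of a phospholipid monolayer so that the
#' radial-distribution first peak sits at the lattice spacing.
#'
#' @param spacing Nearest-neighbour spacing, angstroms.
#' @param n_side Points per lattice side (>= 2).
#' @param jitter_sd Gaussian positional jitter, angstroms.
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y` (angstroms).
#' @export
make_monolayer_lattice <- function(spacing = 8, n_side = 12, jitter_sd = 0,
                                   seed = NULL) {
  stopifnot(spacing > 0, jitter_sd >= 0)
  if (n_side < 2) rlang::abort("lattice needs at least 2 points per side")
  ij <- tidyr::expand_grid(i = seq_len(n_side) - 1, j = seq_len(n_side) - 1)
  x <- spacing * (ij$i + 0.5 * (ij$j %% 2))
  y <- spacing * sqrt(3) / 2 * ij$j
  with_seed(seed, {
    if (jitter_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, jitter_sd)
      y <- y + stats::rnorm(length(y), 0, jitter_sd)
    }
    tibble::tibble(x = x, y = y)
  })
}

#' Minimal rigid surrogate ligand with a named reference bond
#'
#' A small T-shaped rigid body whose long axis is the designated bond,
#' standing in for the steroid-ring long axis of a cholesteryl ester when
#' exercising trajectory and orientation code.
#'
#' @param bond Two atom names for the reference bond ends.
#' @param bond_length Distance between the bond atoms, angstroms.
#' @param width Lateral extent of the two off-axis atoms, angstroms.
#' @return Atom tibble with four atoms and vdW radii assigned.
#' @export
#' @examples
#' make_ligand()
make_ligand <- function(bond = c("C10", "C19"), bond_length = 2.4, width = 1.2) {
  stopifnot(length(bond) == 2, bond_length > 0, width > 0)
  half <- bond_length / 2
  tibble::tibble(
    serial = 1:4,
    name = c(bond[1], bond[2], "C1", "C2"),
    element = "C",
    resname = "LIG",
    resseq = 1L,
    chain = "L",
    x = c(0, 0, width, -width),
    y = 0,
    z = c(-half, half, 0, 0),
    vdw_radius = 1.7
  )
}
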