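# In-code fixtures shared across test files.

# Minimal two-atom PDB text (alanine CA + CB).
mini_pdb_lines <- function() {
  c(
    "HEADER    TEST",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "TER",
    "END"
  )
}

# A single isolated atom as a structure row.
one_atom <- function(x = 0, y = 0, z = 0, r = 1.7, resname = "ALA",
                     name = "CA", resseq = 1L, chain = "A", serial = 1L) {
  tibble::tibble(
    serial = serial, name = name, element = "C", resname = resname,
    resseq = resseq, chain = chain, x = x, y = y, z = z, vdw_radius = r
  )
}

# n atoms evenly spaced on a ring of given center radius in the z = 0 plane.
ring_structure <- function(n = 4, radius = 5, r_vdw = 1.7) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(
    serial = seq_len(n), name = "C", element = "C", resname = "ALA",
    resseq = seq_len(n), chain = "A",
    x = radius * cos(ang), y = radius * sin(ang), z = 0,
    vdw_radius = r_vdw
  )
}

# Brute-force clearance oracle: exhaustive grid of candidate centers at
# `res` spacing within `probe` of point p; clearance = max over candidates
# of min over atoms of (distance - vdw radius). Independent of the
# package's candidate generation and refinement.
brute_force_clearance <- function(p, structure, probe = 3.0, res = 0.05) {
  g <- seq(-probe, probe, by = res)
  cand <- as.matrix(expand.grid(x = g, y = g, z = g))
  cand <- cand[rowSums(cand^2) <= probe^2, ]
  cand <- sweep(cand, 2, p, "+")
  cl <- rep(Inf, nrow(cand))
  for (j in seq_len(nrow(structure))) {
    d <- sqrt((cand[, 1] - structure$x[j])^2 +
                (cand[, 2] - structure$y[j])^2 +
                (cand[, 3] - structure$z[j])^2) - structure$vdw_radius[j]
    cl <- pmin(cl, d)
  }
  max(cl)
}

# Barrel bent by `angle_deg` in the x-z plane at arclength `s_bend`;
# returns structure, the true piecewise axis at 1-A steps, and the exit
# direction. An independent construction, not make_barrel().
bent_barrel <- function(total_length = 30, s_bend = 15, angle_deg = 30,
                        inner_radius = 3.3, atom_vdw = 1.7,
                        atoms_per_ring = 16) {
  a <- angle_deg * pi / 180
  dir1 <- c(0, 0, 1)
  dir2 <- c(sin(a), 0, cos(a))
  axis_point <- function(s) {
    if (s <= s_bend) c(0, 0, s) else c(0, 0, s_bend) + (s - s_bend) * dir2
  }
  axis_dir <- function(s) if (s <= s_bend) dir1 else dir2
  s_rings <- seq(0, total_length, by = 1)
  ang0 <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring + 1)]
  rc <- inner_radius + atom_vdw
  rows <- lapply(seq_along(s_rings), function(i) {
    s <- s_rings[i]
    ctr <- axis_point(s)
    d <- axis_dir(s)
    e1 <- c(d[3], 0, -d[1]) # unit, orthogonal to d (d lies in x-z plane)
    e2 <- c(0, 1, 0)
    ang <- ang0 + (i %% 2) * pi / atoms_per_ring
    pts <- t(vapply(
      ang,
      function(th) ctr + rc * (cos(th) * e1 + sin(th) * e2),
      numeric(3)
    ))
    tibble::tibble(
      name = "C", element = "C", resname = "ILE", resseq = i, chain = "A",
      x = pts[, 1], y = pts[, 2], z = pts[, 3], vdw_radius = atom_vdw
    )
  })
  str <- dplyr::bind_rows(rows)
  str$serial <- seq_len(nrow(str))
  axis <- t(vapply(s_rings, axis_point, numeric(3)))
  list(
    structure = str,
    axis = tibble::tibble(x = axis[, 1], y = axis[, 2], z = axis[, 3],
                          arclength = s_rings),
    exit_dir = dir2, s_bend = s_bend, total_length = total_length
  )
}

# Interior slice of a diameter profile: at least `margin` angstroms of
# barrel on both sides, so the probe ball cannot reach past the mouths.
interior <- function(profile, axis_length, margin = 4) {
  profile[profile$arclength >= margin & profile$arclength <= axis_length - margin, ]
}
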