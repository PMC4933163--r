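test_that("diameter profile recovers the barrel construction oracle", {
  b <- make_barrel(axis_length = 20, inner_radius = 3.3)
  dp <- diameter_profile(b$structure, b$path)
  inner <- interior(dp, 20)
  expect_true(all(abs(inner$diameter - 6.6) <= 0.1))
  expect_true(all(inner$open))
  expect_false(any(dp$outside))
})

test_that("constriction below the interior threshold is flagged closed", {
  # the narrow section must outspan the probe ball, or the probe center
  # escapes to the wide flanks
  rfun <- function(s) ifelse(abs(s - 8) <= 3.5, 1.0, 3.3)
  b <- make_barrel(axis_length = 16, inner_radius = rfun, atom_vdw = 0.9)
  dp <- diameter_profile(b$structure, b$path)
  expect_false(dp$open[dp$arclength == 8])
  expect_true(dp$open[dp$arclength == 2])
})

test_that("clearance maximisation agrees with a brute-force grid oracle", {
  ring <- ring_structure(n = 4, radius = 5, r_vdw = 1.7)
  path <- tibble::tibble(x = 0, y = 0, z = 0, arclength = 0)
  dp <- diameter_profile(ring, path)
  oracle <- brute_force_clearance(c(0, 0, 0), ring, probe = 3.0, res = 0.05)
  expect_equal(dp$diameter, 2 * oracle, tolerance = 0.02)
  # in the ring plane itself the clearance is the analytic 5.0 - 1.7
  in_plane <- min(sqrt(ring$x^2 + ring$y^2)) - 1.7
  expect_equal(in_plane, 3.3)
})

test_that("refined clearance never drops below the unrefined path-point clearance", {
  b <- make_barrel(axis_length = 12, inner_radius = function(s) 3.3 + 0.5 * sin(s))
  dp <- diameter_profile(b$structure, b$path)
  point_cl <- vapply(seq_len(nrow(b$path)), function(k) {
    d <- sqrt((b$structure$x - b$path$x[k])^2 +
                (b$structure$y - b$path$y[k])^2 +
                (b$structure$z - b$path$z[k])^2) - b$structure$vdw_radius
    min(d)
  }, numeric(1))
  expect_true(all(dp$diameter >= 2 * point_cl - 1e-9))
})

test_that("path search recovers a straight tunnel axis", {
  b <- make_barrel(axis_length = 20, inner_radius = 3.3)
  path <- path_search(
    b$structure,
    entry = c(0, 0, 1),
    exit_fn = function(p) p[3] > 18
  )
  expect_true(attr(path, "reached_exit"))
  expect_false(attr(path, "terminated_early"))
  off_axis <- sqrt(mean(path$x^2 + path$y^2))
  expect_lt(off_axis, 0.5)
})

test_that("path search follows a bent tunnel into the exit region", {
  bb <- bent_barrel(total_length = 30, s_bend = 15, angle_deg = 30)
  exit_ctr <- unlist(bb$axis[nrow(bb$axis), c("x", "y", "z")])
  path <- path_search(
    bb$structure,
    entry = c(0, 0, 1),
    initial_direction = c(0, 0, 1),
    exit_fn = function(p) sum((p - exit_ctr)^2) < 2^2,
    cone_half_angle = 40
  )
  expect_true(attr(path, "reached_exit"))
  # every path point lies close to the known piecewise axis
  dev <- vapply(seq_len(nrow(path)), function(k) {
    min(sqrt((bb$axis$x - path$x[k])^2 +
               (bb$axis$y - path$y[k])^2 +
               (bb$axis$z - path$z[k])^2))
  }, numeric(1))
  expect_lt(max(dev), 1.0)
})

test_that("path search errors inside atoms and flags dead ends", {
  b <- make_barrel(axis_length = 10, inner_radius = 3.3)
  wall_atom <- c(b$structure$x[1], b$structure$y[1], b$structure$z[1])
  expect_error(
    path_search(b$structure, entry = wall_atom, exit_fn = function(p) FALSE),
    "clearance"
  )
  rfun <- function(s) ifelse(s > 10, 1.1, 3.3)
  blocked <- make_barrel(axis_length = 16, inner_radius = rfun, atom_vdw = 1.0)
  path <- path_search(
    blocked$structure,
    entry = c(0, 0, 1),
    initial_direction = c(0, 0, 1),
    exit_fn = function(p) p[3] > 15
  )
  expect_true(attr(path, "terminated_early"))
  expect_false(attr(path, "reached_exit"))
})

test_that("contact criterion is strictly less-than the cutoff", {
  target <- one_atom(x = 0)
  at <- function(d) one_atom(x = d, name = "L1", resname = "LIG", chain = "L")
  expect_equal(nrow(contact_residues(target, at(2.0))), 1)
  expect_equal(nrow(contact_residues(target, at(2.4))), 0) # exact boundary
  expect_equal(nrow(contact_residues(target, at(3.0))), 0)
})

test_that("contact sets are invariant to atom order", {
  b <- make_barrel(axis_length = 6, inner_radius = 2.0, atom_vdw = 1.7)
  lig <- one_atom(x = 1.5, z = 3, name = "L1", resname = "LIG", chain = "L")
  fwd <- contact_residues(b$structure, lig)
  rev <- contact_residues(b$structure[rev(seq_len(nrow(b$structure))), ], lig)
  expect_equal(dplyr::arrange(fwd, resseq), dplyr::arrange(rev, resseq))
})

test_that("SASA matches analytic sphere areas", {
  a <- one_atom(r = 1.7)
  s <- sasa(a, probe_radius = 1.4)
  expect_equal(s$area, 4 * pi * 3.1^2, tolerance = 0.01)
  # two far atoms: both full spheres
  two <- dplyr::bind_rows(a, one_atom(x = 100, serial = 2L, resseq = 2L))
  s2 <- sasa(two, probe_radius = 1.4)
  expect_equal(s2$area, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
  # atom fully engulfed by a larger sphere
  engulfed <- dplyr::bind_rows(
    one_atom(r = 0.5),
    one_atom(r = 3.0, serial = 2L, resseq = 2L)
  )
  s3 <- sasa(engulfed, probe_radius = 1.4)
  expect_equal(s3$area[s3$resseq == 1], 0)
  expect_error(sasa(a, n_points = 10), "accuracy floor")
})

test_that("SASA converges as the point count doubles", {
  st <- tibble::tibble(
    serial = 1:8, name = "C", element = "C",
    resname = rep(c("ILE", "ARG"), each = 4), resseq = rep(1:2, each = 4),
    chain = "A",
    x = c(0, 1.5, 0.8, 2.2, 4.0, 5.2, 4.6, 5.9),
    y = c(0, 0.5, 1.6, 1.2, 0.3, 0, 1.4, 1.0),
    z = c(0, 0.2, 0.9, 0.4, 0.1, 0.8, 0.2, 1.1),
    vdw_radius = 1.7
  )
  s1 <- sasa(st, n_points = 2000)
  s2 <- sasa(st, n_points = 4000)
  rel <- abs(s2$area - s1$area) / s1$area
  expect_lt(max(rel), 0.005)
})

test_that("hydrophobicity weighting follows SASA fractions of contacts", {
  # one ILE atom in reach, one ARG far away: pure ILE value
  prot <- dplyr::bind_rows(
    one_atom(x = 1.6, resname = "ILE"),
    one_atom(x = 50, resname = "ARG", serial = 2L, resseq = 2L)
  )
  path1 <- tibble::tibble(x = 0, y = 0, z = 0, arclength = 0)
  traj <- make_ligand_trajectory(path1, make_ligand(), bond = c("C10", "C19"))
  hp <- hydrophobicity_profile(prot, traj)
  expect_equal(hp$value[!hp$undefined], 4.5)

  # symmetric ILE/ARG pair with equal SASA: exact zero
  pair <- dplyr::bind_rows(
    one_atom(x = -1.0, resname = "ILE"),
    one_atom(x = 1.0, resname = "ARG", serial = 2L, resseq = 2L)
  )
  # the two SASA estimates agree to ~1%, so the weighted value sits at 0
  # within that sampling accuracy
  hp2 <- hydrophobicity_profile(pair, traj, n_points = 4000)
  expect_lt(abs(hp2$value[!hp2$undefined]), 0.02)
})

test_that("an all-ILE barrel gives a constant +4.5 profile", {
  b <- make_barrel(axis_length = 12, inner_radius = 3.3, residues = "ILE")
  # wide ligand whose arm atoms reach the barrel wall
  lig <- make_ligand(width = 3.0)
  traj <- make_ligand_trajectory(b$path, lig, bond = c("C10", "C19"))
  hp <- hydrophobicity_profile(b$structure, traj)
  vals <- hp$value[!hp$undefined]
  expect_gt(length(vals), 0)
  expect_equal(vals, rep(4.5, length(vals)))
  # convex combination invariant on a mixed barrel
  bm <- make_barrel(axis_length = 12, inner_radius = 3.3,
                    residues = c("ILE", "ARG", "ALA"))
  hpm <- hydrophobicity_profile(bm$structure, traj)
  vm <- hpm$value[!hpm$undefined]
  expect_true(all(vm >= -4.5 - 1e-9 & vm <= 4.5 + 1e-9))
})

test_that("hydrophobicity errors when the ligand never touches the structure", {
  b <- make_barrel(axis_length = 6, inner_radius = 3.3)
  lig <- make_ligand(width = 0.3) # stays on the axis, out of reach
  traj <- make_ligand_trajectory(b$path, lig, bond = c("C10", "C19"))
  expect_error(hydrophobicity_profile(b$structure, traj), "never contacts")
})

test_that("orientation angle hits the plane and normal limits", {
  b <- make_barrel(axis_length = 10, inner_radius = 3.3)
  lig <- make_ligand()
  in_plane <- make_ligand_trajectory(b$path, lig, bond = c("C10", "C19"),
                                     orientation = c(1, 0, 0))
  ang <- orientation_angle(in_plane, normal = c(0, 0, 1))
  expect_equal(ang$angle_deg, rep(0, nrow(ang)), tolerance = 1e-6)
  along <- make_ligand_trajectory(b$path, lig, bond = c("C10", "C19"),
                                  orientation = c(0, 0, 1))
  ang2 <- orientation_angle(along, normal = c(0, 0, 1))
  expect_equal(ang2$angle_deg, rep(90, nrow(ang2)), tolerance = 1e-6)
})

test_that("a scheduled 90-degree flip appears at the right arclength", {
  b <- make_barrel(axis_length = 20, inner_radius = 3.3)
  sched <- function(s) if (s < 10) c(0, 0, 1) else c(1, 0, 0)
  traj <- make_ligand_trajectory(b$path, make_ligand(), bond = c("C10", "C19"),
                                 orientation = sched)
  ang <- orientation_angle(traj, normal = c(0, 0, 1))
  expect_equal(ang$angle_deg[ang$arclength < 10], rep(90, 10), tolerance = 1e-6)
  expect_equal(ang$angle_deg[ang$arclength >= 10], rep(0, 11), tolerance = 1e-6)
})

test_that("hydrogens can be excluded from the contact criterion", {
  prot <- one_atom(x = 0)
  hyd <- one_atom(x = 2.0, name = "H1", resname = "LIG", chain = "L")
  hyd$element <- "H"
  expect_equal(nrow(contact_residues(prot, hyd)), 1)
  expect_equal(nrow(contact_residues(prot, hyd, include_hydrogens = FALSE)), 0)
})
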