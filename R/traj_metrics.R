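check_coordset <- function(x, arg = "coordinates") {
  if (!is.data.frame(x) || !all(c("label", "x", "y", "z") %in% names(x))) {
    rlang::abort(paste0("`", arg, "` must have columns label, x, y, z"))
  }
  if (nrow(x) < 1) rlang::abort(paste0("`", arg, "` is empty"))
  if (anyDuplicated(x$label)) rlang::abort(paste0("`", arg, "` has duplicate labels"))
  invisible(x)
}

# Kabsch: proper rotation (det +1) and translation superposing mobile onto
# fixed; returns the transformed mobile coordinate matrix.
kabsch_superpose <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(A %*% t(R), 2, cf, "+")
}

#' Root-mean-square deviation between two labelled coordinate sets
#'
#' With `superpose = TRUE` the optimal rigid motion (Kabsch algorithm,
#' proper rotation only: reflections are disallowed because molecules are
#' chiral) is applied before computing the RMSD.
#'
#' @param a,b Coordinate tables with columns `label`, `x`, `y`, `z`;
#'   matched by label.
#' @param superpose Superpose `b` onto `a` first?
#' @return RMSD in angstroms.
#' @export
#' @examples
#' s <- tibble::tibble(label = 1:4, x = c(0, 1, 0, 2), y = c(0, 0, 1, 2), z = 0)
#' kabsch_rmsd(s, s)
kabsch_rmsd <- function(a, b, superpose = TRUE) {
  check_coordset(a, "a")
  check_coordset(b, "b")
  if (!setequal(a$label, b$label)) rlang::abort("label sets differ")
  b <- b[match(a$label, b$label), ]
  xa <- cbind(a$x, a$y, a$z)
  xb <- cbind(b$x, b$y, b$z)
  if (superpose) {
    if (nrow(xa) < 3) rlang::abort("superposition needs at least 3 points")
    xb <- kabsch_superpose(xb, xa)
  }
  sqrt(mean(rowSums((xa - xb)^2)))
}

check_trajectory <- function(traj) {
  if (!is.data.frame(traj) || !all(c("frame", "label", "x", "y", "z") %in% names(traj))) {
    rlang::abort("trajectory must have columns frame, label, x, y, z")
  }
  labs <- split(traj$label, traj$frame)
  if (length(labs) < 2) rlang::abort("trajectory needs at least 2 frames")
  first <- sort(labs[[1]])
  same <- vapply(labs, function(l) identical(sort(l), first), logical(1))
  if (!all(same)) rlang::abort("frames carry different label sets")
  invisible(traj)
}

#' Root-mean-square fluctuation per label
#'
#' Two-pass scheme: every frame is superposed onto the first frame, the
#' time-mean structure is computed, every frame is re-superposed onto that
#' mean, and the per-label RMS deviation from the mean position is
#' reported. Rigid-body motion therefore contributes nothing.
#'
#' @param traj Long trajectory table: columns `frame`, `label`, `x`, `y`,
#'   `z`; every frame must carry the same labels.
#' @return Tibble with `label` and `rmsf` (angstroms).
#' @export
rmsf <- function(traj) {
  check_trajectory(traj)
  frames <- split(traj, traj$frame)
  lab <- sort(frames[[1]]$label)
  mat <- function(f) {
    f <- f[match(lab, f$label), ]
    cbind(f$x, f$y, f$z)
  }
  ref <- mat(frames[[1]])
  fitted <- lapply(frames, function(f) kabsch_superpose(mat(f), ref))
  mean1 <- Reduce(`+`, fitted) / length(fitted)
  refit <- lapply(fitted, function(m) kabsch_superpose(m, mean1))
  mean2 <- Reduce(`+`, refit) / length(refit)
  dev2 <- Reduce(`+`, lapply(refit, function(m) rowSums((m - mean2)^2))) / length(refit)
  tibble::tibble(label = lab, rmsf = sqrt(dev2))
}

#' Radius of gyration
#'
#' @param x Coordinate table (`label`, `x`, `y`, `z`, optional `mass`).
#' @return sqrt(sum m_i |x_i - xbar|^2 / sum m_i), angstroms; unit masses
#'   when no `mass` column is present.
#' @export
radius_of_gyration <- function(x) {
  check_coordset(x)
  m <- if ("mass" %in% names(x)) x$mass else rep(1, nrow(x))
  xyz <- cbind(x$x, x$y, x$z)
  ctr <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
}

#' Molecular volume on a cubic grid
#'
#' Counts grid cells whose center falls inside any atom's vdW sphere;
#' overlaps are counted once (a union volume, not a sum of spheres).
#'
#' @param structure Atom table with vdW radii.
#' @param grid Grid spacing, angstroms.
#' @return Volume in cubic angstroms.
#' @export
molecular_volume <- function(structure, grid = 0.25) {
  check_structure(structure)
  if (grid <= 0) rlang::abort("grid spacing must be positive")
  xyz <- coords(structure)
  r <- structure$vdw_radius
  lo <- apply(xyz - r, 2, min) - grid
  hi <- apply(xyz + r, 2, max) + grid
  gx <- seq(lo[1] + grid / 2, hi[1], by = grid)
  gy <- seq(lo[2] + grid / 2, hi[2], by = grid)
  gz <- seq(lo[3] + grid / 2, hi[3], by = grid)
  inside <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(gx - xyz[i, 1]) <= r[i])
    iy <- which(abs(gy - xyz[i, 2]) <= r[i])
    iz <- which(abs(gz - xyz[i, 3]) <= r[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside[ix, iy, iz] <- inside[ix, iy, iz] | (d2 <= r[i]^2)
  }
  sum(inside) * grid^3
}

#' First peak of a radial distribution function
#'
#' Builds the pair-distance histogram, normalises by shell area (2-D) or
#' shell volume (3-D), and returns the center of the first local maximum
#' whose density exceeds the mean pair density.
#'
#' @param points Table of coordinates: columns `x`, `y` and, for
#'   `dimension = 3`, `z`.
#' @param bin_width Histogram bin, angstroms.
#' @param max_radius Largest distance considered, angstroms.
#' @param dimension 2 or 3.
#' @return Peak position, angstroms.
#' @export
rdf_first_peak <- function(points, bin_width = 0.5, max_radius = 20,
                           dimension = 2) {
  stopifnot(is.data.frame(points), nrow(points) >= 2, bin_width > 0)
  cols <- if (dimension == 3) c("x", "y", "z") else c("x", "y")
  d <- as.vector(stats::dist(as.matrix(points[, cols])))
  d <- d[d <= max_radius]
  if (length(d) == 0) rlang::abort("no pair distances below max_radius")
  breaks <- seq(0, max_radius + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  mid <- h$mids
  shell <- if (dimension == 2) 2 * pi * mid * bin_width else 4 * pi * mid^2 * bin_width
  g <- h$counts / shell
  thresh <- mean(g[g > 0])
  # first interior local maximum above the mean density
  n <- length(g)
  for (i in 2:(n - 1)) {
    if (g[i] > thresh && g[i] >= g[i - 1] && g[i] >= g[i + 1]) {
      return(mid[i])
    }
  }
  rlang::abort("no radial distribution peak found below max_radius")
}
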