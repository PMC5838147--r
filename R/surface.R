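#' Surface-integration settings
#'
#' @param probe_radius Solvent probe radius in Å (default 1.4, water).
#' @param n_sphere_points Number of quasi-uniform test points per atom
#'   sphere (default 960; minimum 32).  Doubling the count changes the
#'   total area by well under 0.5% on typical inputs.
#' @param point_scheme Point construction; only `"golden-spiral"` is
#'   implemented (deterministic, so results are bit-reproducible).
#' @return Object of class `"surface_config"`.
#' @export
surface_config <- function(probe_radius = 1.4, n_sphere_points = 960,
                           point_scheme = "golden-spiral") {
  if (!is.numeric(probe_radius) || probe_radius < 0) {
    stop("probe_radius must be >= 0", call. = FALSE)
  }
  if (n_sphere_points < 32) {
    stop("n_sphere_points must be >= 32", call. = FALSE)
  }
  point_scheme <- match.arg(point_scheme, "golden-spiral")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 point_scheme = point_scheme),
            class = "surface_config")
}

#' Quasi-uniform points on the unit sphere (golden spiral)
#'
#' Deterministic golden-spiral construction: latitudes place equal-area
#' bands, longitudes advance by the golden angle.  The centroid of the
#' point set lies near the origin (norm < 0.05 for usable n).
#'
#' @param n Number of points (>= 32).
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 32) stop("n must be >= 32", call. = FALSE)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)            # polar angle, equal-area bands
  theta <- pi * (1 + sqrt(5)) * (i - 0.5)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Accessible area of one atom (Shrake-Rupley)
#'
#' Area on the probe-expanded sphere `R_i = r_i + probe`: the fraction
#' of test points farther than `R_j = r_j + probe` from every other
#' atom j, times `4*pi*R_i^2`.  This is the probe-center (accessible)
#' surface, not the contact surface.  A point exactly at distance `R_j`
#' counts as exposed.
#'
#' @param i Atom index (1-based).
#' @param conf A [conformer()] with radii assigned.
#' @param config A [surface_config()].
#' @return Accessible area in Å².
#' @export
atom_accessible_area <- function(i, conf, config = surface_config()) {
  r <- conf$topology$atoms$radius
  if (any(is.na(r))) stop("radii not assigned; run assign_radii()",
                          call. = FALSE)
  pts <- sphere_points(config$n_sphere_points)
  xyz <- surface_pose(conf$xyz, conf$topology$atoms$is_polar)
  shrake_rupley_atom(i, xyz, r + config$probe_radius, pts)
}

# Deterministic canonical pose: centroid of the anchor atoms at the
# origin, axes along their principal axes, signs fixed by the anchor
# projection of largest magnitude (a rotation-invariant functional),
# frame forced right-handed.  Because the test-point sphere is fixed in
# space, integrating in this pose makes areas exactly invariant under
# rigid-body motion of the input.  Returns NULL when the anchor set is
# too degenerate (rank < 2) to define a stable frame.
canonical_pose <- function(xyz, anchor, allow_degenerate = FALSE) {
  a <- xyz[anchor, , drop = FALSE]
  ctr <- colMeans(a)
  x <- sweep(xyz, 2, ctr)
  ax <- sweep(a, 2, ctr)
  if (nrow(ax) < 2L) {
    return(if (allow_degenerate) x else NULL)
  }
  e <- eigen(crossprod(ax), symmetric = TRUE)
  if (!allow_degenerate && e$values[2] <= 1e-8 * max(e$values[1], 1)) {
    return(NULL)
  }
  ev <- e$vectors
  for (k in 1:3) {
    proj <- ax %*% ev[, k]
    s <- sign(proj[which.max(abs(proj))])
    if (s < 0) ev[, k] <- -ev[, k]
  }
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  x %*% ev
}

# The pose is anchored to the polar atoms when they define a stable
# frame (>= 3 of them, non-collinear): the polar subgeometry is
# untouched by apolar side-chain edits, so SAPSA comparisons across a
# truncation share one discretization exactly.  Otherwise all atoms
# anchor the pose.
surface_pose <- function(xyz, is_polar = NULL) {
  if (!is.null(is_polar) && !anyNA(is_polar) && sum(is_polar) >= 3) {
    p <- canonical_pose(xyz, which(is_polar))
    if (!is.null(p)) return(p)
  }
  canonical_pose(xyz, seq_len(nrow(xyz)), allow_degenerate = TRUE)
}

shrake_rupley_atom <- function(i, xyz, R, pts) {
  di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  nbr <- which(di < R[i] + R & seq_along(R) != i)
  if (!length(nbr)) return(4 * pi * R[i]^2)
  p <- pts * R[i]
  p <- sweep(p, 2, xyz[i, ], "+")
  exposed <- rep(TRUE, nrow(p))
  for (j in nbr) {
    d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
      (p[, 3] - xyz[j, 3])^2
    exposed <- exposed & d2 >= R[j]^2
    if (!any(exposed)) return(0)
  }
  mean(exposed) * 4 * pi * R[i]^2
}

#' Accessible surface of a whole conformer
#'
#' Per-atom accessible areas for all atoms (apolar atoms occlude polar
#' ones — this is the shielding mechanism), the total accessible area,
#' and the SAPSA: the sum of areas over polar atoms (N, O and their
#' bonded hydrogens; see [classify_polarity()]).
#'
#' @param conf A [conformer()] with radii and polarity assigned.
#' @param config A [surface_config()].
#' @return Object of class `"surface_result"` with fields
#'   `per_atom_area` (Å²), `total_sasa`, `sapsa`, `frame_index`.
#' @export
conformer_surface <- function(conf, config = surface_config()) {
  top <- conf$topology
  r <- top$atoms$radius
  if (any(is.na(r))) stop("radii not assigned; run assign_radii()",
                          call. = FALSE)
  if (any(is.na(top$atoms$is_polar))) {
    stop("polarity not assigned; run classify_polarity()", call. = FALSE)
  }
  R <- r + config$probe_radius
  pts <- sphere_points(config$n_sphere_points)
  xyz <- surface_pose(conf$xyz, top$atoms$is_polar)
  area <- vapply(seq_along(R), shrake_rupley_atom, numeric(1),
                 xyz = xyz, R = R, pts = pts)
  structure(list(per_atom_area = area,
                 total_sasa = sum(area),
                 sapsa = sum(area[top$atoms$is_polar]),
                 frame_index = conf$frame_index),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat(sprintf("surface_result (frame %d): total %.2f A^2, SAPSA %.2f A^2\n",
              x$frame_index, x$total_sasa, x$sapsa))
  invisible(x)
}
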