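#' Two-state shielded/exposed SAPSA test fixture
#'
#' Builds a deterministic synthetic ensemble of a hand-made
#' mini-molecule: a polar amide-like group (N, its H, and a carbonyl O)
#' on a small apolar scaffold, an Abu-like terminal ethyl (Cβ-Cγ(H3))
#' pointing away from the polar atoms, and a mobile apolar blocker
#' carbon.  Every frame is in one of two states, drawn i.i.d.:
#'
#' * `exposed` — the blocker is parked far from everything (probability
#'   `p_exposed`);
#' * `shielded` — the blocker hovers over the polar group, occluding it.
#'
#' The blocker height is solved (1-D root-find against the surface
#' engine) so that the polar-area gap between the two states equals
#' `delta_area`.  The ensemble mean SAPSA therefore has the closed form
#' `p * A_exposed + (1 - p) * A_shielded`, with both state areas
#' computed exactly by [conformer_surface()] and stored in the
#' metadata.  Geometry uses toy bond lengths with explicit bonds; the
#' methyl points away from the polar group and every sight line to it
#' is blocked by the scaffold, so truncating it (Cγ -> H) leaves the
#' polar area unchanged frame-by-frame (zero direct-shielding
#' component) — the construction that isolates the conformational
#' component in [decompose_side_chain_effect()].
#'
#' @param p_exposed Probability of the exposed state, in \[0, 1\].
#' @param delta_area Target polar-area gap `A_exposed - A_shielded`
#'   (Å²); must be achievable by the blocker (roughly 0-60 Å²).
#' @param n_frames Number of frames.
#' @param seed RNG seed for the state draws.
#' @param side_chain `"abu"` (ethyl, default) or `"ala"` (methyl — the
#'   topology that truncating the abu variant produces).
#' @param config [surface_config()] used for the state-area
#'   calibration.
#' @return An [ensemble()]; `metadata` holds `states` (logical,
#'   exposed), `A_exposed`, `A_shielded`, `p_exposed`, `seed`.
#' @export
make_two_state_fixture <- function(p_exposed, delta_area = 30, n_frames,
                                   seed, side_chain = c("abu", "ala"),
                                   config = surface_config()) {
  if (!is.numeric(p_exposed) || p_exposed < 0 || p_exposed > 1) {
    stop("p_exposed must be in [0, 1]", call. = FALSE)
  }
  side_chain <- match.arg(side_chain)
  base <- two_state_molecule(side_chain)
  top <- base$topology
  blocker <- base$blocker_index
  exposed_pos <- c(0, 0, 6.5)

  xyz_state <- function(blocker_xyz) {
    xyz <- base$xyz
    xyz[blocker, ] <- blocker_xyz
    xyz
  }
  sapsa_of <- function(xyz) conformer_surface(conformer(top, xyz), config)$sapsa
  a_exposed <- sapsa_of(xyz_state(exposed_pos))
  shielded_at <- function(h) xyz_state(c(3.4, -0.4, h))
  gap <- function(h) a_exposed - sapsa_of(shielded_at(h)) - delta_area
  lo <- 1.5
  hi <- 8
  if (gap(hi) > 0 || gap(lo) < 0) {
    stop("delta_area ", delta_area, " A^2 outside achievable range [",
         sprintf("%.1f", a_exposed - sapsa_of(shielded_at(hi))), ", ",
         sprintf("%.1f", a_exposed - sapsa_of(shielded_at(lo))), "]",
         call. = FALSE)
  }
  h_star <- stats::uniroot(gap, c(lo, hi), tol = 1e-4)$root
  shielded_pos <- c(3.4, -0.4, h_star)
  a_shielded <- sapsa_of(xyz_state(shielded_pos))

  states <- withr::with_seed(seed, stats::runif(n_frames) < p_exposed)
  coords <- array(rep(base$xyz, n_frames),
                  dim = c(n_atoms(top), 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[blocker, , f] <- if (states[f]) exposed_pos else shielded_pos
  }
  ensemble(top, coords, metadata = list(
    source = "make_two_state_fixture", side_chain = side_chain,
    states = states, A_exposed = a_exposed, A_shielded = a_shielded,
    blocker_height = h_star, p_exposed = p_exposed, seed = seed))
}

# the shared mini-molecule; bonds explicit (toy geometry, not chemistry)
two_state_molecule <- function(side_chain) {
  unit <- function(v) v / sqrt(sum(v^2))
  atoms <- data.frame(
    name = c("C1", "N", "HN", "O", "CB"),
    element = c("C", "N", "H", "O", "C"),
    stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(4.21, 0, 0),
               c(3.0, -1.3, 0), c(-1.5, 0, 0))
  bonds <- rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5))
  if (side_chain == "abu") {
    cg <- c(-2.8, 0, 0)
    atoms <- rbind(atoms, data.frame(
      name = c("CG", "HG1", "HG2", "HG3"),
      element = c("C", "H", "H", "H")))
    xyz <- rbind(xyz, cg,
                 cg + 1.09 * c(-1, 0, 0),
                 cg + 1.09 * unit(c(0.36, 0.86, 0.36)),
                 cg + 1.09 * unit(c(0.36, 0.86, -0.36)))
    bonds <- rbind(bonds, c(5, 6), c(6, 7), c(6, 8), c(6, 9))
  } else {
    atoms <- rbind(atoms, data.frame(name = "HB", element = "H"))
    xyz <- rbind(xyz, c(-1.5, 0, 0) + 1.09 * c(-1, 0, 0))
    bonds <- rbind(bonds, c(5, 6))
  }
  blocker <- nrow(atoms) + 1L
  atoms <- rbind(atoms, data.frame(name = "CX", element = "C"))
  xyz <- rbind(xyz, c(0, 0, 6.5))
  bonds <- rbind(bonds, c(1, blocker))
  top <- topology(atoms, bonds)
  top <- assign_radii(top)
  top <- classify_polarity(top)
  list(topology = top, xyz = unname(xyz), blocker_index = blocker)
}

#' Butane-like toy conformer for sampler demonstrations
#'
#' A four-carbon chain (no hydrogens) with one rotatable central bond;
#' radii assigned, no polar atoms.  Start geometry is eclipsed (syn) so
#' the 1-4 clash is maximal.
#'
#' @return A [conformer()].
#' @export
toy_butane <- function() {
  atoms <- data.frame(name = paste0("C", 1:4), element = "C",
                      stringsAsFactors = FALSE)
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4))
  top <- assign_radii(topology(atoms, bonds))
  # 1.53 A bonds, 112 deg angles, torsion 0 (syn: C1 and C4 cis)
  xyz <- rbind(c(-0.573, 1.419, 0),
               c(0, 0, 0),
               c(1.53, 0, 0),
               c(2.103, 1.419, 0))
  conformer(top, xyz)
}
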