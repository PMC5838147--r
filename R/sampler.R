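#' Settings for the torsional Metropolis Monte-Carlo sampler
#'
#' The sampler produces seeded, topologically valid, conformationally
#' diverse ensembles for exercising the surface pipeline.  Its energy
#' model is deliberately minimal and non-physical: a soft-sphere clash
#' penalty plus a hydrogen-bond contact reward (see
#' [sample_ensemble()]).  It does not emulate any force field.
#'
#' @param seed Integer RNG seed; every run is fully reproducible.
#' @param n_frames Frames to record (>= 1); one proposal per frame.
#' @param temperature Kelvin (> 0); energies are treated as kcal/mol.
#' @param torsion_step Maximum rotation per proposal, degrees.
#' @param rotatable_bonds Two-column matrix (1-based atom pairs); each
#'   must be a real bond whose removal splits the molecule (ring
#'   torsions are rejected).
#' @param clash_energy_scale Prefactor of the clash penalty
#'   (kcal/mol/Å²).
#' @param hbond_reward Reward per donor-H...acceptor contact (kcal/mol).
#' @param emulated_md Free-form provenance record describing the
#'   molecular-dynamics protocol the synthetic ensemble stands in for
#'   (stored in metadata; never used in computation).
#' @return Object of class `"sampler_config"`.
#' @export
sampler_config <- function(seed, n_frames, temperature = 300,
                           torsion_step = 60,
                           rotatable_bonds = matrix(integer(), ncol = 2),
                           clash_energy_scale = 10, hbond_reward = 1,
                           emulated_md = list(length_ns = 20,
                                              n_conformations = 20000,
                                              dielectric = 80,
                                              friction_per_ps = 1,
                                              temperature_K = 300)) {
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 temperature = temperature, torsion_step = torsion_step,
                 rotatable_bonds = matrix(as.integer(rotatable_bonds),
                                          ncol = 2),
                 clash_energy_scale = clash_energy_scale,
                 hbond_reward = hbond_reward, emulated_md = emulated_md),
            class = "sampler_config")
}

#' Sample a conformer ensemble by torsional Metropolis Monte Carlo
#'
#' One step per recorded frame: pick a rotatable bond uniformly, rotate
#' the smaller^[actually: the side containing the bond's second atom]
#' side by a uniform angle in `[-torsion_step, torsion_step]` degrees,
#' and accept with probability `min(1, exp(-dE / kT))`.  The energy is
#' `clash_energy_scale * sum(max(0, 0.8 (r_i + r_j) - d_ij)^2)` over
#' non-bonded pairs (1-2 and 1-3 pairs excluded; their distances are
#' invariant under torsions) minus `hbond_reward` times the number of
#' polar-H...N/O contacts under 2.5 Å.  The current (not only accepted)
#' conformation is recorded every step, as in a standard Markov chain.
#'
#' With zero rotatable bonds the chain is the identity and all frames
#' equal the start.
#'
#' @param start A [conformer()] with radii assigned (for the clash
#'   term); polarity should be assigned if `hbond_reward > 0`.
#' @param config A [sampler_config()].
#' @return An [ensemble()]; metadata records the config and the
#'   acceptance rate.
#' @export
sample_ensemble <- function(start, config) {
  stopifnot(inherits(start, "conformer"), inherits(config, "sampler_config"))
  top <- start$topology
  r <- top$atoms$radius
  if (any(is.na(r))) stop("radii not assigned; run assign_radii()",
                          call. = FALSE)
  rb <- config$rotatable_bonds
  moving <- lapply(seq_len(nrow(rb)), function(k) {
    torsion_moving_side(top, rb[k, 1], rb[k, 2])
  })
  excl <- topology_exclusions(top)
  polar_h <- which(top$atoms$element == "H" &
                     isTRUE_vec(top$atoms$is_polar))
  acceptors <- which(top$atoms$element %in% c("N", "O"))
  energy <- function(xyz) {
    clash_energy(xyz, r, excl, config$clash_energy_scale) -
      config$hbond_reward * hbond_count(xyz, polar_h, acceptors, top)
  }
  kT <- 0.0019872041 * config$temperature
  coords <- array(NA_real_, dim = c(n_atoms(top), 3, config$n_frames))
  accepted <- 0L
  withr::with_seed(config$seed, {
    xyz <- start$xyz
    e <- energy(xyz)
    for (f in seq_len(config$n_frames)) {
      if (nrow(rb)) {
        k <- sample.int(nrow(rb), 1L)
        ang <- stats::runif(1, -config$torsion_step, config$torsion_step)
        prop <- rotate_about_bond(xyz, rb[k, 1], rb[k, 2], moving[[k]],
                                  ang * pi / 180)
        e_new <- energy(prop)
        if (stats::runif(1) < exp(-(e_new - e) / kT)) {
          xyz <- prop
          e <- e_new
          accepted <- accepted + 1L
        }
      }
      coords[, , f] <- xyz
    }
  })
  ensemble(top, coords,
           metadata = list(sampler = unclass(config),
                           acceptance_rate = if (nrow(rb)) {
                             accepted / config$n_frames
                           } else NA_real_))
}

isTRUE_vec <- function(x) !is.na(x) & x

# atoms on the j-side once bond i-j is cut; error if the bond is in a ring
torsion_moving_side <- function(top, i, j) {
  b <- top$bonds
  in_bond <- (b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i)
  if (!any(in_bond)) stop("rotatable pair (", i, ",", j,
                          ") is not a bond", call. = FALSE)
  g <- igraph::graph_from_edgelist(b[!in_bond, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_atoms(top) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  if (comp[i] == comp[j]) {
    stop("bond (", i, ",", j, ") lies in a ring; ring torsions are not ",
         "supported", call. = FALSE)
  }
  setdiff(which(comp == comp[j]), j)
}

# Rodrigues rotation of `moving` atoms about the i->j axis through x_j
rotate_about_bond <- function(xyz, i, j, moving, angle) {
  if (!length(moving)) return(xyz)
  axis <- xyz[j, ] - xyz[i, ]
  axis <- axis / sqrt(sum(axis^2))
  v <- sweep(xyz[moving, , drop = FALSE], 2, xyz[j, ])
  cosA <- cos(angle)
  sinA <- sin(angle)
  kxv <- cbind(axis[2] * v[, 3] - axis[3] * v[, 2],
               axis[3] * v[, 1] - axis[1] * v[, 3],
               axis[1] * v[, 2] - axis[2] * v[, 1])
  kdv <- v %*% axis
  rot <- v * cosA + kxv * sinA + outer(as.vector(kdv), axis) * (1 - cosA)
  xyz[moving, ] <- sweep(rot, 2, xyz[j, ], "+")
  xyz
}

# pairs excluded from the clash term: bonded (1-2) and angle (1-3)
topology_exclusions <- function(top) {
  b <- top$bonds
  n <- n_atoms(top)
  excl <- matrix(FALSE, n, n)
  if (nrow(b)) {
    excl[b] <- TRUE
    excl[b[, c(2, 1), drop = FALSE]] <- TRUE
    adj <- lapply(seq_len(n), function(i) bonded_to(top, i))
    for (i in seq_len(n)) {
      for (j in adj[[i]]) {
        excl[i, adj[[j]]] <- TRUE
      }
    }
  }
  diag(excl) <- TRUE
  excl
}

clash_energy <- function(xyz, r, excl, scale) {
  d <- as.matrix(stats::dist(xyz))
  thr <- 0.8 * outer(r, r, "+")
  over <- pmax(0, thr - d)
  over[excl] <- 0
  scale * sum(over[upper.tri(over)]^2)
}

hbond_count <- function(xyz, polar_h, acceptors, top) {
  if (!length(polar_h) || !length(acceptors)) return(0L)
  cnt <- 0L
  for (h in polar_h) {
    donor <- bonded_to(top, h)
    acc <- setdiff(acceptors, donor)
    if (!length(acc)) next
    d <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[h, ])^2))
    cnt <- cnt + sum(d < 2.5)
  }
  cnt
}
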