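two_state_pair <- function(n_frames = 30) {
  list(A = make_two_state_fixture(0.25, 30, n_frames, seed = 11,
                                  side_chain = "abu"),
       B = make_two_state_fixture(0.75, 30, n_frames, seed = 12,
                                  side_chain = "ala"))
}

cg_spec <- function(ens) {
  truncation_spec(which(ens$topology$atoms$name == "CG"))
}

test_that("ensemble SAPSA mean/sd/block statistics are exact arithmetic", {
  es2 <- sapsa:::new_ensemble_sapsa(c(100, 120), block_size = 2)
  expect_equal(es2$mean, 110)
  expect_equal(es2$sd, 10)           # population sd, divisor n
  es1 <- sapsa:::new_ensemble_sapsa(42, block_size = 5)
  expect_equal(es1$mean, 42)
  expect_equal(es1$sd, 0)
  x <- rnorm(20, 100, 5)
  es <- sapsa:::new_ensemble_sapsa(x, block_size = 5)
  expect_length(es$block_means, 4L)
  expect_equal(es$block_means,
               as.numeric(tapply(x, rep(1:4, each = 5), mean)))
  # equal-sized blocks: block means average back to the global mean
  expect_equal(mean(es$block_means), es$mean)
  # ragged last block handled: ceil(7/3) = 3 blocks
  expect_length(sapsa:::new_ensemble_sapsa(rnorm(7), 3)$block_means, 3L)
  expect_error(ensemble_sapsa(two_state_pair(2)$A, block_size = 0),
               "block_size")
})

test_that("per-frame engine SAPSA matches the fixture's two-state values", {
  fx <- make_two_state_fixture(0.6, 25, n_frames = 12, seed = 3)
  es <- ensemble_sapsa(fx, block_size = 4)
  md <- fx$metadata
  expect_equal(es$per_frame,
               ifelse(md$states, md$A_exposed, md$A_shielded))
  expect_equal(md$A_exposed - md$A_shielded, 25, tolerance = 1e-2)
})

test_that("terminal methyl truncation edits topology and geometry as specified", {
  fx <- make_two_state_fixture(0.5, 30, n_frames = 4, seed = 8,
                               side_chain = "abu")
  spec <- cg_spec(fx)
  tr <- truncate_side_chain(fx, spec)
  # 3 methyl H removed; the swapped atom stays
  expect_equal(nrow(tr$topology$atoms), nrow(fx$topology$atoms) - 3L)
  cg_new <- which(fx$topology$atoms$name == "CG") # same position after drop?
  hx <- which(tr$topology$atoms$element == "H" &
                tr$topology$atoms$name == "HX")
  expect_length(hx, 1L)
  cb <- which(tr$topology$atoms$name == "CB")
  for (f in seq_len(n_frames(tr))) {
    d <- sqrt(sum((tr$coords[hx, , f] - tr$coords[cb, , f])^2))
    expect_equal(d, 1.09, tolerance = 1e-10)
    # everything except the edited atom is untouched
    keep_old <- setdiff(seq_len(nrow(fx$topology$atoms)),
                        c(cg_new, which(fx$topology$atoms$name %in%
                                          c("HG1", "HG2", "HG3"))))
    keep_new <- setdiff(seq_len(nrow(tr$topology$atoms)), hx)
    expect_equal(tr$coords[keep_new, , f], fx$coords[keep_old, , f])
  }
  # replacement H is apolar (bonded to C) and has the H radius
  expect_false(tr$topology$atoms$is_polar[hx])
  expect_equal(tr$topology$atoms$radius[hx], 1.20)
})

test_that("truncation guards: non-terminal targets and unknown elements", {
  fx <- make_two_state_fixture(0.5, 30, n_frames = 2, seed = 8)
  cb <- which(fx$topology$atoms$name == "CB")   # two heavy neighbours
  expect_error(truncate_side_chain(fx, truncation_spec(cb)), "terminal")
  expect_error(
    truncate_side_chain(fx, truncation_spec(
      which(fx$topology$atoms$name == "CG"), replacement_element = "Zz")),
    "absent from radius table")
})

test_that("per-frame SAPSA never decreases when a terminal methyl becomes H", {
  pair <- two_state_pair(20)
  tr <- truncate_side_chain(pair$A, cg_spec(pair$A))
  cfg <- surface_config()
  for (f in seq_len(20)) {
    s_a <- conformer_surface(get_frame(pair$A, f), cfg)$sapsa
    s_t <- conformer_surface(get_frame(tr, f), cfg)$sapsa
    expect_gte(s_t, s_a - 1e-9)
  }
})

test_that("an unobstructed methyl produces a strictly positive direct component", {
  # N-H plus a methyl floating beside it with clear line of sight
  atoms <- data.frame(
    name = c("N", "HN", "CC", "CG", "HG1", "HG2", "HG3"),
    element = c("N", "H", "C", "C", "H", "H", "H"),
    stringsAsFactors = FALSE)
  cg <- c(4.5, 0, 0)
  bonds <- rbind(c(1, 2), c(3, 4), c(4, 5), c(4, 6), c(4, 7))
  xyz <- rbind(c(0, 0, 0), c(-1.01, 0, 0), c(6.0, 0, 0), cg,
               cg + 1.09 * c(0.5, 0.866, 0), cg + 1.09 * c(0.5, -0.433, 0.75),
               cg + 1.09 * c(0.5, -0.433, -0.75))
  top <- classify_polarity(assign_radii(topology(atoms, bonds)))
  ens <- ensemble(top, array(xyz, dim = c(nrow(xyz), 3, 1)))
  tr <- truncate_side_chain(ens, truncation_spec(4))
  s_a <- conformer_surface(get_frame(ens, 1))$sapsa
  s_t <- conformer_surface(get_frame(tr, 1))$sapsa
  expect_gt(s_t, s_a + 1)
})

test_that("decomposition components are consistent and identity holds exactly", {
  pair <- two_state_pair(30)
  dec <- decompose_side_chain_effect(pair$A, pair$B, cg_spec(pair$A),
                                     block_size = 10)
  expect_equal(dec$direct_shielding_component +
                 dec$conformational_component,
               dec$sapsa_B$mean - dec$sapsa_A$mean, tolerance = 1e-12)
  # fixture construction: methyl never touches polar atoms
  expect_lt(abs(dec$direct_shielding_component), 0.5)
  expect_equal(dec$conformational_component,
               dec$sapsa_B$mean - dec$sapsa_A$mean, tolerance = 0.05)
  # edited-A stays at/above A and well below the more exposed B
  expect_gte(dec$sapsa_A_truncated$mean, dec$sapsa_A$mean - 1e-9)
  expect_lt(dec$sapsa_A_truncated$mean, dec$sapsa_B$mean)
})

test_that("a null edit on identical ensembles gives zero components", {
  A <- make_two_state_fixture(0.5, 30, n_frames = 10, seed = 21,
                              side_chain = "ala")
  B <- make_two_state_fixture(0.5, 30, n_frames = 10, seed = 21,
                              side_chain = "ala")
  hb <- which(A$topology$atoms$name == "HB")
  dec <- decompose_side_chain_effect(A, B, truncation_spec(hb),
                                     block_size = 5)
  expect_equal(dec$direct_shielding_component, 0, tolerance = 1e-9)
  expect_equal(dec$conformational_component, 0, tolerance = 1e-9)
})

test_that("topology mismatch after editing names the first differing atom", {
  pair <- two_state_pair(4)
  expect_error(
    decompose_side_chain_effect(pair$A, pair$A, cg_spec(pair$A),
                                block_size = 2),
    "first difference")
})

test_that("kabsch rmsd agrees with bio3d superposition", {
  set.seed(99)
  for (k in 1:5) {
    x <- matrix(rnorm(30), ncol = 3)
    th <- runif(1, 0, pi)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
               c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    y <- sweep(x %*% t(R), 2, rnorm(3), "+") + matrix(rnorm(30, 0, 0.1), ncol = 3)
    ours <- kabsch_rmsd(x, y)
    ref <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE)
    expect_lt(abs(ours - ref), 6e-4)   # bio3d rounds to 3 decimals
  }
})

test_that("leader clustering recovers a 70/30 two-state mixture", {
  fx <- make_two_state_fixture(0.7, 30, n_frames = 40, seed = 31)
  cl <- leader_cluster(fx, rmsd_cutoff = 1.0)
  expect_equal(length(cl$sizes), 2L)
  expect_equal(sum(cl$sizes), 40L)
  states <- fx$metadata$states
  dominant_members <- cl$assignment == cl$dominant_cluster
  expect_true(all(states[dominant_members] == states[which(dominant_members)[1]]))
  expect_equal(max(cl$sizes), max(sum(states), sum(!states)))
  expect_true(cl$representative %in% which(dominant_members))
  # identical frames collapse to one cluster
  one <- make_two_state_fixture(1, 30, n_frames = 8, seed = 2)
  expect_equal(length(leader_cluster(one, 1.0)$sizes), 1L)
  # deterministic given frame order
  cl2 <- leader_cluster(fx, rmsd_cutoff = 1.0)
  expect_identical(cl$assignment, cl2$assignment)
  expect_error(leader_cluster(fx, 0), "rmsd_cutoff")
})
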