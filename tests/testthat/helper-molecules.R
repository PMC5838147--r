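# shared in-code fixtures: tiny molecules and geometry utilities

# a lone polar atom with its hydrogen parked far away (no occlusion)
isolated_polar_atom <- function(element = "N") {
  top <- topology(data.frame(name = c(element, "HX"),
                             element = c(element, "H"),
                             stringsAsFactors = FALSE),
                  rbind(c(1, 2)))
  top <- classify_polarity(assign_radii(top))
  conformer(top, rbind(c(0, 0, 0), c(100, 0, 0)))
}

# seeded random compact cluster without hydrogens; polarity set directly
random_cluster <- function(n_atoms = 6, seed = 1, box = 4) {
  set.seed(seed)
  el <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
  top <- topology(data.frame(name = paste0(el, seq_len(n_atoms)),
                             element = el, stringsAsFactors = FALSE))
  top <- assign_radii(top)
  top$atoms$is_polar <- el %in% c("N", "O")
  conformer(top, matrix(runif(3 * n_atoms, 0, box), ncol = 3))
}

# icosahedron vertices (unit circumradius)
icosahedron_vertices <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, g, 0), c(1, g, 0), c(-1, -g, 0), c(1, -g, 0),
    c(0, -1, g), c(0, 1, g), c(0, -1, -g), c(0, 1, -g),
    c(g, 0, -1), c(g, 0, 1), c(-g, 0, -1), c(-g, 0, 1))
  v / sqrt(1 + g^2)
}

# small polar atom fully enclosed by a tight cage of large apolar atoms
caged_polar_conformer <- function(cage_radius = 2.2) {
  v <- icosahedron_vertices()
  n <- nrow(v) + 1L
  el <- c("N", rep("C", nrow(v)))
  top <- topology(data.frame(name = paste0(el, seq_len(n)), element = el,
                             stringsAsFactors = FALSE))
  top <- assign_radii(top)
  top$atoms$is_polar <- el == "N"
  conformer(top, rbind(c(0, 0, 0), v * cage_radius))
}

dihedral_deg <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# a dense schedule (h) for parameter-recovery checks, t = 0 included
dense_schedule <- function() sort(unique(c(0, seq(0.05, 4, by = 0.05),
                                           seq(4, 48, by = 0.5))))
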