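# independent brute-force oracle: Monte-Carlo surface integration with
# uniform random directions (the engine uses deterministic golden-spiral
# points, so the two routes share no discretization)

mc_atom_area <- function(i, xyz, radii, probe = 1.4, n_samples = 2e5,
                         seed = 1, chunk = 5e4) {
  R <- radii + probe
  di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  nbr <- which(di < R[i] + R & seq_along(R) != i)
  if (!length(nbr)) return(4 * pi * R[i]^2)
  set.seed(seed + i)
  hits <- 0
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    u <- matrix(rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, m)
    for (j in nbr) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= R[j]^2
    }
    hits <- hits + sum(exposed)
    done <- done + m
  }
  hits / n_samples * 4 * pi * R[i]^2
}

mc_total_sasa <- function(conf, probe = 1.4, n_samples = 2e5, seed = 1) {
  radii <- conf$topology$atoms$radius
  sum(vapply(seq_len(nrow(conf$xyz)), mc_atom_area, numeric(1),
             xyz = conf$xyz, radii = radii, probe = probe,
             n_samples = n_samples, seed = seed))
}
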