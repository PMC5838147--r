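#' Infer covalent bonds from interatomic distances
#'
#' Distance rule: atoms i and j are bonded iff
#' `d_ij <= scale * (r_i + r_j) + tolerance`, with radii taken from the
#' vdW table (default scale 0.6, tolerance 0 Å).  The rule is a covalent
#' proxy on vdW radii, e.g. N-H at 1.01 Å is bonded because
#' 1.01 <= 0.6 * (1.55 + 1.20) = 1.65.
#'
#' Every hydrogen must end up with exactly one bond; otherwise the
#' offending atoms are reported and the caller must supply explicit
#' bonds (CONECT records or a bond file).
#'
#' @param conf A [conformer()] (coordinates are required).
#' @param radius_table Element -> vdW radius (Å); default [bondi_radii()].
#' @param tolerance Additive slack in Å (default 0).
#' @param scale Multiplier on the radius sum (default 0.6).
#' @return Two-column integer matrix of 1-based bonded pairs.
#' @export
infer_bonds <- function(conf, radius_table = bondi_radii(),
                        tolerance = 0, scale = 0.6) {
  stopifnot(inherits(conf, "conformer"))
  top <- assign_radii(conf$topology, radius_table)
  r <- top$atoms$radius
  n <- n_atoms(top)
  d <- as.matrix(stats::dist(conf$xyz))
  cut <- scale * outer(r, r, "+") + tolerance
  adj <- d <= cut
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  bonds <- normalize_bonds(idx, n)
  h <- which(top$atoms$element == "H")
  if (length(h)) {
    deg <- tabulate(c(bonds), nbins = n)
    bad <- h[deg[h] != 1L]
    if (length(bad)) {
      stop("bond inference left hydrogen(s) with != 1 bond: ",
           paste0(top$atoms$name[bad], " (index ", bad, ")", collapse = ", "),
           "; supply CONECT records or an explicit bond file", call. = FALSE)
    }
  }
  bonds
}

#' Classify atoms as polar or apolar
#'
#' The polar set is all nitrogen, all oxygen, and every hydrogen bonded
#' to a nitrogen or oxygen; everything else (C, S, H on C, ...) is
#' apolar.  This is the atom set whose accessible area defines the
#' SAPSA.  Classification is a pure function of the topology; bonds must
#' be present and explicit hydrogens are required (structures without
#' hydrogens are rejected rather than silently protonated).
#'
#' @param top A [topology()] with bonds.
#' @return The topology with `atoms$is_polar` set.
#' @export
classify_polarity <- function(top) {
  stopifnot(inherits(top, "topology"))
  el <- top$atoms$element
  if (!any(el == "H")) {
    stop("no hydrogens in topology: explicit hydrogens are required for ",
         "polar-surface classification (protonation is not performed)",
         call. = FALSE)
  }
  if (!nrow(top$bonds)) {
    stop("bonds are required to classify hydrogen polarity; run ",
         "infer_bonds() or supply explicit bonds", call. = FALSE)
  }
  polar <- el %in% c("N", "O")
  for (i in which(el == "H")) {
    nb <- bonded_to(top, i)
    polar[i] <- any(el[nb] %in% c("N", "O"))
  }
  top$atoms$is_polar <- polar
  top
}

#' Read an explicit bond file
#'
#' Two whitespace-separated integer columns of 0-based atom indices,
#' one bond per line.
#'
#' @param path File path.
#' @param n_atoms Atom count, for range checking.
#' @return Two-column integer matrix of 1-based pairs.
#' @export
read_bond_file <- function(path, n_atoms) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "integer"))
  if (ncol(m) != 2L) stop("bond file must have two columns", call. = FALSE)
  normalize_bonds(m + 1L, n_atoms)
}
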