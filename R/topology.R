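#' Build a molecular topology
#'
#' A topology is the frame-independent part of a conformational
#' ensemble: the atom table and the bond list.  Atom indices are 1-based
#' throughout the package (externally supplied bond files are 0-based;
#' see [read_bond_file()]).
#'
#' @param atoms `data.frame` with columns `name` (atom name),
#'   `element` (symbol), and optionally `resname`, `resid`.  Columns
#'   `radius` and `is_polar` are added/kept and may be `NA` until
#'   [assign_radii()] and [classify_polarity()] run.
#' @param bonds Two-column integer matrix of 1-based atom index pairs
#'   (unordered); may have zero rows.
#' @return Object of class `"topology"`.
#' @seealso [assign_radii()], [classify_polarity()], [ensemble()]
#' @export
topology <- function(atoms, bonds = matrix(integer(), ncol = 2)) {
  stopifnot(is.data.frame(atoms), all(c("name", "element") %in% names(atoms)))
  n <- nrow(atoms)
  if (n < 1L) stop("topology needs at least one atom", call. = FALSE)
  if (is.null(atoms$resname)) atoms$resname <- "LIG"
  if (is.null(atoms$resid)) atoms$resid <- 1L
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$is_polar)) atoms$is_polar <- NA
  bonds <- normalize_bonds(bonds, n)
  top <- structure(list(atoms = atoms, bonds = bonds), class = "topology")
  check_hydrogen_valence(top)
  top
}

normalize_bonds <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > n_atoms)) {
      stop("bond index out of range [1, ", n_atoms, "]", call. = FALSE)
    }
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond found", call. = FALSE)
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  dimnames(bonds) <- NULL
  bonds
}

# every explicit hydrogen must carry exactly one bond (needed by the
# polar-hydrogen rule); topologies without any bonds are left alone so
# that inference can still run later
check_hydrogen_valence <- function(top) {
  if (!nrow(top$bonds)) return(invisible(top))
  h <- which(top$atoms$element == "H")
  if (!length(h)) return(invisible(top))
  deg <- tabulate(c(top$bonds), nbins = nrow(top$atoms))
  bad <- h[deg[h] != 1L]
  if (length(bad)) {
    stop("hydrogen atom(s) with != 1 bond: ",
         paste0(top$atoms$name[bad], " (index ", bad, ", ", deg[bad],
                " bonds)", collapse = ", "),
         call. = FALSE)
  }
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Assign van der Waals radii to a topology
#'
#' @param top A [topology()].
#' @param radius_table Named numeric vector, element -> radius (Å);
#'   default [bondi_radii()].
#' @return The topology with `atoms$radius` filled.
#' @export
assign_radii <- function(top, radius_table = bondi_radii()) {
  check_radius_table(radius_table)
  el <- top$atoms$element
  unknown <- setdiff(unique(el), names(radius_table))
  if (length(unknown)) {
    stop("element(s) missing from radius table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  top$atoms$radius <- unname(radius_table[el])
  top
}

bonded_to <- function(top, i) {
  b <- top$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

#' Construct a single conformer
#'
#' @param top A [topology()].
#' @param xyz Numeric matrix, one row per atom, columns x/y/z (Å).
#' @param frame_index Integer frame label.
#' @param time_ps Optional time stamp (ps).
#' @return Object of class `"conformer"`.
#' @export
conformer <- function(top, xyz, frame_index = 1L, time_ps = NA_real_) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != n_atoms(top)) {
    stop("xyz must be an n_atoms x 3 numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  structure(list(topology = top, xyz = unname(xyz),
                 frame_index = as.integer(frame_index), time_ps = time_ps),
            class = "conformer")
}

#' Construct a conformational ensemble
#'
#' All frames share one topology; coordinates live in an
#' `n_atoms x 3 x n_frames` array.
#'
#' @param top A [topology()].
#' @param coords `n_atoms x 3 x n_frames` array, a list of
#'   `n_atoms x 3` matrices, or a single matrix (one frame).
#' @param metadata Free-form list (source, seed, sampler settings, ...).
#' @return Object of class `"ensemble"`.
#' @export
ensemble <- function(top, coords, metadata = list()) {
  if (is.list(coords) && !is.array(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  if (dim(coords)[1] != n_atoms(top) || dim(coords)[2] != 3L) {
    stop("coordinate array must be n_atoms x 3 x n_frames", call. = FALSE)
  }
  if (dim(coords)[3] < 1L) stop("ensemble needs at least one frame", call. = FALSE)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  structure(list(topology = top, coords = coords, metadata = metadata),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", dim(x$coords)[3], "frames x", n_atoms(x$topology), "atoms\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens An [ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Extract one frame of an ensemble as a conformer
#' @param ens An [ensemble()].
#' @param i Frame index (1-based).
#' @return A [conformer()].
#' @export
get_frame <- function(ens, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(ens)) stop("frame index out of range", call. = FALSE)
  conformer(ens$topology, ens$coords[, , i, drop = TRUE], frame_index = i)
}
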