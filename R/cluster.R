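#' Best-fit (Kabsch) RMSD between two coordinate sets
#'
#' Centres both sets, finds the optimal proper rotation by singular
#' value decomposition of the covariance matrix, and returns the
#' root-mean-square deviation after superposition.
#'
#' @param x,y `n x 3` coordinate matrices over the same atoms.
#' @return RMSD in Å.
#' @export
kabsch_rmsd <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)), ncol(x) == 3)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xc - yc %*% rot)^2)))
}

#' Leader clustering of a conformational ensemble
#'
#' Frames are visited in order; a frame joins the first existing cluster
#' whose leader it matches within `rmsd_cutoff` (heavy-atom, best-fit
#' RMSD), otherwise it founds a new cluster.  Deterministic given the
#' frame order.  The dominant cluster is the largest (earliest leader
#' wins ties) and its representative is the member frame with the
#' smallest mean RMSD to all other members.
#'
#' @param ens An [ensemble()].
#' @param rmsd_cutoff Cluster radius in Å (> 0); default 1.0.
#' @return Object of class `"leader_clustering"`: `assignment` (integer
#'   per frame), `leaders` (frame indices), `sizes`,
#'   `dominant_cluster`, `representative` (frame index).
#' @export
leader_cluster <- function(ens, rmsd_cutoff = 1.0) {
  stopifnot(inherits(ens, "ensemble"))
  if (rmsd_cutoff <= 0) stop("rmsd_cutoff must be > 0", call. = FALSE)
  heavy <- which(ens$topology$atoms$element != "H")
  nf <- n_frames(ens)
  xyz <- function(f) matrix(ens$coords[heavy, , f], ncol = 3)
  leaders <- integer()
  assignment <- integer(nf)
  for (f in seq_len(nf)) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (kabsch_rmsd(xyz(leaders[k]), xyz(f)) <= rmsd_cutoff) {
        assignment[f] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, f)
      assignment[f] <- length(leaders)
    }
  }
  sizes <- tabulate(assignment, nbins = length(leaders))
  dominant <- which.max(sizes)
  members <- which(assignment == dominant)
  if (length(members) == 1L) {
    rep_frame <- members
  } else {
    mean_rmsd <- vapply(members, function(f) {
      mean(vapply(setdiff(members, f),
                  function(g) kabsch_rmsd(xyz(f), xyz(g)), numeric(1)))
    }, numeric(1))
    rep_frame <- members[which.min(mean_rmsd)]
  }
  structure(list(assignment = assignment, leaders = leaders, sizes = sizes,
                 dominant_cluster = dominant, representative = rep_frame,
                 rmsd_cutoff = rmsd_cutoff),
            class = "leader_clustering")
}

#' @export
print.leader_clustering <- function(x, ...) {
  cat(sprintf(
    "leader_clustering: %d cluster(s) at %.2f A cutoff; dominant %d (%d/%d frames), representative frame %d\n",
    length(x$sizes), x$rmsd_cutoff, x$dominant_cluster,
    x$sizes[x$dominant_cluster], sum(x$sizes), x$representative))
  invisible(x)
}
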