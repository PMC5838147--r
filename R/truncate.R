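#' Specification of a terminal side-chain truncation
#'
#' Describes replacing a terminal heavy atom (e.g. the Cγ methyl carbon
#' of a 2-aminobutyryl side chain) by a lighter element (default H),
#' turning an ethyl side chain into the methyl of the alanine analogue
#' on the *same* trajectory.
#'
#' @param target_atom 1-based index of the terminal heavy atom to
#'   replace.  It must have exactly one bonded heavy-atom neighbour.
#' @param replacement_element Element symbol for the replacement
#'   (default `"H"`).
#' @param new_bond_length Distance (Å) from the heavy neighbour at which
#'   the replacement is placed, along the old bond vector (default 1.09,
#'   a standard C-H length).
#' @return Object of class `"truncation_spec"`.
#' @export
truncation_spec <- function(target_atom, replacement_element = "H",
                            new_bond_length = 1.09) {
  stopifnot(length(target_atom) == 1L, target_atom >= 1)
  if (new_bond_length <= 0) stop("new_bond_length must be > 0", call. = FALSE)
  structure(list(target_atom = as.integer(target_atom),
                 replacement_element = replacement_element,
                 new_bond_length = new_bond_length),
            class = "truncation_spec")
}

#' Replace a terminal heavy atom by a lighter one across a trajectory
#'
#' In every frame: the hydrogens bonded to the target atom are deleted,
#' the target atom's element is changed to the replacement (radius
#' re-assigned, polarity re-derived), and the atom is repositioned along
#' the unit vector from its heavy neighbour at `new_bond_length`.  All
#' other coordinates are untouched, so the edited ensemble shares the
#' original's scaffold geometry — this is what isolates direct shielding
#' from conformational effects in [decompose_side_chain_effect()].
#'
#' @param ens An [ensemble()].
#' @param spec A [truncation_spec()].
#' @param radius_table Element -> radius (Å) for re-assignment.
#' @return The edited [ensemble()]; metadata records the edit.
#' @export
truncate_side_chain <- function(ens, spec, radius_table = bondi_radii()) {
  stopifnot(inherits(ens, "ensemble"), inherits(spec, "truncation_spec"))
  top <- ens$topology
  el <- top$atoms$element
  t_idx <- spec$target_atom
  if (t_idx > n_atoms(top)) stop("target atom out of range", call. = FALSE)
  nb <- bonded_to(top, t_idx)
  heavy_nb <- nb[el[nb] != "H"]
  if (length(heavy_nb) != 1L) {
    stop("target atom must be terminal (exactly 1 heavy neighbour, found ",
         length(heavy_nb), ")", call. = FALSE)
  }
  if (!spec$replacement_element %in% names(radius_table)) {
    stop("replacement element '", spec$replacement_element,
         "' absent from radius table", call. = FALSE)
  }
  h_nb <- nb[el[nb] == "H"]
  keep <- setdiff(seq_len(n_atoms(top)), h_nb)

  atoms <- top$atoms[keep, , drop = FALSE]
  new_map <- match(seq_len(n_atoms(top)), keep)       # old -> new index
  t_new <- new_map[t_idx]
  a_new <- new_map[heavy_nb]
  atoms$element[t_new] <- spec$replacement_element
  atoms$name[t_new] <- paste0(spec$replacement_element, "X")
  rownames(atoms) <- NULL

  b <- top$bonds
  b <- b[!(b[, 1] %in% h_nb | b[, 2] %in% h_nb), , drop = FALSE]
  b[] <- new_map[b]
  new_top <- topology(atoms, b)
  new_top <- assign_radii(new_top, radius_table)
  new_top <- classify_polarity(new_top)

  coords <- ens$coords[keep, , , drop = FALSE]
  for (f in seq_len(dim(coords)[3])) {
    v <- coords[t_new, , f] - coords[a_new, , f]
    coords[t_new, , f] <- coords[a_new, , f] +
      v / sqrt(sum(v^2)) * spec$new_bond_length
  }
  md <- ens$metadata
  md$truncation <- list(target_atom = t_idx, removed_h = h_nb,
                        replacement = spec$replacement_element,
                        new_bond_length = spec$new_bond_length)
  ensemble(new_top, coords, metadata = md)
}

#' Decompose a side-chain SAPSA difference into shielding and
#' conformational components
#'
#' Given ensemble A (the larger side chain), ensemble B (the smaller
#' analogue, its own independently sampled ensemble), and a truncation
#' turning A's topology into B's, the SAPSA difference splits as
#'
#' * direct shielding = `mean(A truncated) - mean(A)` — what the extra
#'   group hides while the scaffold geometry is held fixed;
#' * conformational = `mean(B) - mean(A truncated)` — what the group
#'   changes by shifting the scaffold's conformer distribution.
#'
#' The two components sum to `mean(B) - mean(A)` by construction.
#'
#' @param ensemble_A,ensemble_B [ensemble()] objects with radii and
#'   polarity assigned.
#' @param spec A [truncation_spec()] applied to `ensemble_A`.
#' @param config A [surface_config()].
#' @param block_size Frames per block for the three SAPSA series.
#' @param radius_table Element -> radius (Å).
#' @return Object of class `"sapsa_decomposition"` with the three
#'   `ensemble_sapsa` series and the two components (Å²).
#' @export
decompose_side_chain_effect <- function(ensemble_A, ensemble_B, spec,
                                        config = surface_config(),
                                        block_size = 1000L,
                                        radius_table = bondi_radii()) {
  a_trunc <- truncate_side_chain(ensemble_A, spec, radius_table)
  el_t <- a_trunc$topology$atoms$element
  el_b <- ensemble_B$topology$atoms$element
  if (length(el_t) != length(el_b) || any(el_t != el_b)) {
    bad <- if (length(el_t) != length(el_b)) {
      min(length(el_t), length(el_b)) + 1L
    } else {
      which(el_t != el_b)[1]
    }
    stop("post-edit topology does not match ensemble_B: first difference ",
         "at atom ", bad, call. = FALSE)
  }
  sapsa_A <- ensemble_sapsa(ensemble_A, config, block_size)
  sapsa_B <- ensemble_sapsa(ensemble_B, config, block_size)
  sapsa_At <- ensemble_sapsa(a_trunc, config, block_size)
  structure(list(
    sapsa_A = sapsa_A, sapsa_B = sapsa_B, sapsa_A_truncated = sapsa_At,
    direct_shielding_component = sapsa_At$mean - sapsa_A$mean,
    conformational_component = sapsa_B$mean - sapsa_At$mean
  ), class = "sapsa_decomposition")
}

#' @export
print.sapsa_decomposition <- function(x, ...) {
  cat(sprintf(paste0(
    "SAPSA decomposition (A^2):\n",
    "  mean A            %8.2f\n  mean A truncated  %8.2f\n",
    "  mean B            %8.2f\n  direct shielding  %8.2f\n",
    "  conformational    %8.2f\n"),
    x$sapsa_A$mean, x$sapsa_A_truncated$mean, x$sapsa_B$mean,
    x$direct_shielding_component, x$conformational_component))
  invisible(x)
}
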