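#' Bondi van der Waals radii
#'
#' The standard Bondi radius set used for both the conventional polar
#' surface area and the 3D solvent-accessible polar surface area
#' (SAPSA).  Values are in Angstrom.
#'
#' @return Named numeric vector mapping element symbol to vdW radius (Å).
#' @examples
#' bondi_radii()[["N"]]
#' @export
bondi_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, H = 1.20, S = 1.80)
}

#' Read a radius / bond-inference configuration file
#'
#' The configuration is a YAML mapping with a `radii:` block
#' (element -> radius in Å) and an optional `bond_scale:` scalar used by
#' [infer_bonds()] (default 0.6).  A reference file with the Bondi set
#' ships with the package; see
#' `system.file("extdata", "bondi.yaml", package = "sapsa")`.
#'
#' @param path Path to a YAML file.
#' @return List with elements `radii` (named numeric vector) and
#'   `bond_scale` (scalar).
#' @export
read_radius_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$radii)) {
    stop("radius config must contain a 'radii:' mapping", call. = FALSE)
  }
  radii <- unlist(cfg$radii)
  if (any(is.na(names(radii)) | names(radii) %in% c("TRUE", "FALSE"))) {
    stop("element symbols in the radii mapping must be quoted ",
         "(bare N and Y are YAML booleans)", call. = FALSE)
  }
  check_radius_table(radii)
  scale <- if (is.null(cfg$bond_scale)) 0.6 else as.numeric(cfg$bond_scale)
  list(radii = radii, bond_scale = scale)
}

check_radius_table <- function(radii) {
  if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
    stop("radius table must be a named vector (element -> Å)", call. = FALSE)
  }
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all radii must be positive and finite", call. = FALSE)
  }
  invisible(radii)
}
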