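#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each `MODEL` block becomes one frame (a file without `MODEL` records
#' is a single-frame ensemble).  All models must contain the same number
#' of atoms.  Elements are taken from the element column when present,
#' falling back to an atom-name heuristic.  Bond source precedence:
#' `CONECT` records, then an explicit bond file, then distance inference
#' on the first frame (see [infer_bonds()]).
#'
#' @param path PDB file path.
#' @param bond_file Optional path to a 0-based two-column bond file.
#' @param radius_table Element -> radius (Å) for radius assignment and
#'   bond inference; default [bondi_radii()].
#' @param bond_scale Scale factor for distance-based bond inference.
#' @param classify If `TRUE` (default) also assign radii and polarity.
#' @return An [ensemble()].
#' @export
read_multimodel_pdb <- function(path, bond_file = NULL,
                                radius_table = bondi_radii(),
                                bond_scale = 0.6, classify = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  check_model_atom_counts(lines, path)

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  el <- trimws(at$elesy)
  missing_el <- !nzchar(el) | is.na(el)
  if (any(missing_el)) el[missing_el] <- guess_element(at$elety[missing_el])
  el <- paste0(toupper(substr(el, 1, 1)),
               tolower(substr(el, 2, nchar(el))))
  unknown <- !(el %in% names(radius_table))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("unknown element '", el[i], "' for atom ", at$elety[i],
         " (serial ", at$eleno[i], ")", call. = FALSE)
  }

  atoms <- data.frame(name = trimws(at$elety), element = el,
                      resname = trimws(at$resid), resid = at$resno,
                      stringsAsFactors = FALSE)
  n <- nrow(atoms)
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, dim = c(n, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }

  bonds <- parse_conect(lines, serials = at$eleno, n_atoms = n)
  if (!nrow(bonds) && !is.null(bond_file)) bonds <- read_bond_file(bond_file, n)
  top <- topology(atoms, bonds)
  if (!nrow(top$bonds)) {
    top$bonds <- infer_bonds(conformer(top, coords[, , 1, drop = TRUE]),
                             radius_table = radius_table, scale = bond_scale)
  }
  if (classify) {
    top <- assign_radii(top, radius_table)
    top <- classify_polarity(top)
  }
  ensemble(top, coords, metadata = list(source = path))
}

# per-MODEL ATOM/HETATM counts must agree; report the first offender
check_model_atom_counts <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  model_starts <- which(startsWith(rec, "MODEL"))
  if (length(model_starts) < 2L) return(invisible(TRUE))
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- findInterval(seq_along(lines), model_starts)
  counts <- tapply(is_atom[model_id > 0], model_id[model_id > 0], sum)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[[1]])[1]
    stop("inconsistent atom count across models in ", path, ": model ",
         names(counts)[bad], " has ", counts[[bad]], " atoms, expected ",
         counts[[1]], call. = FALSE)
  }
  invisible(TRUE)
}

parse_conect <- function(lines, serials, n_atoms) {
  con <- lines[startsWith(lines, "CONECT")]
  if (!length(con)) return(matrix(integer(), ncol = 2))
  pairs <- list()
  for (ln in con) {
    ints <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)),
                                                 "\\s+")[[1]]))
    ints <- ints[!is.na(ints)]
    if (length(ints) >= 2L) {
      pairs[[length(pairs) + 1L]] <- cbind(ints[1], ints[-1])
    }
  }
  m <- do.call(rbind, pairs)
  idx <- match(as.vector(m), serials)
  if (any(is.na(idx))) stop("CONECT references unknown atom serial",
                            call. = FALSE)
  normalize_bonds(matrix(idx, ncol = 2), n_atoms)
}

guess_element <- function(name) {
  name <- trimws(name)
  # strip leading digits (e.g. 1HG1), then take the leading letters;
  # two-letter organics are rare in peptides, so first letter wins
  core <- sub("^[0-9]+", "", name)
  toupper(substr(core, 1, 1))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard `MODEL`/`ENDMDL` records (coordinates at 3 decimals)
#' and `CONECT` records for the topology's bonds, so the file round-trips
#' through [read_multimodel_pdb()].
#'
#' @param ens An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  at <- ens$topology$atoms
  n <- nrow(at)
  out <- character()
  for (f in seq_len(n_frames(ens))) {
    xyz <- ens$coords[, , f, drop = TRUE]
    out <- c(out, sprintf("MODEL     %4d", f),
             sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(n), format_atom_name(at$name),
                     substr(at$resname, 1, 3), "A", at$resid,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                     toupper(at$element)),
             "ENDMDL")
  }
  b <- ens$topology$bonds
  if (nrow(b)) {
    out <- c(out, sprintf("CONECT%5d%5d", b[, 1], b[, 2]))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

# PDB convention: names of <= 3 chars start in column 14
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(" ", name))
}
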