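#' Parameterised molecular systems
#'
#' A `prb_system` bundles an atom table (one row per atom) with the probe
#' bookkeeping needed by the sampler and the trajectory analyses. The atom
#' table is an ordinary tibble, so the usual dplyr verbs work on
#' `atoms(sys)`; the constructor validates the invariants the rest of the
#' package relies on.
#'
#' Columns of the atom table: `serial`, `name`, `element`, `resname`,
#' `resid`, `chain`, `x`, `y`, `z` (Angstrom), `charge` (e),
#' `epsilon` (LJ well depth, kcal/mol), `rmin_half` (Rmin/2, Angstrom),
#' `mass` (amu), `is_probe`, `hydrophobic`. Parameters may be `NA` for a
#' freshly read structure; analyses that need them check first.
#' `hydrophobic` is derived from the element (C and S hydrophobic, all
#' other elements hydrophilic) and is recomputed on construction.
#'
#' @param atoms data frame with at least `name`, `element`, `resname`,
#'   `resid`, `chain`, `x`, `y`, `z`; missing parameter columns are added
#'   as `NA`.
#' @param probes list of integer vectors, each giving the atom rows of one
#'   probe molecule. Groups must be disjoint.
#' @return A `prb_system` object.
#' @export
new_system <- function(atoms, probes = list()) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("name", "element", "resname", "resid", "chain", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("atom table is empty")
  for (col in c("charge", "epsilon", "rmin_half", "mass")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"is_probe" %in% names(atoms)) atoms$is_probe <- FALSE
  if (any(!nzchar(atoms$element) | is.na(atoms$element))) {
    abort("every atom needs a non-empty element symbol")
  }
  bad_eps <- !is.na(atoms$epsilon) & atoms$epsilon < 0
  if (any(bad_eps)) {
    abort(paste0("negative LJ epsilon for atom(s) ",
                 paste(which(bad_eps), collapse = ", ")))
  }
  bad_mass <- !is.na(atoms$mass) & atoms$mass <= 0
  if (any(bad_mass)) {
    abort(paste0("non-positive mass for atom(s) ",
                 paste(which(bad_mass), collapse = ", ")))
  }
  atoms$hydrophobic <- atoms$element %in% c("C", "S")
  atoms <- atoms[c("serial", "name", "element", "resname", "resid", "chain",
                   "x", "y", "z", "charge", "epsilon", "rmin_half", "mass",
                   "is_probe", "hydrophobic")]
  probes <- lapply(probes, as.integer)
  if (length(probes) > 0) {
    all_idx <- unlist(probes)
    if (anyDuplicated(all_idx)) abort("probe groups must be disjoint")
    if (any(all_idx < 1 | all_idx > nrow(atoms))) {
      abort("probe group index out of range")
    }
    atoms$is_probe <- seq_len(nrow(atoms)) %in% all_idx
  }
  structure(list(atoms = atoms, probes = probes), class = "prb_system")
}

#' @export
print.prb_system <- function(x, ...) {
  n_res <- nrow(dplyr::distinct(x$atoms, .data$chain, .data$resid))
  cat(sprintf("<prb_system> %d atoms, %d residues, %d probe molecule(s)\n",
              nrow(x$atoms), n_res, length(x$probes)))
  invisible(x)
}

#' Atom table of a system
#' @param system a `prb_system`
#' @return tibble of atoms
#' @export
atoms <- function(system) system$atoms

#' Coordinates of a system as a matrix
#' @param system a `prb_system`
#' @param idx optional integer row subset
#' @return numeric matrix (n x 3)
#' @export
system_coords <- function(system, idx = NULL) {
  a <- system$atoms
  if (!is.null(idx)) a <- a[idx, ]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Replace coordinates of a system
#' @param system a `prb_system`
#' @param coords matrix (n x 3) matching the atom count
#' @return updated system
#' @export
set_coords <- function(system, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(system$atoms)) {
    abort("coordinate matrix does not match atom count")
  }
  system$atoms$x <- coords[, 1]
  system$atoms$y <- coords[, 2]
  system$atoms$z <- coords[, 3]
  system
}

#' Atom indices by predicate
#'
#' Tidy selection over the atom table: `select_atoms(sys, element != "H",
#' !is_probe)` returns the matching row indices.
#'
#' @param system a `prb_system`
#' @param ... filter conditions evaluated in the atom table
#' @return integer vector of atom rows
#' @export
select_atoms <- function(system, ...) {
  a <- dplyr::mutate(system$atoms, .row = dplyr::row_number())
  dplyr::filter(a, ...)$.row
}

#' Heavy (non-hydrogen) atom indices
#' @param system a `prb_system`
#' @param receptor_only drop probe atoms
#' @return integer vector
#' @export
heavy_atoms <- function(system, receptor_only = FALSE) {
  keep <- system$atoms$element != "H"
  if (receptor_only) keep <- keep & !system$atoms$is_probe
  which(keep)
}

#' All probe atom indices
#' @param system a `prb_system`
#' @return integer vector (empty if no probes)
#' @export
probe_atoms <- function(system) {
  as.integer(unlist(system$probes))
}

#' Residue index of a system
#'
#' @param system a `prb_system`
#' @param receptor_only drop probe residues
#' @return tibble with `chain`, `resid`, `resname` and a list column
#'   `atom_idx` of atom rows
#' @export
residue_index <- function(system, receptor_only = FALSE) {
  a <- dplyr::mutate(system$atoms, .row = dplyr::row_number())
  if (receptor_only) a <- dplyr::filter(a, !.data$is_probe)
  dplyr::summarise(
    dplyr::group_by(a, .data$chain, .data$resid),
    resname = .data$resname[1],
    atom_idx = list(.data$.row),
    .groups = "drop"
  )
}

#' Atom rows of one residue
#' @param system a `prb_system`
#' @param chain chain identifier
#' @param resid residue number
#' @param heavy_only keep heavy atoms only
#' @return integer vector of atom rows (error if the residue is unknown)
#' @export
residue_atoms <- function(system, chain, resid, heavy_only = TRUE) {
  a <- system$atoms
  idx <- which(a$chain == chain & a$resid == resid)
  if (length(idx) == 0) {
    abort(sprintf("unknown residue %s:%s", chain, resid))
  }
  if (heavy_only) idx <- idx[a$element[idx] != "H"]
  idx
}

# atoms must all carry charge/LJ parameters; error naming offenders
check_parameterized <- function(system, idx = seq_len(nrow(system$atoms))) {
  a <- system$atoms[idx, ]
  bad <- is.na(a$charge) | is.na(a$epsilon) | is.na(a$rmin_half)
  if (any(bad)) {
    abort(paste0("unparameterized atoms (missing charge/LJ): serial ",
                 paste(a$serial[bad], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Assign generic per-element parameters
#'
#' Fills missing charge (0), LJ well depth, Rmin/2 and mass with generic
#' per-element values. Intended for structures read from PDB, which carry
#' no force-field parameters; real probe molecules should come from a
#' probe definition file instead.
#'
#' @param system a `prb_system`
#' @return updated system
#' @export
set_default_parameters <- function(system) {
  eps_tab <- c(C = 0.07, N = 0.17, O = 0.15, S = 0.3, H = 0.03, P = 0.4)
  rmin_tab <- c(C = 2.0, N = 1.85, O = 1.7, S = 2.0, H = 1.2, P = 2.1)
  mass_tab <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                H = 1.008, P = 30.974)
  a <- system$atoms
  el <- a$element
  fill <- function(cur, tab, default) {
    v <- unname(tab[el])
    v[is.na(v)] <- default
    ifelse(is.na(cur), v, cur)
  }
  a$charge <- ifelse(is.na(a$charge), 0, a$charge)
  a$epsilon <- fill(a$epsilon, eps_tab, 0.1)
  a$rmin_half <- fill(a$rmin_half, rmin_tab, 2.0)
  a$mass <- fill(a$mass, mass_tab, 12.011)
  system$atoms <- a
  system
}
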