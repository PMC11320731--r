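#' Nonbonded interaction model
#'
#' Coulomb plus Lennard-Jones energetics with a finite cutoff. The
#' electrostatic term is `k_c q_i q_j / (eps_r r)` with
#' `k_c = 332.0637 kcal A mol^-1 e^-2`; the LJ term is
#' `eps_ij ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with geometric-mean well
#' depths and `Rmin_ij = Rmin_i/2 + Rmin_j/2`. With `switching`, both
#' terms are scaled by a smooth switching function between
#' `switch_start` and `cutoff`, keeping forces continuous; otherwise
#' interactions are truncated at the cutoff. `cutoff = Inf` disables
#' truncation.
#'
#' @param cutoff Angstrom (default 12)
#' @param dielectric relative dielectric constant
#' @param switching logical
#' @param switch_start Angstrom
#' @return a `nonbonded_model`
#' @export
nonbonded_model <- function(cutoff = 12, dielectric = 1,
                            switching = FALSE, switch_start = 10) {
  if (cutoff <= 0) abort("cutoff must be > 0 (use Inf for none)")
  if (dielectric <= 0) abort("dielectric must be > 0")
  if (switching && switch_start >= cutoff) {
    abort("switch_start must be below the cutoff")
  }
  structure(list(coulomb_k = COULOMB_K, dielectric = dielectric,
                 cutoff = cutoff, switching = isTRUE(switching),
                 switch_start = switch_start),
            class = "nonbonded_model")
}

# cutoff argument for the C++ kernels: <= 0 means "no cutoff"
model_cut <- function(model) if (is.finite(model$cutoff)) model$cutoff else -1

atoms_to_param <- function(a) {
  list(x = cbind(a$x, a$y, a$z), q = a$charge, e = a$epsilon, r = a$rmin_half)
}

#' Pairwise interaction energy between two atom sets
#'
#' Sums Coulomb and Lennard-Jones energies over all cross pairs under
#' the model's cutoff. Atom sets are rows of a system's atom table (see
#' [atoms()]); all atoms must carry charges and LJ parameters.
#'
#' @param atoms_a,atoms_b data frames of atoms (`x`, `y`, `z`, `charge`,
#'   `epsilon`, `rmin_half`)
#' @param model a [nonbonded_model()]
#' @return tibble with one row: `elec` and `vdw` (kcal/mol)
#' @export
pair_energy <- function(atoms_a, atoms_b, model = nonbonded_model()) {
  for (a in list(atoms_a, atoms_b)) {
    bad <- is.na(a$charge) | is.na(a$epsilon) | is.na(a$rmin_half)
    if (any(bad)) {
      abort(paste0("unparameterized atoms (missing charge/LJ): row(s) ",
                   paste(which(bad), collapse = ", ")))
    }
  }
  pa <- atoms_to_param(atoms_a)
  pb <- atoms_to_param(atoms_b)
  res <- nb_cross_cpp(pa$x, pb$x, pa$q, pb$q, pa$e, pb$e, pa$r, pb$r,
                      model$coulomb_k, model$dielectric, model_cut(model),
                      model$switching, model$switch_start, FALSE)
  tibble::tibble(elec = res$elec, vdw = res$vdw)
}
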