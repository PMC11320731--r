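#' Probe molecule templates
#'
#' A probe template is a rigid small molecule: atom names, elements, 3D
#' coordinates, partial charges and Lennard-Jones parameters. Templates
#' are read from a whitespace-delimited table with a header line and one
#' row per atom (`name element x y z charge epsilon rmin_half mass`).
#' Two fragment-like templates mirroring common mapping probes, an
#' N-methylthiophene-2-sulfonamide (`nms`) and a
#' 4-methoxy-1-methylindazole (`mmi`), ship with the package; their
#' partial charges are generic placeholders and can be overridden by
#' supplying an edited definition file.
#'
#' @param path path to a probe definition file
#' @return a `probe_template`
#' @export
read_probe <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- sub("\\.[a-zA-Z]+$", "", basename(path))
  probe_template(tab, name = nm)
}

#' @rdname read_probe
#' @param atoms data frame with the columns listed above
#' @param name short template name
#' @export
probe_template <- function(atoms, name = "PRB") {
  required <- c("name", "element", "x", "y", "z", "charge", "epsilon",
                "rmin_half", "mass")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("probe definition is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  atoms <- tibble::as_tibble(atoms)[required]
  num <- atoms[c("x", "y", "z", "charge", "epsilon", "rmin_half", "mass")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    abort("probe definition contains non-finite values")
  }
  if (any(atoms$epsilon < 0)) abort("probe LJ epsilon must be >= 0")
  if (any(atoms$mass <= 0)) abort("probe atom masses must be > 0")
  structure(
    list(name = name, atoms = atoms, net_charge = sum(atoms$charge)),
    class = "probe_template"
  )
}

#' @export
print.probe_template <- function(x, ...) {
  cat(sprintf("<probe_template> %s: %d atoms, net charge %+.3f e\n",
              x$name, nrow(x$atoms), x$net_charge))
  invisible(x)
}

#' Single-bead diagnostic probe
#'
#' One neutral Lennard-Jones bead. Useful for sampler diagnostics
#' (harmonic-trap variance, diffusion) where molecular structure would
#' only obscure the physics.
#'
#' @param mass amu
#' @param epsilon LJ well depth, kcal/mol
#' @param rmin_half Rmin/2, Angstrom
#' @param charge elementary charges
#' @return a `probe_template`
#' @export
bead_probe <- function(mass = 40, epsilon = 0.2, rmin_half = 2.0,
                       charge = 0) {
  probe_template(
    data.frame(name = "BD", element = "C", x = 0, y = 0, z = 0,
               charge = charge, epsilon = epsilon, rmin_half = rmin_half,
               mass = mass),
    name = "bead"
  )
}

#' Packaged probe templates
#' @param which `"nms"` or `"mmi"`
#' @return a `probe_template`
#' @export
packaged_probe <- function(which = c("nms", "mmi")) {
  which <- match.arg(which)
  read_probe(system.file("extdata", paste0(which, ".prb"),
                         package = "probemap", mustWork = TRUE))
}

#' Recover probe groups from a round-tripped structure
#'
#' PDB files carry no probe bookkeeping, so a system read back from disk
#' has an empty probe list. This registers every residue on the probe
#' chain (written as chain `"P"` by [add_probes()]) as one rigid probe
#' molecule.
#'
#' @param system a `prb_system`
#' @param chain chain holding the probe molecules
#' @return updated `prb_system`
#' @export
infer_probes <- function(system, chain = "P") {
  a <- system$atoms
  idx <- which(a$chain == chain)
  if (length(idx) == 0) return(system)
  groups <- split(idx, a$resid[idx])
  new_system(a, probes = unname(groups))
}

#' Add probe copies to a system
#'
#' Appends `n` copies of a probe template as new residues on chain `"P"`
#' (resnames from the template, residue ids 1..n) and registers them as
#' probe groups. Copies are placed at the template coordinates; use
#' [place_probes()] to position them inside a confinement region.
#'
#' @param system a `prb_system` (receptor)
#' @param template a `probe_template`
#' @param n number of copies
#' @return updated `prb_system`
#' @export
add_probes <- function(system, template, n) {
  stopifnot(inherits(template, "probe_template"), n >= 1)
  a <- system$atoms
  t_at <- template$atoms
  resname <- toupper(substr(template$name, 1, 3))
  new_rows <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      serial = 0L, name = t_at$name, element = t_at$element,
      resname = resname, resid = i, chain = "P",
      x = t_at$x, y = t_at$y, z = t_at$z,
      charge = t_at$charge, epsilon = t_at$epsilon,
      rmin_half = t_at$rmin_half, mass = t_at$mass,
      is_probe = TRUE, hydrophobic = t_at$element %in% c("C", "S")
    )
  })
  n_t <- nrow(t_at)
  n0 <- nrow(a)
  out <- dplyr::bind_rows(a, new_rows)
  out$serial <- seq_len(nrow(out))
  probes <- c(system$probes,
              lapply(seq_len(n), function(i) n0 + (i - 1L) * n_t + seq_len(n_t)))
  new_system(out, probes = probes)
}
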