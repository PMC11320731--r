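# evenly distributed unit-sphere test points (golden spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical solvent probe (default 1.4 A, water) over the
#' selected atoms: each atom's accessible area is the fraction of
#' `n_points` test points on its expanded sphere (vdW + probe radius)
#' not buried inside any other context atom, times the sphere area.
#' The total is split into hydrophobic (C, S) and hydrophilic (all
#' other elements) contributions; the two always sum to the total.
#'
#' @param system a `prb_system` (current coordinates)
#' @param sel atom rows to report areas for (default: all receptor
#'   atoms)
#' @param context atom rows that can occlude (default: every atom of
#'   the system); must contain `sel`
#' @param probe_radius Angstrom (default 1.4)
#' @param n_points test points per atom (default 960)
#' @return a `sasa_result`: `total`, `hydrophobic`, `hydrophilic`
#'   (Angstrom^2) and a per-atom tibble
#' @export
sasa <- function(system, sel = NULL, context = NULL, probe_radius = 1.4,
                 n_points = 960) {
  a <- system$atoms
  if (is.null(sel)) sel <- which(!a$is_probe)
  if (length(sel) == 0) abort("empty selection")
  if (is.null(context)) context <- seq_len(nrow(a))
  context <- union(context, sel)
  pts <- sphere_points(n_points)
  cx <- system_coords(system, context)
  rad_c <- vdw_radius(a$element[context]) + probe_radius
  pos_in_context <- match(sel, context)
  areas <- vapply(seq_along(sel), function(k) {
    i <- pos_in_context[k]
    ri <- rad_c[i]
    center <- cx[i, ]
    d <- sqrt(colSums((t(cx) - center)^2))
    nb <- which(d < ri + rad_c & seq_along(d) != i)
    test <- sweep(pts * ri, 2, center, `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1] - cx[j, 1])^2 + (test[, 2] - cx[j, 2])^2 +
        (test[, 3] - cx[j, 3])^2
      exposed <- exposed & dj2 > rad_c[j]^2
      if (!any(exposed)) break
    }
    sum(exposed) / n_points * 4 * pi * ri^2
  }, numeric(1))
  per_atom <- tibble::tibble(
    serial = a$serial[sel], element = a$element[sel],
    hydrophobic = a$hydrophobic[sel], area = areas
  )
  hphob <- sum(areas[per_atom$hydrophobic])
  structure(list(
    total = sum(areas), hydrophobic = hphob,
    hydrophilic = sum(areas) - hphob, per_atom = per_atom,
    probe_radius = probe_radius, n_points = n_points
  ), class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "<sasa_result> total %.1f A^2 (hydrophobic %.1f, hydrophilic %.1f)\n",
    x$total, x$hydrophobic, x$hydrophilic))
  invisible(x)
}

#' @export
tidy.sasa_result <- function(x, ...) x$per_atom

#' @export
glance.sasa_result <- function(x, ...) {
  tibble::tibble(total = x$total, hydrophobic = x$hydrophobic,
                 hydrophilic = x$hydrophilic,
                 probe_radius = x$probe_radius, n_points = x$n_points)
}
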