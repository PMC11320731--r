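#' Cylindrical confinement region
#'
#' The probe-confinement geometry: a cylinder anchored at `base_point`
#' (the centre of its open face, sitting over the pocket mouth) with its
#' axis pointing away from the receptor. Inside the cylinder the wall
#' potential is zero; beyond the radial wall, or beyond the far end when
#' `closed_far_end`, a half-harmonic restraint with force constant
#' `k_wall` pushes probes back. The face at `base_point` is open so
#' probes can reach the receptor surface, which itself blocks escape on
#' that side.
#'
#' @param base_point centre of the open face, Angstrom
#' @param axis cylinder axis, pointing away from the receptor
#'   (normalised internally)
#' @param radius cylinder radius, Angstrom
#' @param length cylinder length, Angstrom
#' @param k_wall wall force constant, kcal mol^-1 A^-2
#' @param closed_far_end restrain the far end too (default)
#' @return a `cylinder_region`
#' @export
cylinder_region <- function(base_point, axis, radius, length,
                            k_wall = 10, closed_far_end = TRUE) {
  base_point <- as.numeric(base_point)
  axis <- as.numeric(axis)
  stopifnot(length(base_point) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) abort("axis vector has zero length")
  axis <- axis / nrm
  if (radius <= 0 || length <= 0) abort("radius and length must be > 0")
  if (k_wall < 0) abort("k_wall must be >= 0")
  structure(list(base_point = base_point, axis = axis, radius = radius,
                 length = length, k_wall = k_wall,
                 closed_far_end = isTRUE(closed_far_end)),
            class = "cylinder_region")
}

#' @export
print.cylinder_region <- function(x, ...) {
  cat(sprintf(
    "<cylinder_region> r = %.2f A, L = %.2f A, k_wall = %.2f kcal/mol/A^2\n",
    x$radius, x$length, x$k_wall))
  cat(sprintf("  base (%.2f, %.2f, %.2f), axis (%.3f, %.3f, %.3f), %s\n",
              x$base_point[1], x$base_point[2], x$base_point[3],
              x$axis[1], x$axis[2], x$axis[3],
              if (x$closed_far_end) "closed far end" else "open far end"))
  invisible(x)
}

#' Anchor a confinement region over pocket residues
#'
#' Places the open face of the cylinder at the heavy-atom centroid of the
#' anchor residues (typically the three pocket-centre positions) and
#' points the axis outward, from the receptor centre of geometry through
#' that centroid. Default dimensions scale with the anchor spread:
#' radius = half the maximum pairwise anchor-centroid distance + 6 A,
#' length = 15 A.
#'
#' @param system a `prb_system`
#' @param residues data frame of residue keys (`chain`, `resid`), e.g.
#'   from [bw_residues()]
#' @param radius,length cylinder dimensions, Angstrom (`NULL` = derived)
#' @param k_wall wall force constant
#' @return a `cylinder_region`
#' @export
region_from_residues <- function(system, residues, radius = NULL,
                                 length = 15, k_wall = 10) {
  residues <- tibble::as_tibble(residues)
  if (nrow(residues) == 0) abort("need at least one anchor residue")
  if (!"chain" %in% names(residues)) residues$chain <- "A"
  cents <- purrr::map(seq_len(nrow(residues)), function(i) {
    idx <- residue_atoms(system, residues$chain[i], residues$resid[i],
                         heavy_only = TRUE)
    if (length(idx) == 0) {
      abort(sprintf("residue %s:%d has no heavy atoms",
                    residues$chain[i], residues$resid[i]))
    }
    colMeans(system_coords(system, idx))
  })
  cents <- do.call(rbind, cents)
  base_point <- colMeans(cents)
  center <- colMeans(system_coords(system, heavy_atoms(system,
                                                      receptor_only = TRUE)))
  axis <- base_point - center
  if (sqrt(sum(axis^2)) < 1e-6) {
    abort("degenerate geometry: anchor centroid coincides with receptor centre")
  }
  if (is.null(radius)) {
    maxd <- if (nrow(cents) > 1) max(stats::dist(cents)) else 0
    radius <- maxd / 2 + 6
  }
  cylinder_region(base_point, axis, radius, length, k_wall = k_wall)
}

#' Wall energy and force
#'
#' Flat-bottom half-harmonic wall: zero inside the cylinder, and
#' `E = k_wall/2 * (d_radial^2 + d_axial^2)` outside, where `d_radial`
#' is the excursion beyond the radius and `d_axial` the excursion beyond
#' the far end (closed cylinders only). No penalty applies through the
#' open face. The energy is C1: both E and its gradient vanish at the
#' wall.
#'
#' @param position 3-vector, or an n x 3 matrix of positions
#' @param region a `cylinder_region`
#' @return list with `energy` (kcal/mol, summed over rows) and `force`
#'   (same shape as `position`, kcal mol^-1 A^-1)
#' @export
wall_energy_force <- function(position, region) {
  p <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  v <- sweep(p, 2, region$base_point)
  a <- drop(v %*% region$axis)
  rad <- v - outer(a, region$axis)
  r <- sqrt(rowSums(rad^2))
  d_rad <- pmax(0, r - region$radius)
  d_ax <- if (region$closed_far_end) pmax(0, a - region$length) else 0 * a
  k <- region$k_wall
  energy <- 0.5 * k * sum(d_rad^2 + d_ax^2)
  # gradient: k*d_rad * radial unit + k*d_ax * axis; zero where inside
  rs <- ifelse(r > 0, r, 1)
  grad <- rad * (k * d_rad / rs) + outer(k * d_ax, region$axis)
  force <- -grad
  if (!is.matrix(position)) force <- drop(force)
  list(energy = energy, force = force)
}

#' Is a point inside the confinement region?
#'
#' True iff the wall energy is zero at the point and the point is on the
#' cylinder side of the open face (axial coordinate >= 0).
#'
#' @param region a `cylinder_region`
#' @param position 3-vector or n x 3 matrix
#' @return logical (one per row)
#' @export
region_contains <- function(region, position) {
  p <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  v <- sweep(p, 2, region$base_point)
  a <- drop(v %*% region$axis)
  rad <- v - outer(a, region$axis)
  r <- sqrt(rowSums(rad^2))
  inside <- r <= region$radius & a >= 0
  if (region$closed_far_end) inside <- inside & a <= region$length
  inside
}

#' Serialise / restore a region
#'
#' Writes the region as `key = value` text (`region_base`, `region_axis`,
#' `region_radius`, `region_length`, `region_k_wall`,
#' `region_closed_far_end`) so it can live in a run-config file.
#'
#' @param region a `cylinder_region`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_region <- function(region, path) {
  writeLines(c(
    sprintf("region_base = %.6f,%.6f,%.6f", region$base_point[1],
            region$base_point[2], region$base_point[3]),
    sprintf("region_axis = %.9f,%.9f,%.9f", region$axis[1], region$axis[2],
            region$axis[3]),
    sprintf("region_radius = %.6f", region$radius),
    sprintf("region_length = %.6f", region$length),
    sprintf("region_k_wall = %.6f", region$k_wall),
    sprintf("region_closed_far_end = %s",
            if (region$closed_far_end) "true" else "false")
  ), path)
  invisible(path)
}

#' @rdname write_region
#' @export
read_region <- function(path) {
  kv <- parse_kv_lines(readLines(path, warn = FALSE))
  need <- c("region_base", "region_axis", "region_radius", "region_length")
  missing <- setdiff(need, names(kv))
  if (length(missing) > 0) {
    abort(paste0("region file missing key(s): ",
                 paste(missing, collapse = ", ")))
  }
  num3 <- function(s) as.numeric(strsplit(s, ",")[[1]])
  cylinder_region(
    base_point = num3(kv[["region_base"]]),
    axis = num3(kv[["region_axis"]]),
    radius = as.numeric(kv[["region_radius"]]),
    length = as.numeric(kv[["region_length"]]),
    k_wall = as.numeric(kv[["region_k_wall"]] %||% "10"),
    closed_far_end = !identical(kv[["region_closed_far_end"]], "false")
  )
}

# shared key = value parser (comments with #)
parse_kv_lines <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0) return(list())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  setNames(as.list(trimws(vapply(kv, `[`, "", 2))),
           trimws(vapply(kv, `[`, "", 1)))
}
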