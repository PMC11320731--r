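#' Frame-averaged probe density grid
#'
#' Voxelises the selected atoms on an axis-aligned grid (default 1 A
#' cell side). In each frame a voxel counts as occupied when its centre
#' lies within the van der Waals radius of any selected atom; the grid
#' value is the fraction of frames in which the voxel was occupied, so
#' all values lie in `[0, 1]`. The grid spans the selection's bounding
#' box over all frames plus a 2 A pad.
#'
#' @param traj a `prb_trajectory`
#' @param sel atom rows to rasterise (default: all probe atoms)
#' @param spacing cell side, Angstrom (default 1)
#' @param pad bounding-box padding, Angstrom
#' @return a `density_grid`: `origin` (centre of the first voxel),
#'   `spacing`, `dim`, and a 3D `values` array
#' @export
density_grid <- function(traj, sel = NULL, spacing = 1, pad = 2) {
  if (spacing <= 0) abort("spacing must be > 0")
  sys <- traj$system
  if (is.null(sel)) sel <- probe_atoms(sys)
  if (length(sel) == 0) abort("zero-extent selection")
  radii <- vdw_radius(sys$atoms$element[sel])
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (f in traj$frames) {
    s <- f[sel, , drop = FALSE]
    lo <- pmin(lo, apply(s, 2, min))
    hi <- pmax(hi, apply(s, 2, max))
  }
  lo <- lo - pad; hi <- hi + pad
  dim3 <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  origin <- lo + spacing / 2      # centre of voxel (1,1,1)
  counts <- array(0L, dim3)
  centers <- lapply(1:3, function(d) origin[d] + (seq_len(dim3[d]) - 1) * spacing)
  for (f in traj$frames) {
    occ <- array(FALSE, dim3)
    s <- f[sel, , drop = FALSE]
    for (ia in seq_len(nrow(s))) {
      r <- radii[ia]
      p <- s[ia, ]
      rng <- lapply(1:3, function(d) {
        which(abs(centers[[d]] - p[d]) <= r)
      })
      if (any(lengths(rng) == 0)) next
      dx2 <- (centers[[1]][rng[[1]]] - p[1])^2
      dy2 <- (centers[[2]][rng[[2]]] - p[2])^2
      dz2 <- (centers[[3]][rng[[3]]] - p[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      sub <- occ[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      occ[rng[[1]], rng[[2]], rng[[3]]] <- sub | inside
    }
    counts <- counts + occ
  }
  structure(list(origin = origin, spacing = spacing, dim = dim3,
                 values = counts / length(traj$frames)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels, %.2f A spacing\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing))
  cat(sprintf("  origin (%.2f, %.2f, %.2f), max value %.3f\n",
              x$origin[1], x$origin[2], x$origin[3], max(x$values)))
  invisible(x)
}

#' Threshold a density grid at an isovalue
#'
#' Retains voxels whose value is at least `isovalue` and strictly
#' positive (so an isovalue of 0 selects only voxels that were ever
#' occupied). The default 0.5 keeps regions occupied in at least half
#' the frames.
#'
#' @param grid a [density_grid()]
#' @param isovalue threshold in `[0, 1]` (default 0.5)
#' @return tibble of suprathreshold voxels (`ix`, `iy`, `iz`, `value`,
#'   and Cartesian centres `x`, `y`, `z`), with attributes `n_voxels`
#'   and `centroid`
#' @export
threshold_density <- function(grid, isovalue = 0.5) {
  keep <- which(grid$values >= isovalue & grid$values > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    ix = as.integer(keep[, 1]), iy = as.integer(keep[, 2]),
    iz = as.integer(keep[, 3]),
    value = grid$values[keep],
    x = grid$origin[1] + (as.integer(keep[, 1]) - 1) * grid$spacing,
    y = grid$origin[2] + (as.integer(keep[, 2]) - 1) * grid$spacing,
    z = grid$origin[3] + (as.integer(keep[, 3]) - 1) * grid$spacing
  )
  attr(out, "n_voxels") <- nrow(out)
  attr(out, "centroid") <- if (nrow(out) > 0) {
    c(mean(out$x), mean(out$y), mean(out$z))
  } else {
    c(NA_real_, NA_real_, NA_real_)
  }
  out
}

#' Write a density grid as an OpenDX scalar field
#'
#' Standard `gridpositions`/`gridconnections`/`array` layout with the
#' last (z) index varying fastest, three values per line, readable by
#' VMD, PyMOL and Chimera.
#'
#' @param grid a [density_grid()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  v <- aperm(grid$values, c(3, 2, 1))  # z fastest
  v <- as.vector(v)
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(v) > n3) {
    writeLines(paste(sprintf("%.6f", v[(n3 + 1):length(v)]), collapse = " "),
               con)
  }
  writeLines(c(
    'attribute "dep" string "positions"',
    'object "density" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  ), con)
  invisible(path)
}

#' Export suprathreshold voxels as PDB pseudo-atoms
#'
#' @param voxels output of [threshold_density()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_density_pdb <- function(voxels, path) {
  lines <- sprintf(
    "HETATM%5d  DX  DEN X%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(voxels)) %% 100000L, 1L, voxels$x, voxels$y, voxels$z,
    1.0, voxels$value)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
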