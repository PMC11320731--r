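#' Grid-based pocket volume
#'
#' Estimates the solvent-accessible cavity volume inside a confinement
#' region. On a cubic grid restricted to the region, a voxel counts as
#' pocket when a solvent probe centred there (1) clears every receptor
#' atom (centre at least vdW + probe radius from each atom centre) and
#' (2) stays within probe reach of the receptor surface - no further
#' than two probe radii from the nearest atom's vdW surface - so open
#' solvent beyond the pocket mouth is not counted. Volume is voxel
#' count times `spacing^3`, averaged over frames.
#'
#' @param traj a `prb_trajectory` or a `prb_system` (single frame)
#' @param region a [cylinder_region()]
#' @param spacing grid spacing, Angstrom (default 1)
#' @param probe_radius solvent probe radius, Angstrom (default 1.4)
#' @return a `pocket_volume` result: `mean`, `sd` and per-frame volumes
#'   (Angstrom^3)
#' @export
pocket_volume <- function(traj, region, spacing = 1, probe_radius = 1.4) {
  if (spacing <= 0) abort("spacing must be > 0")
  if (inherits(traj, "prb_system")) {
    traj <- trajectory(traj, list(system_coords(traj)), dt = 1)
  }
  sys <- traj$system
  ridx <- heavy_atoms(sys, receptor_only = TRUE)
  radii <- vdw_radius(sys$atoms$element[ridx])
  # grid covering the cylinder's bounding box
  ax <- region$axis
  ends <- rbind(region$base_point, region$base_point + region$length * ax)
  lo <- apply(ends, 2, min) - region$radius
  hi <- apply(ends, 2, max) + region$radius
  n3 <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  centers <- as.matrix(expand.grid(
    lo[1] + (seq_len(n3[1]) - 0.5) * spacing,
    lo[2] + (seq_len(n3[2]) - 0.5) * spacing,
    lo[3] + (seq_len(n3[3]) - 0.5) * spacing
  ))
  centers <- centers[region_contains(region, centers), , drop = FALSE]
  vols <- vapply(seq_len(n_frames(traj)), function(i) {
    rc <- traj$frames[[i]][ridx, , drop = FALSE]
    if (nrow(rc) == 0 || nrow(centers) == 0) return(0)
    # surface distance to the nearest receptor atom for every voxel
    m1 <- rep(Inf, nrow(centers))
    for (j in seq_len(nrow(rc))) {
      d <- sqrt((centers[, 1] - rc[j, 1])^2 + (centers[, 2] - rc[j, 2])^2 +
                  (centers[, 3] - rc[j, 3])^2) - radii[j]
      m1 <- pmin(m1, d)
    }
    # reach measured from the nearest atom's vdW surface; the largest
    # tabulated vdW radius bounds "max vdW of the nearest atom"
    reach <- 2 * probe_radius + max(VDW_RADII)
    ok <- m1 >= probe_radius & m1 <= reach
    sum(ok) * spacing^3
  }, numeric(1))
  structure(list(mean = mean(vols),
                 sd = if (length(vols) > 1) sd(vols) else 0,
                 per_frame = vols, spacing = spacing,
                 probe_radius = probe_radius),
            class = "pocket_volume")
}

#' @export
print.pocket_volume <- function(x, ...) {
  cat(sprintf("<pocket_volume> %.1f +/- %.1f A^3 over %d frame(s)\n",
              x$mean, x$sd, length(x$per_frame)))
  invisible(x)
}

#' @export
tidy.pocket_volume <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$per_frame), volume = x$per_frame)
}
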