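#' Pocket occupancy
#'
#' The headline mapping statistic: the percentage of trajectory frames
#' in which at least one probe heavy atom lies within `cutoff` of any
#' heavy atom of any pocket-centre residue. The centre defaults to the
#' three generic positions 2.43, 7.56 and 8.48 that define the
#' intracellular pocket, resolved through a [bw_map()]; explicit residue
#' keys can be given instead.
#'
#' @param traj a `prb_trajectory`
#' @param map a [bw_map()] used to resolve `center` labels
#' @param center generic residue labels of the pocket centre
#' @param residues optional data frame of residue keys (`chain`,
#'   `resid`), overriding `center`/`map`
#' @param probe_sel atom rows treated as probe atoms (default: all probe
#'   heavy atoms)
#' @param cutoff Angstrom (default 4)
#' @return an `occupancy_result`: `percent`, per-frame logical `flags`,
#'   and the resolved centre residues
#' @export
pocket_occupancy <- function(traj, map = NULL,
                             center = c("2.43", "7.56", "8.48"),
                             residues = NULL, probe_sel = NULL,
                             cutoff = 4) {
  sys <- traj$system
  if (is.null(residues)) {
    if (is.null(map)) abort("supply either a bw_map or explicit residues")
    residues <- bw_residues(map, center)
    if (nrow(residues) == 0) {
      abort("none of the centre labels are in the annotation")
    }
  }
  residues <- tibble::as_tibble(residues)
  if (!"chain" %in% names(residues)) residues$chain <- "A"
  center_idx <- unlist(purrr::map(seq_len(nrow(residues)), function(i) {
    residue_atoms(sys, residues$chain[i], residues$resid[i],
                  heavy_only = TRUE)
  }))
  if (is.null(probe_sel)) {
    probe_sel <- intersect(probe_atoms(sys), heavy_atoms(sys))
  }
  if (length(probe_sel) == 0) abort("empty probe selection")
  flags <- vapply(seq_len(n_frames(traj)), function(i) {
    f <- traj$frames[[i]]
    min_dist_cpp(f[probe_sel, , drop = FALSE],
                 f[center_idx, , drop = FALSE]) <= cutoff
  }, logical(1))
  structure(list(percent = 100 * mean(flags), flags = flags,
                 cutoff = cutoff, center_residues = residues),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "<occupancy_result> %.1f%% of %d frames occupied (cutoff %.1f A)\n",
    x$percent, length(x$flags), x$cutoff))
  invisible(x)
}

#' @export
tidy.occupancy_result <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$flags), occupied = x$flags)
}

#' @export
glance.occupancy_result <- function(x, ...) {
  tibble::tibble(percent = x$percent, n_frames = length(x$flags),
                 cutoff = x$cutoff)
}

#' Contact frequency between two atom groups
#'
#' Fraction of frames in which the minimum heavy-atom distance between
#' the two groups is at most `d_cut`. Used e.g. for the conserved
#' 3.50-3.49 ionic-lock salt bridge.
#'
#' @param traj a `prb_trajectory`
#' @param group_a,group_b atom rows
#' @param d_cut Angstrom (default 4)
#' @return fraction in `[0, 1]`
#' @export
contact_frequency <- function(traj, group_a, group_b, d_cut = 4) {
  el <- traj$system$atoms$element
  group_a <- group_a[el[group_a] != "H"]
  group_b <- group_b[el[group_b] != "H"]
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("contact groups must contain at least one heavy atom")
  }
  hits <- vapply(traj$frames, function(f) {
    min_dist_cpp(f[group_a, , drop = FALSE],
                 f[group_b, , drop = FALSE]) <= d_cut
  }, logical(1))
  mean(hits)
}
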