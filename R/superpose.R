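# Kabsch least-squares superposition: rotation (det = +1) and translation
# aligning P onto Q (both n x 3)
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

apply_kabsch <- function(P, fit) {
  sweep(sweep(P, 2, fit$cp) %*% t(fit$R), 2, fit$cq, `+`)
}

#' Per-frame RMSD against a reference
#'
#' Root-mean-square deviation of the selected atoms from a reference
#' frame, optionally after Kabsch least-squares superposition (proper
#' rotations only).
#'
#' @param traj a `prb_trajectory`
#' @param reference frame index, or an n_sel x 3 coordinate matrix
#' @param sel atom rows (default: receptor heavy atoms)
#' @param superpose fit each frame onto the reference first (default)
#' @return tibble with `frame`, `time`, `rmsd` (Angstrom)
#' @export
rmsd_series <- function(traj, reference = 1, sel = NULL, superpose = TRUE) {
  sys <- traj$system
  if (is.null(sel)) sel <- heavy_atoms(sys, receptor_only = TRUE)
  if (length(sel) == 0) abort("empty selection")
  ref <- if (is.matrix(reference)) {
    reference
  } else {
    frame_coords(traj, reference, sel)
  }
  if (nrow(ref) != length(sel)) {
    abort("reference atom count does not match the selection")
  }
  rmsd <- vapply(seq_len(n_frames(traj)), function(i) {
    P <- frame_coords(traj, i, sel)
    if (superpose) P <- apply_kabsch(P, kabsch(P, ref))
    sqrt(mean(rowSums((P - ref)^2)))
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(traj)),
                 time = (seq_len(n_frames(traj)) - 1) * traj$dt,
                 rmsd = rmsd)
}

#' Root-mean-square fluctuation
#'
#' Per-atom spread about the mean structure,
#' `RMSF_i = sqrt(<|x_i - <x_i>|^2>)`, optionally after aligning every
#' frame to the mean structure (Kabsch on the selection's heavy atoms;
#' the mean is obtained by aligning to the first frame, averaging, and
#' re-aligning). Per-residue values average the heavy atoms of each
#' residue.
#'
#' @param traj a `prb_trajectory` (at least two frames)
#' @param sel atom rows (default: receptor heavy atoms)
#' @param align `"mean"` (superpose onto the mean structure) or
#'   `"none"`
#' @param per `"residue"` (default) or `"atom"`
#' @return tibble: per residue (`chain`, `resid`, `rmsf`) or per atom
#'   (`serial`, `rmsf`), Angstrom
#' @export
rmsf <- function(traj, sel = NULL, align = c("mean", "none"),
                 per = c("residue", "atom")) {
  align <- match.arg(align)
  per <- match.arg(per)
  sys <- traj$system
  if (is.null(sel)) sel <- heavy_atoms(sys, receptor_only = TRUE)
  if (length(sel) == 0) abort("empty selection")
  if (n_frames(traj) < 2) abort("RMSF needs at least two frames")
  coords <- lapply(seq_len(n_frames(traj)), function(i) {
    frame_coords(traj, i, sel)
  })
  if (align == "mean") {
    ref <- coords[[1]]
    aligned <- lapply(coords, function(P) apply_kabsch(P, kabsch(P, ref)))
    m <- Reduce(`+`, aligned) / length(aligned)
    coords <- lapply(coords, function(P) apply_kabsch(P, kabsch(P, m)))
  }
  m <- Reduce(`+`, coords) / length(coords)
  msf <- Reduce(`+`, lapply(coords, function(P) rowSums((P - m)^2))) /
    length(coords)
  atom_rmsf <- sqrt(msf)
  if (per == "atom") {
    return(tibble::tibble(serial = sys$atoms$serial[sel], rmsf = atom_rmsf))
  }
  tab <- tibble::tibble(chain = sys$atoms$chain[sel],
                        resid = sys$atoms$resid[sel], rmsf = atom_rmsf)
  dplyr::summarise(dplyr::group_by(tab, .data$chain, .data$resid),
                   rmsf = mean(.data$rmsf), .groups = "drop")
}
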