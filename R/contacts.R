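#' Hydrogen bonds over a trajectory
#'
#' A donor-acceptor pair is hydrogen bonded in a frame when the
#' donor-acceptor heavy-atom distance is at most `d_cut` (default
#' 3.5 A) and the D-H...A angle at the hydrogen is at least `angle_cut`
#' (default 90 degrees; 180 is linear). The angle convention is the
#' minimum-angle reading of the usual VMD-style cutoff: geometries with
#' angles below 90 degrees are rejected. Donors must be supplied with
#' their attached hydrogens, since the package carries no bond topology.
#'
#' @param traj a `prb_trajectory`
#' @param donors data frame with atom-row columns `donor` and
#'   `hydrogen` (one row per D-H pair)
#' @param acceptors atom rows of acceptor heavy atoms
#' @param d_cut donor-acceptor distance cutoff, Angstrom
#' @param angle_cut minimum D-H...A angle, degrees
#' @return tibble with `donor`, `hydrogen`, `acceptor` and the fraction
#'   of frames bonded
#' @export
hydrogen_bonds <- function(traj, donors, acceptors, d_cut = 3.5,
                           angle_cut = 90) {
  donors <- tibble::as_tibble(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors))) {
    abort("donors must have columns `donor` and `hydrogen`")
  }
  if (any(is.na(donors$hydrogen))) {
    abort(paste0("donor(s) without an attached hydrogen: atom row ",
                 paste(donors$donor[is.na(donors$hydrogen)], collapse = ", ")))
  }
  el <- traj$system$atoms$element
  if (any(el[donors$hydrogen] != "H")) {
    abort("`hydrogen` rows must be hydrogen atoms")
  }
  if (length(acceptors) == 0) abort("empty acceptor selection")
  pairs <- tidyr::crossing(donors, acceptor = as.integer(acceptors))
  pairs <- dplyr::filter(pairs, .data$acceptor != .data$donor)
  nf <- n_frames(traj)
  count <- numeric(nrow(pairs))
  for (i in seq_len(nf)) {
    f <- traj$frames[[i]]
    d <- f[pairs$donor, , drop = FALSE]
    h <- f[pairs$hydrogen, , drop = FALSE]
    a <- f[pairs$acceptor, , drop = FALSE]
    da <- sqrt(rowSums((d - a)^2))
    hd <- d - h
    ha <- a - h
    cosang <- rowSums(hd * ha) /
      (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    count <- count + as.numeric(da <= d_cut & ang >= angle_cut)
  }
  pairs$fraction <- count / nf
  pairs
}
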