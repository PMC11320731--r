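# Independent oracles and tiny fixture builders shared across tests.
# Everything here is deliberately naive (double loops, closed forms) so
# it cannot share a code path with the implementation it checks.

# brute-force Coulomb + LJ double loop; hard cutoff, no switching
brute_pair_energy <- function(a, b, cutoff = Inf, dielectric = 1) {
  kc <- 332.0637
  elec <- 0
  vdw <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (r > cutoff) next
      elec <- elec + kc * a$charge[i] * b$charge[j] / (dielectric * r)
      eps <- sqrt(a$epsilon[i] * b$epsilon[j])
      rmin <- a$rmin_half[i] + b$rmin_half[j]
      vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  c(elec = elec, vdw = vdw)
}

# random parameterised atom table
random_atoms <- function(n, seed, spread = 10, charged = TRUE) {
  set.seed(seed)
  tibble::tibble(
    serial = seq_len(n), name = "X", element = sample(c("C", "N", "O"), n,
                                                      replace = TRUE),
    resname = "RND", resid = seq_len(n), chain = "A",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread),
    charge = if (charged) runif(n, -0.5, 0.5) else 0,
    epsilon = runif(n, 0.02, 0.3), rmin_half = runif(n, 1.5, 2.2),
    mass = 12, is_probe = FALSE, hydrophobic = FALSE
  )
}

# a single-atom "residue" at a position
point_atom <- function(x, y, z, resid = 1L, chain = "A", element = "C",
                       charge = 0, epsilon = 0.1, rmin_half = 2,
                       name = "CA", resname = "PNT", is_probe = FALSE) {
  tibble::tibble(serial = resid, name = name, element = element,
                 resname = resname, resid = resid, chain = chain,
                 x = x, y = y, z = z, charge = charge, epsilon = epsilon,
                 rmin_half = rmin_half, mass = 12, is_probe = is_probe,
                 hydrophobic = element %in% c("C", "S"))
}

# uniform random rotation matrix (QR of Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigidly transform every frame of a trajectory
transform_trajectory <- function(traj, R, shift) {
  traj$frames <- lapply(traj$frames, function(f) {
    sweep(f %*% t(R), 2, shift, `+`)
  })
  traj
}

# minimal CHARMM-style DCD writer (native endianness, float32 frames);
# used only to cross-check the DCD reader against the XYZ reader
write_dcd_fixture <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nframes <- length(frames)
  natom <- nrow(frames[[1]])
  icntrl <- integer(20)
  icntrl[1] <- nframes
  icntrl[2] <- 1L
  icntrl[3] <- 1L
  icntrl[4] <- nframes
  icntrl[20] <- 24L
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "dcd cross-format fixture"), con, nchars = 80,
            eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natom), con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in frames) {
    for (d in 1:3) {
      writeBin(as.integer(4 * natom), con, size = 4)
      writeBin(as.numeric(f[, d]), con, size = 4)
      writeBin(as.integer(4 * natom), con, size = 4)
    }
  }
  invisible(path)
}

# analytic SASA of two intersecting equal spheres of expanded radius R
# at centre distance d: each sphere loses a cap of height R - d/2
two_sphere_sasa <- function(R, d) {
  2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
}
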