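# a tiny receptor + single-bead probe system where frame geometry is
# fully hand-controlled: receptor residues 1..3 along x, probe atom last
controlled_system <- function() {
  recv <- dplyr::bind_rows(
    point_atom(0, 0, 0, resid = 1, charge = -0.3),
    point_atom(6, 0, 0, resid = 2, charge = 0.2),
    point_atom(12, 0, 0, resid = 3, charge = 0.1)
  )
  probe <- point_atom(0, 0, 30, resid = 1, chain = "P", charge = 0.25,
                      resname = "PRB", is_probe = TRUE)
  new_system(dplyr::bind_rows(recv, probe), probes = list(4L))
}

probe_frames <- function(sys, zs) {
  base <- unname(system_coords(sys))
  lapply(zs, function(z) {
    f <- base
    f[4, ] <- c(0, 0, z)
    f
  })
}

test_that("pocket occupancy counts frames with a probe inside the shell", {
  sys <- controlled_system()
  # frames 1, 2, 4 inside the 4 A shell around residue 1; 3, 5 outside
  traj <- trajectory(sys, probe_frames(sys, c(3, 3.9, 10, 2, 30)), dt = 1)
  occ <- pocket_occupancy(traj, residues = data.frame(chain = "A", resid = 1),
                          cutoff = 4)
  expect_equal(occ$percent, 60)
  expect_equal(occ$flags, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  far <- trajectory(sys, probe_frames(sys, rep(30, 4)), dt = 1)
  expect_equal(pocket_occupancy(far,
                                residues = data.frame(chain = "A", resid = 1),
                                cutoff = 4)$percent, 0)
})

test_that("occupancy equals an independent all-pairs distance scan", {
  run <- planted_hotspot_trajectory(n_frames = 200, seed = 8,
                                    mode = "synthesize", f = 0.35)
  traj <- run$trajectory
  occ <- pocket_occupancy(traj, map = run$bw)
  centers <- bw_residues(run$bw, c("2.43", "7.56", "8.48"))
  a <- atoms(traj$system)
  cidx <- which(paste(a$chain, a$resid) %in%
                  paste(centers$chain, centers$resid) & !a$is_probe &
                  a$element != "H")
  pidx <- which(a$is_probe & a$element != "H")
  ref <- vapply(traj$frames, function(f) {
    any(as.matrix(stats::dist(rbind(f[pidx, , drop = FALSE],
                                    f[cidx, , drop = FALSE])))[
      seq_along(pidx), length(pidx) + seq_along(cidx)] <= 4)
  }, logical(1))
  expect_equal(occ$flags, unname(ref))
  expect_equal(occ$percent, 100 * mean(ref))
})

test_that("occupancy and contacts are invariant under rigid motion", {
  run <- planted_hotspot_trajectory(n_frames = 40, seed = 4,
                                    mode = "synthesize", f = 0.5)
  traj <- run$trajectory
  set.seed(77)
  moved <- transform_trajectory(traj, random_rotation(), c(13, -8, 5))
  res <- data.frame(chain = "A",
                    resid = bw_residues(run$bw, "8.49")$resid)
  o1 <- pocket_occupancy(traj, map = run$bw)
  o2 <- pocket_occupancy(moved, map = run$bw)
  expect_equal(o1$flags, o2$flags)
  ga <- residue_atoms(traj$system, "A", res$resid)
  gb <- probe_atoms(traj$system)
  expect_equal(contact_frequency(traj, ga, gb),
               contact_frequency(moved, ga, gb))
})

test_that("density grid follows the voxel-centre-in-sphere definition", {
  sys <- new_system(point_atom(0.2, -0.1, 0.3, element = "S",
                               is_probe = TRUE), probes = list(1L))
  traj <- trajectory(sys, list(unname(system_coords(sys))), dt = 1)
  g <- density_grid(traj, spacing = 1)
  expect_true(all(g$values %in% c(0, 1)))
  # every voxel centre within the S vdW radius (1.8 A) is 1, others 0
  ctr <- c(0.2, -0.1, 0.3)
  for (ix in seq_len(g$dim[1])) {
    for (iy in seq_len(g$dim[2])) {
      for (iz in seq_len(g$dim[3])) {
        vc <- g$origin + (c(ix, iy, iz) - 1) * g$spacing
        expect_equal(g$values[ix, iy, iz],
                     as.numeric(sqrt(sum((vc - ctr)^2)) <= 1.8))
      }
    }
  }
})

test_that("density values are per-voxel occupied-frame fractions", {
  sys <- new_system(point_atom(0, 0, 0, element = "C", is_probe = TRUE),
                    probes = list(1L))
  f1 <- matrix(c(0, 0, 0), 1)
  f2 <- matrix(c(8, 0, 0), 1)
  g <- density_grid(trajectory(sys, list(f1, f2), dt = 1), spacing = 1)
  expect_true(all(g$values %in% c(0, 0.5)))
  # voxel at the first-frame position was occupied in 1 of 2 frames
  idx0 <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
  expect_equal(g$values[idx0[1], idx0[2], idx0[3]], 0.5)
})

test_that("density grid matches brute-force rasterisation on random frames", {
  set.seed(55)
  sys <- new_system(
    dplyr::bind_rows(point_atom(0, 0, 0, 1, element = "C", is_probe = TRUE),
                     point_atom(1, 1, 1, 2, element = "O", chain = "B",
                                is_probe = TRUE)),
    probes = list(1L, 2L))
  frames <- lapply(1:50, function(i) matrix(runif(6, -3, 3), 2, 3))
  traj <- trajectory(sys, frames, dt = 1)
  g <- density_grid(traj, spacing = 1)
  radii <- c(1.7, 1.52)
  ref <- array(0, g$dim)
  for (f in frames) {
    occ <- array(FALSE, g$dim)
    for (ix in seq_len(g$dim[1])) for (iy in seq_len(g$dim[2])) {
      for (iz in seq_len(g$dim[3])) {
        vc <- g$origin + (c(ix, iy, iz) - 1) * g$spacing
        for (ia in 1:2) {
          if (sqrt(sum((vc - f[ia, ])^2)) <= radii[ia]) {
            occ[ix, iy, iz] <- TRUE
          }
        }
      }
    }
    ref <- ref + occ
  }
  expect_equal(g$values, ref / 50, tolerance = 1e-12)
  expect_true(all(g$values >= 0 & g$values <= 1))
})

test_that("refining the grid never uncovers fewer atoms at threshold", {
  set.seed(66)
  sys <- new_system(
    dplyr::bind_rows(lapply(1:5, function(i) {
      point_atom(runif(1, -2, 2), runif(1, -2, 2), runif(1, -2, 2),
                 resid = i, element = "C", is_probe = TRUE)
    })), probes = as.list(1:5))
  traj <- trajectory(sys, list(unname(system_coords(sys))), dt = 1)
  covered <- function(spacing) {
    vox <- threshold_density(density_grid(traj, spacing = spacing), 0.5)
    xyz <- system_coords(sys)
    sum(vapply(1:5, function(i) {
      any(sqrt((vox$x - xyz[i, 1])^2 + (vox$y - xyz[i, 2])^2 +
                 (vox$z - xyz[i, 3])^2) <= 1.7)
    }, logical(1)))
  }
  expect_gte(covered(0.5), covered(1.0))
})

test_that("threshold semantics keep >= isovalue and strictly positive", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dim = c(3L, 3L, 3L),
                      values = array(0, c(3, 3, 3))),
                 class = "density_grid")
  expect_equal(nrow(threshold_density(g, 0.5)), 0)
  g$values[2, 3, 1] <- 0.6
  hit <- threshold_density(g, 0.5)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$ix, hit$iy, hit$iz), c(2, 3, 1))
  expect_equal(attr(hit, "n_voxels"), 1)
  # isovalue 0 still excludes never-occupied voxels
  g$values[1, 1, 1] <- 0.2
  expect_equal(nrow(threshold_density(g, 0)), 2)
})

test_that("DX export round-trips through an independent reader", {
  run <- planted_hotspot_trajectory(n_frames = 10, seed = 2,
                                    mode = "synthesize", f = 0.5)
  g <- density_grid(run$trajectory, spacing = 2)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  lines <- readLines(f)
  expect_match(lines[1], sprintf("counts %d %d %d", g$dim[1], g$dim[2],
                                 g$dim[3]))
  vals <- scan(text = paste(lines[8:(length(lines) - 5)], collapse = " "),
               quiet = TRUE)
  expect_equal(length(vals), prod(g$dim))
  expect_equal(max(vals), max(g$values), tolerance = 1e-6)
  # z varies fastest in the data block
  expect_equal(vals[seq_len(g$dim[3])], g$values[1, 1, ], tolerance = 1e-6)
})

test_that("per-residue energies reduce to pair_energy on fixed geometry", {
  sys <- controlled_system()
  traj <- trajectory(sys, probe_frames(sys, rep(2.5, 3)), dt = 1)
  model <- nonbonded_model(cutoff = Inf)
  tab <- residue_interaction_energies(traj, probe = "all", cutoff = 5,
                                      model = model)
  expect_equal(nrow(tab), 1)  # only residue 1 is inside the 5 A shell
  ref <- pair_energy(atoms(sys)[1, ], atoms(sys)[4, ] |>
                       dplyr::mutate(z = 2.5), model)
  expect_equal(tab$elec_mean, ref$elec, tolerance = 1e-12)
  expect_equal(tab$vdw_mean, ref$vdw, tolerance = 1e-12)
  expect_equal(tab$elec_sd, 0)
  expect_equal(tab$n_frames, 3L)
  # probe beyond the shell of every residue: empty table
  far <- trajectory(sys, probe_frames(sys, rep(40, 3)), dt = 1)
  expect_equal(nrow(residue_interaction_energies(far, model = model)), 0)
})

test_that("per-residue energies match brute-force recomputation", {
  set.seed(91)
  recv <- random_atoms(20, seed = 91, spread = 8)
  probe <- point_atom(0, 0, 4, resid = 1, chain = "P", charge = 0.3,
                      resname = "PRB", is_probe = TRUE)
  sys <- new_system(dplyr::bind_rows(recv, probe), probes = list(21L))
  base <- unname(system_coords(sys))
  frames <- lapply(1:15, function(i) {
    f <- base
    f[21, ] <- runif(3, -6, 6)
    f
  })
  traj <- trajectory(sys, frames, dt = 1)
  model <- nonbonded_model(cutoff = Inf)
  tab <- residue_interaction_energies(traj, cutoff = 5, model = model)
  a <- atoms(sys)
  for (r in seq_len(20)) {
    evals <- c()
    vvals <- c()
    for (k in seq_along(frames)) {
      f <- frames[[k]]
      d <- sqrt(sum((f[r, ] - f[21, ])^2))
      if (d <= 5) {
        ar <- a[r, ]; ap <- a[21, ]
        ar$x <- f[r, 1]; ar$y <- f[r, 2]; ar$z <- f[r, 3]
        ap$x <- f[21, 1]; ap$y <- f[21, 2]; ap$z <- f[21, 3]
        e <- brute_pair_energy(ar, ap)
        evals <- c(evals, e[["elec"]])
        vvals <- c(vvals, e[["vdw"]])
      }
    }
    row <- tab[tab$resid == r, ]
    if (length(evals) == 0) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$elec_mean, mean(evals), tolerance = 1e-9)
      expect_equal(row$vdw_mean, mean(vvals), tolerance = 1e-9)
      expect_equal(row$n_frames, length(evals))
    }
  }
})

test_that("residue decomposition is exactly additive at infinite cutoff", {
  run <- planted_hotspot_trajectory(n_frames = 25, seed = 12,
                                    mode = "synthesize", f = 0.6)
  traj <- run$trajectory
  model <- nonbonded_model(cutoff = Inf)
  tab <- residue_interaction_energies(traj, cutoff = Inf, model = model,
                                      average = "all")
  a <- atoms(traj$system)
  pidx <- probe_atoms(traj$system)
  ridx <- which(!a$is_probe)
  totals <- vapply(traj$frames, function(f) {
    ar <- a[ridx, ]; ap <- a[pidx, ]
    ar$x <- f[ridx, 1]; ar$y <- f[ridx, 2]; ar$z <- f[ridx, 3]
    ap$x <- f[pidx, 1]; ap$y <- f[pidx, 2]; ap$z <- f[pidx, 3]
    sum(pair_energy(ar, ap, model))
  }, numeric(1))
  # all residues contribute every frame under average = "all", so the
  # mean total equals the per-frame mean of the whole-receptor energy
  expect_equal(sum(tab$elec_mean + tab$vdw_mean), mean(totals),
               tolerance = 1e-9)
})

test_that("hotspot ranking orders by energy with residue-id tie-breaks", {
  tab <- tibble::tibble(
    chain = "A", resid = c(1L, 2L, 3L), resname = "AAA", bw = NA_character_,
    elec_mean = c(-5, -7.5, 0.3), elec_sd = 0,
    vdw_mean = c(0, 0, 0), vdw_sd = 0,
    total_mean = c(-5, -7.5, 0.3), n_frames = 10L, n_total = 10L
  )
  class(tab) <- c("hotspot_table", class(tibble::tibble()))
  expect_equal(rank_hotspots(tab, "elec")$resid, c(2L, 1L, 3L))
  expect_error(rank_hotspots(tab, "nonsense"))
  ties <- tab
  ties$total_mean <- c(-1, -1, -1)
  expect_equal(rank_hotspots(ties, "total")$resid, c(1L, 2L, 3L))
  expect_error(rank_hotspots(tab[0, ], "total"), "empty")
})

test_that("hydrogen bond detection applies both distance and angle rules", {
  # construct directly: D at origin, H on x; acceptor in the xz plane at
  # D-H...A angle theta and D...A distance d
  build <- function(d_da, angle_deg) {
    h <- c(1.0, 0, 0)
    th <- angle_deg * pi / 180
    # unit vector from H making angle th with (D - H) = (-1, 0, 0)
    u <- c(-cos(th), 0, sin(th))
    # find t with |D - (H + t u)| = d_da  (A = H + t u)
    # |H + t u|^2 = 1 + 2 t (h . u) + t^2 = d_da^2
    b <- 2 * sum(h * u)
    t_pos <- (-b + sqrt(b^2 - 4 * (1 - d_da^2))) / 2
    a_pos <- h + t_pos * u
    sys <- new_system(dplyr::bind_rows(
      point_atom(0, 0, 0, 1, element = "O", name = "OD"),
      point_atom(h[1], h[2], h[3], 1, element = "H", name = "HD"),
      point_atom(a_pos[1], a_pos[2], a_pos[3], 2, element = "O",
                 name = "OA")
    ))
    trajectory(sys, list(unname(system_coords(sys))), dt = 1)
  }
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  hb <- hydrogen_bonds(build(2.8, 180), donors, acceptors = 3L)
  expect_equal(hb$fraction, 1.0)
  expect_equal(hydrogen_bonds(build(3.6, 180), donors, 3L)$fraction, 0)
  expect_equal(hydrogen_bonds(build(2.8, 85), donors, 3L)$fraction, 0)
  expect_equal(hydrogen_bonds(build(2.8, 95), donors, 3L)$fraction, 1.0)
  expect_error(hydrogen_bonds(build(2.8, 180),
                              data.frame(donor = 1L, hydrogen = NA),
                              3L), "without an attached hydrogen")
})

test_that("contact frequency counts frames under the distance cutoff", {
  sys <- controlled_system()
  near <- trajectory(sys, probe_frames(sys, rep(3, 5)), dt = 1)
  expect_equal(contact_frequency(near, 1L, 4L, d_cut = 4), 1.0)
  far <- trajectory(sys, probe_frames(sys, rep(8, 5)), dt = 1)
  expect_equal(contact_frequency(far, 1L, 4L, d_cut = 4), 0.0)
  mixed <- trajectory(sys, probe_frames(sys, c(3, 3, 8, 8, 3, 8, 8, 3, 8, 8)),
                      dt = 1)
  expect_equal(contact_frequency(mixed, 1L, 4L, d_cut = 4), 0.4)
  expect_error(contact_frequency(mixed, integer(0), 4L), "heavy atom")
})

test_that("RMSD is zero on identity and rigid rotation, exact on shifts", {
  sys <- new_system(random_atoms(12, seed = 41))
  base <- unname(system_coords(sys))
  set.seed(42)
  R <- random_rotation()
  rotated <- base %*% t(R)
  shifted <- sweep(base, 2, c(3, 4, 0), `+`)
  traj <- trajectory(sys, list(base, rotated, shifted), dt = 1)
  out_fit <- rmsd_series(traj, reference = 1, sel = 1:12, superpose = TRUE)
  expect_equal(out_fit$rmsd[1], 0, tolerance = 1e-12)
  expect_lt(out_fit$rmsd[2], 1e-9)
  out_raw <- rmsd_series(traj, reference = 1, sel = 1:12, superpose = FALSE)
  expect_equal(out_raw$rmsd[3], 5.0, tolerance = 1e-12)
})

test_that("Kabsch superposition agrees with an independent implementation", {
  sys <- new_system(random_atoms(15, seed = 43))
  base <- unname(system_coords(sys))
  set.seed(44)
  moved <- sweep((base + rnorm(45, sd = 0.3)) %*% t(random_rotation()),
                 2, c(5, -2, 1), `+`)
  traj <- trajectory(sys, list(base, moved), dt = 1)
  ours <- rmsd_series(traj, reference = 1, sel = 1:15,
                      superpose = TRUE)$rmsd[2]
  ref <- bio3d::rmsd(as.vector(t(base)), as.vector(t(moved)), fit = TRUE)
  expect_lt(abs(ours - ref), 1e-3)  # bio3d rounds to 3 decimals
})

test_that("RMSF matches closed forms and the two-pass formula", {
  sys <- new_system(point_atom(0, 0, 0))
  d <- 1.7
  frames <- rep(list(matrix(c(d, 0, 0), 1), matrix(c(-d, 0, 0), 1)), 4)
  traj <- trajectory(sys, frames, dt = 1)
  out <- rmsf(traj, sel = 1L, align = "none", per = "atom")
  expect_equal(out$rmsf, d, tolerance = 1e-12)
  # static trajectory: all zeros (alignment on)
  sys2 <- new_system(random_atoms(10, seed = 45))
  static <- trajectory(sys2, rep(list(unname(system_coords(sys2))), 3),
                       dt = 1)
  expect_true(all(rmsf(static, align = "mean")$rmsf < 1e-12))
  expect_error(rmsf(trajectory(sys2, list(unname(system_coords(sys2)))),
                    align = "none"), "two frames")
  # random fixture vs textbook two-pass computation (no alignment)
  set.seed(46)
  frames3 <- lapply(1:20, function(i) {
    unname(system_coords(sys2)) + rnorm(30, sd = 0.4)
  })
  traj3 <- trajectory(sys2, frames3, dt = 1)
  got <- rmsf(traj3, sel = 1:10, align = "none", per = "atom")$rmsf
  for (i in 1:10) {
    xs <- t(vapply(frames3, function(f) f[i, ], numeric(3)))
    mu <- colMeans(xs)
    expect_equal(got[i], sqrt(mean(rowSums(sweep(xs, 2, mu)^2))),
                 tolerance = 1e-12)
  }
})
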