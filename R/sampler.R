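# quaternion helpers (scalar-first convention, body->lab rotation)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# exact free rotation by body angular velocity w over time h
quat_rotate_by <- function(q, w, h) {
  wn <- sqrt(sum(w^2))
  if (wn * h < 1e-14) return(q)
  half <- wn * h / 2
  dq <- c(cos(half), sin(half) * w / wn)
  quat_normalize(quat_mul(q, dq))
}

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  quat_normalize(q)
}

# random rotation, uniform on SO(3), via normalised 4-vector of normals
random_quat <- function() quat_normalize(rnorm(4))

# rigid-body bookkeeping for one probe group: centre of mass, principal
# inertia moments and body-frame (principal-axis) coordinates
rigid_body_setup <- function(coords, mass) {
  m <- sum(mass)
  com <- colSums(coords * mass) / m
  rel <- sweep(coords, 2, com)
  if (nrow(coords) == 1) {
    return(list(mass = m, com = com, body = rel,
                inertia = c(0, 0, 0), quat = c(1, 0, 0, 0)))
  }
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    I <- I + mass[i] * (sum(r^2) * diag(3) - outer(r, r))
  }
  eg <- eigen(I, symmetric = TRUE)
  A <- eg$vectors
  if (det(A) < 0) A[, 3] <- -A[, 3]   # proper rotation only
  body <- rel %*% A                    # coordinates in principal frame
  list(mass = m, com = com, body = body, inertia = eg$values,
       quat = mat_to_quat(A))
}

#' Place probe molecules randomly inside the confinement region
#'
#' Repositions every probe molecule of the system at a uniform random
#' point inside the cylinder with a uniform random orientation, rejecting
#' placements that bring any probe heavy atom closer than
#' `min_separation` to receptor heavy atoms or previously placed probes.
#' Deterministic for a given seed. If the system has no probes yet,
#' supply a template and `n_probes` to add them first.
#'
#' @param system a `prb_system`
#' @param region a [cylinder_region()]
#' @param n_probes number of probes (defaults to the system's)
#' @param seed RNG seed
#' @param min_separation Angstrom (default 2.5)
#' @param template optional [probe_template()] when the system has no
#'   probes yet
#' @param max_attempts per-probe rejection budget
#' @return updated `prb_system`
#' @export
place_probes <- function(system, region, n_probes = NULL, seed = 1L,
                         min_separation = 2.5, template = NULL,
                         max_attempts = 500L) {
  if (length(system$probes) == 0) {
    if (is.null(template)) {
      abort("system has no probes; supply a probe template and n_probes")
    }
    system <- add_probes(system, template, n_probes %||% 1L)
  } else if (!is.null(n_probes) && n_probes != length(system$probes)) {
    abort("n_probes does not match the system's probe count")
  }
  set.seed(seed)
  a <- system$atoms
  recv_heavy <- system_coords(system, heavy_atoms(system, receptor_only = TRUE))
  placed <- NULL
  # perpendicular frame of the cylinder axis
  ax <- region$axis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * ax) * ax
  u <- u / sqrt(sum(u^2))
  v <- c(ax[2] * u[3] - ax[3] * u[2], ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  for (g in seq_along(system$probes)) {
    idx <- system$probes[[g]]
    sub <- a[idx, ]
    body <- rigid_body_setup(cbind(sub$x, sub$y, sub$z),
                             ifelse(is.na(sub$mass), 12, sub$mass))
    heavy <- sub$element != "H"
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      axial <- runif(1, 0, region$length)
      r <- region$radius * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      center <- region$base_point + axial * ax +
        r * (cos(th) * u + sin(th) * v)
      R <- quat_to_mat(random_quat())
      coords <- sweep(body$body %*% t(R), 2, center, `+`)
      hc <- coords[heavy, , drop = FALSE]
      if (nrow(recv_heavy) > 0 &&
          min_dist_cpp(hc, recv_heavy) < min_separation) next
      if (!is.null(placed) && min_dist_cpp(hc, placed) < min_separation) next
      a$x[idx] <- coords[, 1]
      a$y[idx] <- coords[, 2]
      a$z[idx] <- coords[, 3]
      placed <- rbind(placed, hc)
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(sprintf(paste0(
        "failed to place probe %d after %d attempts; ",
        "use fewer probes or a larger region"), g, max_attempts))
    }
  }
  system$atoms <- a
  system
}

#' Rigid-body Langevin dynamics of confined probes
#'
#' Integrates the probe molecules as rigid bodies (translation plus
#' quaternion rotation) around the fixed receptor with a BAOAB-splitting
#' Langevin integrator at `config$temperature`. Forces are the
#' pairwise Coulomb + Lennard-Jones interactions of the
#' [nonbonded_model()] (probe-receptor and probe-probe) plus the
#' confinement wall acting on each probe's centre of mass. Identical
#' seeds give identical trajectories.
#'
#' @param system a `prb_system` with placed probes (see [place_probes()])
#' @param region a [cylinder_region()], or `NULL` for unconfined motion
#' @param config a [run_config()]
#' @param trap optional diagnostic harmonic trap,
#'   `list(k = kcal/mol/A^2, center = 3-vector)`, applied to each
#'   probe's centre of mass
#' @return a `prb_trajectory` with a `$diagnostics` tibble (per saved
#'   frame: energies and kinetic temperature)
#' @export
run_langevin <- function(system, region = NULL, config = run_config(),
                         trap = NULL) {
  if (length(system$probes) == 0) abort("system has no probes")
  pidx <- probe_atoms(system)
  check_parameterized(system, pidx)
  recv_idx <- which(!system$atoms$is_probe)
  if (length(recv_idx) > 0) check_parameterized(system, recv_idx)
  a <- system$atoms
  if (any(is.na(a$mass[pidx]))) abort("probe atoms need masses")

  model <- nonbonded_model(cutoff = config$cutoff,
                           dielectric = config$dielectric,
                           switching = config$switching,
                           switch_start = config$switch_start)
  pr <- atoms_to_param(a[pidx, ])
  has_recv <- length(recv_idx) > 0
  if (has_recv) rc <- atoms_to_param(a[recv_idx, ])
  # pidx is unlist(probes), so group labels align with the probe-atom block
  group <- rep(seq_along(system$probes), lengths(system$probes))
  np <- length(system$probes)
  mass_atom <- a$mass[pidx]

  bodies <- lapply(seq_len(np), function(g) {
    rows <- which(group == g)
    b <- rigid_body_setup(pr$x[rows, , drop = FALSE], mass_atom[rows])
    b$rows <- rows
    b$rotate <- b$inertia > 1e-8
    b
  })

  kT <- KB_KCAL * config$temperature
  dt <- config$dt
  c1 <- exp(-config$friction * dt)
  c2 <- sqrt(1 - c1^2)

  set.seed(config$seed)
  # initial Maxwell-Boltzmann velocities
  vel <- t(vapply(bodies, function(b) {
    rnorm(3, sd = sqrt(kT * ACC_CONV / b$mass))
  }, numeric(3)))
  omega <- t(vapply(bodies, function(b) {
    w <- rnorm(3)
    s <- ifelse(b$rotate, sqrt(kT * ACC_CONV / pmax(b$inertia, 1e-8)), 0)
    w * s
  }, numeric(3)))
  centers <- t(vapply(bodies, function(b) b$com, numeric(3)))
  quats <- lapply(bodies, function(b) b$quat)
  rots <- lapply(quats, quat_to_mat)

  all_beads <- length(pidx) == np   # every probe is a single atom
  any_rot <- any(vapply(bodies, function(b) any(b$rotate), logical(1)))

  probe_coords <- function() {
    if (all_beads) return(centers)
    X <- matrix(0, length(pidx), 3)
    for (g in seq_len(np)) {
      b <- bodies[[g]]
      X[b$rows, ] <- sweep(b$body %*% t(rots[[g]]), 2, centers[g, ], `+`)
    }
    X
  }

  eval_forces <- function(X) {
    fa <- matrix(0, nrow(X), 3)
    elec <- 0; vdw <- 0
    if (has_recv) {
      resv <- nb_cross_cpp(X, rc$x, pr$q, rc$q, pr$e, rc$e, pr$r, rc$r,
                           model$coulomb_k, model$dielectric,
                           model_cut(model), model$switching,
                           model$switch_start, TRUE)
      fa <- fa + resv$forces
      elec <- elec + resv$elec; vdw <- vdw + resv$vdw
    }
    if (np > 1) {
      ress <- nb_self_groups_cpp(X, pr$q, pr$e, pr$r, as.integer(group),
                                 model$coulomb_k, model$dielectric,
                                 model_cut(model), model$switching,
                                 model$switch_start)
      fa <- fa + ress$forces
      elec <- elec + ress$elec; vdw <- vdw + ress$vdw
    }
    fnet <- rowsum(fa, group)
    tq <- matrix(0, np, 3)
    if (any_rot) {
      for (g in seq_len(np)) {
        b <- bodies[[g]]
        if (!any(b$rotate)) next
        rel <- sweep(X[b$rows, , drop = FALSE], 2, centers[g, ])
        fg <- fa[b$rows, , drop = FALSE]
        tlab <- c(sum(rel[, 2] * fg[, 3] - rel[, 3] * fg[, 2]),
                  sum(rel[, 3] * fg[, 1] - rel[, 1] * fg[, 3]),
                  sum(rel[, 1] * fg[, 2] - rel[, 2] * fg[, 1]))
        tq[g, ] <- drop(t(rots[[g]]) %*% tlab)
      }
    }
    e_wall <- 0
    if (!is.null(region)) {
      wl <- wall_energy_force(centers, region)
      fnet <- fnet + wl$force
      e_wall <- wl$energy
    }
    e_trap <- 0
    if (!is.null(trap)) {
      d <- sweep(centers, 2, trap$center)
      fnet <- fnet - trap$k * d
      e_trap <- 0.5 * trap$k * sum(d^2)
    }
    list(fnet = fnet, torque = tq, elec = elec, vdw = vdw,
         e_wall = e_wall, e_trap = e_trap)
  }

  mtot <- vapply(bodies, function(b) b$mass, numeric(1))
  inv_m <- ACC_CONV / mtot
  inertia <- t(vapply(bodies, function(b) pmax(b$inertia, 1e-8), numeric(3)))
  rot_mask <- t(vapply(bodies, function(b) as.numeric(b$rotate), numeric(3)))
  inv_I <- ACC_CONV / inertia * rot_mask
  sd_v <- sqrt(kT * ACC_CONV / mtot)
  sd_w <- sqrt(kT * ACC_CONV / inertia) * rot_mask

  n_save <- config$n_steps %/% config$save_interval
  frames <- vector("list", n_save)
  diag_rows <- vector("list", n_save)
  base_coords <- system_coords(system)
  isave <- 0L

  X <- probe_coords()
  f <- eval_forces(X)

  half_A <- function() {
    centers <<- centers + 0.5 * dt * vel
    if (any_rot) {
      for (g in seq_len(np)) {
        if (any(bodies[[g]]$rotate)) {
          quats[[g]] <<- quat_rotate_by(quats[[g]], omega[g, ], 0.5 * dt)
          rots[[g]] <<- quat_to_mat(quats[[g]])
        }
      }
    }
  }

  for (step in seq_len(config$n_steps)) {
    # B: half kick
    vel <- vel + 0.5 * dt * f$fnet * inv_m
    omega <- omega + 0.5 * dt * f$torque * inv_I
    half_A()
    # O: Ornstein-Uhlenbeck on linear and angular velocities
    noise <- matrix(rnorm(np * 6), np, 6)
    vel <- c1 * vel + c2 * sd_v * noise[, 1:3, drop = FALSE]
    omega <- c1 * omega + c2 * sd_w * noise[, 4:6, drop = FALSE]
    half_A()
    X <- probe_coords()
    f <- eval_forces(X)
    vel <- vel + 0.5 * dt * f$fnet * inv_m
    omega <- omega + 0.5 * dt * f$torque * inv_I

    e_pot <- f$elec + f$vdw + f$e_wall + f$e_trap
    if (!is.finite(e_pot) || abs(e_pot) > config$energy_abort) {
      abort(sprintf("energy divergence at step %d (E = %g kcal/mol)",
                    step, e_pot))
    }

    if (step %% config$save_interval == 0L) {
      isave <- isave + 1L
      fr <- base_coords
      fr[pidx, ] <- X
      frames[[isave]] <- fr
      ke_tr <- 0.5 * sum(mtot * rowSums(vel^2)) / ACC_CONV
      ke_rot <- 0.5 * sum(inertia * rot_mask * omega^2) / ACC_CONV
      diag_rows[[isave]] <- tibble::tibble(
        frame = isave, step = step, time = step * dt,
        elec = f$elec, vdw = f$vdw, wall = f$e_wall, trap = f$e_trap,
        ke_trans = ke_tr, ke_rot = ke_rot,
        temp_trans = 2 * ke_tr / (3 * np * KB_KCAL)
      )
    }
  }

  trajectory(system, frames, dt = config$dt * config$save_interval,
             diagnostics = dplyr::bind_rows(diag_rows))
}
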