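#' Toy receptor specification
#'
#' Parameters of the deterministic toy receptor generator: a hollow
#' spherical shell of single-atom residues with an opening (the pocket
#' mouth) on `pocket_face`, and a ring of annotated pocket residues
#' around the mouth. One of them - labelled 8.49, mirroring the primary
#' anchoring position of the intracellular pocket - is the planted
#' attractor: it gets `attractor_strength` of extra Lennard-Jones well
#' depth and a negative partial charge, making it the ground-truth
#' hotspot.
#'
#' @param n_shell_atoms shell atoms (one residue each)
#' @param shell_radius Angstrom
#' @param pocket_face unit vector of the pocket opening
#' @param pocket_residues number of annotated pocket residues (up to 6:
#'   anchors 2.43/7.56/8.48, then hotspots 8.49/7.53/6.36)
#' @param attractor_strength extra LJ well depth on the attractor,
#'   kcal/mol (0 = no planted hotspot)
#' @param seed RNG seed for the coordinate jitter
#' @return a `toy_receptor_spec`
#' @export
toy_receptor_spec <- function(n_shell_atoms = 80, shell_radius = 12,
                              pocket_face = c(0, 0, -1),
                              pocket_residues = 6,
                              attractor_strength = 2, seed = 1L) {
  if (shell_radius <= 0) abort("shell_radius must be > 0")
  if (attractor_strength < 0) abort("attractor_strength must be >= 0")
  if (pocket_residues > n_shell_atoms) {
    abort("pocket_residues cannot exceed n_shell_atoms")
  }
  pocket_face <- pocket_face / sqrt(sum(pocket_face^2))
  structure(list(n_shell_atoms = n_shell_atoms,
                 shell_radius = shell_radius, pocket_face = pocket_face,
                 pocket_residues = as.integer(pocket_residues),
                 attractor_strength = attractor_strength,
                 seed = as.integer(seed)),
            class = "toy_receptor_spec")
}

# labels mirror the intracellular pocket topology: three anchor
# positions defining the pocket centre, then the hotspot positions
TOY_BW_LABELS <- c("2.43", "7.56", "8.48", "8.49", "7.53", "6.36")

#' Build a toy receptor with a planted attractive pocket
#'
#' Places `n_shell_atoms` single-atom residues quasi-uniformly on a
#' sphere, removes a cap around `pocket_face` to open a pocket mouth,
#' annotates the residues ringing the mouth with generic labels
#' (anchors 2.43/7.56/8.48 and hotspots 8.49/7.53/6.36), and plants the
#' attractor on the 8.49 residue. Deterministic for a given spec.
#'
#' @param spec a [toy_receptor_spec()]
#' @return list with `system` (a parameterised `prb_system`), `bw` (a
#'   [bw_map()]), and `ground_truth` (tibble: the attractor residue)
#' @export
make_toy_receptor <- function(spec = toy_receptor_spec()) {
  set.seed(spec$seed)
  n0 <- spec$n_shell_atoms
  pts <- sphere_points(n0)
  # open the pocket mouth: drop atoms within ~22 degrees of the face
  cap_cos <- cos(22 * pi / 180)
  face_dot <- drop(pts %*% spec$pocket_face)
  pts <- pts[face_dot < cap_cos, , drop = FALSE]
  face_dot <- face_dot[face_dot < cap_cos]
  coords <- pts * spec$shell_radius +
    matrix(rnorm(length(pts), sd = 0.15), ncol = 3)
  n <- nrow(coords)
  # pocket residues: the ring closest to the mouth
  ring <- order(face_dot, decreasing = TRUE)[seq_len(spec$pocket_residues)]
  labels <- TOY_BW_LABELS[seq_len(min(spec$pocket_residues,
                                      length(TOY_BW_LABELS)))]
  atoms_tbl <- tibble::tibble(
    serial = seq_len(n), name = "CA", element = "C", resname = "SHL",
    resid = seq_len(n), chain = "A",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = 0, epsilon = 0.05, rmin_half = 2.0, mass = 12.011,
    is_probe = FALSE
  )
  attractor <- ring[match("8.49", labels)]
  if (!is.na(attractor) && spec$attractor_strength > 0) {
    atoms_tbl$epsilon[attractor] <- 0.05 + spec$attractor_strength
    atoms_tbl$charge[attractor] <- -0.4
  }
  sys <- new_system(atoms_tbl)
  map <- bw_map(tibble::tibble(chain = "A",
                               resid = ring[seq_along(labels)],
                               bw = labels))
  gt <- if (is.na(attractor)) {
    tibble::tibble(chain = character(), resid = integer(), bw = character())
  } else {
    tibble::tibble(chain = "A", resid = attractor, bw = "8.49")
  }
  list(system = sys, bw = map, ground_truth = gt)
}

#' Trajectory with a planted hotspot
#'
#' Two modes. `"synthesize"` writes frames directly: a single probe
#' dwells within the occupancy shell of the pocket centre in a
#' prescribed fraction `f` of frames (evenly spread) and sits far
#' outside otherwise, so analysis code can be tested against exact
#' ground truth with no sampler stochasticity. `"sample"` runs the
#' Langevin sampler on the toy receptor inside a confinement region
#' anchored over the pocket.
#'
#' @param spec a [toy_receptor_spec()]
#' @param n_frames frames to produce
#' @param seed RNG seed
#' @param mode `"synthesize"` or `"sample"`
#' @param f occupied-frame fraction (synthesize mode), in `[0, 1]`
#' @param template probe template (default packaged NMS fragment)
#' @param config [run_config()] for sample mode (`n_steps` and
#'   `save_interval` are derived from `n_frames` if left at defaults)
#' @param n_probes probes in sample mode
#' @return list with `trajectory`, `system`, `bw`, `ground_truth`,
#'   `region`, and (synthesize mode) the planted `occupied` flags
#' @export
planted_hotspot_trajectory <- function(spec = toy_receptor_spec(),
                                       n_frames = 100, seed = 1L,
                                       mode = c("synthesize", "sample"),
                                       f = 0.6, template = NULL,
                                       config = NULL, n_probes = 6) {
  mode <- match.arg(mode)
  if (f < 0 || f > 1) abort("f must be in [0, 1]")
  toy <- make_toy_receptor(spec)
  if (is.null(template)) template <- packaged_probe("nms")
  anchors <- bw_residues(toy$bw, c("2.43", "7.56", "8.48"))
  region <- region_from_residues(toy$system, anchors)
  sys <- add_probes(toy$system, template, if (mode == "sample") n_probes else 1)

  if (mode == "synthesize") {
    set.seed(seed)
    pidx <- sys$probes[[1]]
    att <- toy$ground_truth
    target <- if (nrow(att) > 0) {
      drop(system_coords(sys, residue_atoms(sys, att$chain[1], att$resid[1])))
    } else {
      region$base_point
    }
    outward <- region$axis
    k_occ <- round(f * n_frames)
    # evenly spread occupied frames so short windows are representative
    occupied <- rep(FALSE, n_frames)
    if (k_occ > 0) {
      occupied[floor(seq(1, n_frames, length.out = k_occ))] <- TRUE
    }
    base <- system_coords(sys)
    body <- sweep(base[pidx, , drop = FALSE], 2,
                  colMeans(base[pidx, , drop = FALSE]))
    heavy_p <- atoms(sys)$element[pidx] != "H"
    center_res <- bw_residues(toy$bw, c("2.43", "7.56", "8.48"))
    cidx <- unlist(lapply(seq_len(nrow(center_res)), function(i) {
      residue_atoms(sys, center_res$chain[i], center_res$resid[i])
    }))
    center_xyz <- base[cidx, , drop = FALSE]
    frames <- lapply(seq_len(n_frames), function(i) {
      fcoord <- base
      rot <- body %*% t(quat_to_mat(random_quat()))
      center <- if (occupied[i]) {
        target + 3.0 * outward + rnorm(3, sd = 0.2)
      } else {
        target + 20 * outward + rnorm(3, sd = 0.5)
      }
      coords <- sweep(rot, 2, center, `+`)
      if (occupied[i]) {
        # slide straight toward the nearest pocket-centre atom until a
        # probe heavy atom sits well inside the 4 A occupancy shell
        hc <- coords[heavy_p, , drop = FALSE]
        com <- colMeans(hc)
        d2 <- rowSums(sweep(center_xyz, 2, com)^2)
        dir <- center_xyz[which.min(d2), ] - com
        dir <- dir / sqrt(sum(dir^2))
        shifts <- seq(0, 25, by = 0.2)
        ds <- vapply(shifts, function(s) {
          min_dist_cpp(sweep(hc, 2, s * dir, `+`), center_xyz)
        }, numeric(1))
        best <- shifts[which.min(abs(ds - 3.0))]
        coords <- sweep(coords, 2, best * dir, `+`)
      }
      fcoord[pidx, ] <- coords
      fcoord
    })
    traj <- trajectory(sys, frames, dt = 1)
    return(list(trajectory = traj, system = sys, bw = toy$bw,
                ground_truth = toy$ground_truth, region = region,
                occupied = occupied))
  }

  if (is.null(config)) {
    config <- run_config(seed = seed, n_steps = n_frames * 50,
                         save_interval = 50)
  } else {
    config$seed <- as.integer(seed)
  }
  sys <- place_probes(sys, region, seed = seed,
                      min_separation = config$min_separation)
  traj <- run_langevin(sys, region, config)
  list(trajectory = traj, system = sys, bw = toy$bw,
       ground_truth = toy$ground_truth, region = region)
}

#' Simulate a noisy 4PL dose-response dataset
#'
#' Responses are generated from the [fourpl()] curve at the given
#' concentrations plus i.i.d. Gaussian noise; deterministic per seed.
#'
#' @param emax,log_ec50,hill,basal true curve parameters
#' @param log10_conc concentrations (log10 M)
#' @param n_replicates replicates per concentration
#' @param noise_sd Gaussian noise SD (response units)
#' @param seed RNG seed
#' @param condition condition label attached to the data
#' @return tibble: `condition`, `replicate`, `log10_conc`, `response`
#' @export
simulate_dose_response <- function(emax = 1, log_ec50 = -8, hill = 1,
                                   basal = 0,
                                   log10_conc = seq(-11, -6, length.out = 8),
                                   n_replicates = 3, noise_sd = 0.02,
                                   seed = 1L, condition = "wt") {
  if (!all(is.finite(c(emax, log_ec50, hill, basal)))) {
    abort("true parameters must be finite")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  set.seed(seed)
  grid <- tidyr::crossing(replicate = seq_len(n_replicates),
                          log10_conc = log10_conc)
  grid$condition <- condition
  mu <- fourpl(grid$log10_conc, emax, log_ec50, hill, basal)
  grid$response <- mu + rnorm(nrow(grid), sd = noise_sd)
  grid[c("condition", "replicate", "log10_conc", "response")]
}
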