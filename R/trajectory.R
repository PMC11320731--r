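#' Trajectories
#'
#' An ordered list of coordinate frames for one [new_system()] system,
#' with a fixed frame spacing `dt` (ps). The canonical on-disk format is
#' XYZ with a `t= <time> ps` comment line; DCD files are read through
#' bio3d.
#'
#' @param system a `prb_system`
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom)
#' @param dt frame spacing, ps
#' @param diagnostics optional per-frame tibble attached by the sampler
#' @return a `prb_trajectory`
#' @export
trajectory <- function(system, frames, dt = 1, diagnostics = NULL) {
  stopifnot(inherits(system, "prb_system"))
  if (dt <= 0) abort("dt must be > 0")
  if (length(frames) == 0) abort("trajectory needs at least one frame")
  n <- nrow(system$atoms)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3) {
      abort("every frame must be an n_atoms x 3 matrix")
    }
    dimnames(f) <- NULL
    f
  })
  structure(list(system = system, frames = frames, dt = dt,
                 diagnostics = diagnostics),
            class = "prb_trajectory")
}

#' @export
print.prb_trajectory <- function(x, ...) {
  cat(sprintf("<prb_trajectory> %d frames x %d atoms, dt = %g ps\n",
              length(x$frames), nrow(x$system$atoms), x$dt))
  invisible(x)
}

#' Number of frames
#' @param traj a `prb_trajectory`
#' @export
n_frames <- function(traj) length(traj$frames)

#' Tidy a trajectory into a long tibble
#' @param x a `prb_trajectory`
#' @param ... unused
#' @return tibble with `frame`, `time`, `serial`, `x`, `y`, `z`
#' @export
tidy.prb_trajectory <- function(x, ...) {
  purrr::map_dfr(seq_along(x$frames), function(i) {
    f <- x$frames[[i]]
    tibble::tibble(frame = i, time = (i - 1) * x$dt,
                   serial = x$system$atoms$serial,
                   x = f[, 1], y = f[, 2], z = f[, 3])
  })
}

#' Write a trajectory as XYZ
#'
#' Standard multi-frame XYZ; the comment line records the frame time as
#' `t= <ps> ps`.
#'
#' @param traj a `prb_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_xyz <- function(traj, path) {
  el <- traj$system$atoms$element
  n <- length(el)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(c(
      as.character(n),
      sprintf("t= %.6f ps", (i - 1) * traj$dt),
      sprintf("%-2s %12.6f %12.6f %12.6f", el, f[, 1], f[, 2], f[, 3])
    ), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file
#' @param system the `prb_system` the frames belong to
#' @return a `prb_trajectory`; `dt` is recovered from the `t=` comment
#'   lines when present, else 1 ps
#' @export
read_xyz <- function(path, system) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty XYZ file: ", path))
  n <- nrow(system$atoms)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) abort(sprintf("XYZ parse error at line %d", i))
    if (cnt != n) {
      abort(sprintf("frame at line %d has %d atoms, system has %d",
                    i, cnt, n))
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t= *([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    body <- lines[i + 1L + seq_len(cnt)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      abort(sprintf("XYZ parse error in frame starting at line %d", i))
    }
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + cnt
  }
  dt <- if (length(times) >= 2 && all(is.finite(times))) {
    d <- diff(times)[1]
    if (d > 0) d else 1
  } else 1
  trajectory(system, frames, dt = dt)
}

#' Read a DCD trajectory
#'
#' CHARMM/NAMD binary trajectories, read through [bio3d::read.dcd()].
#'
#' @param path DCD file
#' @param system the `prb_system` the frames belong to
#' @param dt frame spacing, ps
#' @return a `prb_trajectory`
#' @export
read_dcd <- function(path, system, dt = 1) {
  m <- bio3d::read.dcd(path, verbose = FALSE)
  n <- nrow(system$atoms)
  if (ncol(m) != 3 * n) {
    abort(sprintf("DCD has %d atoms, system has %d", ncol(m) / 3, n))
  }
  frames <- lapply(seq_len(nrow(m)), function(i) {
    matrix(m[i, ], ncol = 3, byrow = TRUE)
  })
  trajectory(system, frames, dt = dt)
}

# coordinates of frame i restricted to atom rows idx
frame_coords <- function(traj, i, idx = NULL) {
  f <- traj$frames[[i]]
  if (is.null(idx)) f else f[idx, , drop = FALSE]
}
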