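#' Per-residue probe interaction energies (hotspot table)
#'
#' For each frame, receptor residues with any heavy atom within
#' `cutoff` (default 5 A) of any probe atom receive that frame's
#' electrostatic and van der Waals interaction energy with the probe
#' (all residue atoms vs all probe atoms, under the nonbonded model).
#' The table reports per-residue means and standard deviations. By
#' default averages run over contributing frames only (frames with the
#' residue inside the shell), which keeps hotspot energies undiluted;
#' `average = "all"` divides by the total frame count instead, counting
#' out-of-shell frames as zero.
#'
#' @param traj a `prb_trajectory`
#' @param probe probe group index (into `system$probes`), `"all"` for
#'   every probe atom, or an explicit atom-row vector
#' @param cutoff residue selection shell, Angstrom (default 5)
#' @param model a [nonbonded_model()]
#' @param map optional [bw_map()] to attach generic labels
#' @param average `"contributing"` (default) or `"all"`
#' @return a `hotspot_table` tibble: `chain`, `resid`, `resname`, `bw`,
#'   `elec_mean`, `elec_sd`, `vdw_mean`, `vdw_sd`, `total_mean`,
#'   `n_frames` (contributing), `n_total`
#' @export
residue_interaction_energies <- function(traj, probe = "all", cutoff = 5,
                                         model = nonbonded_model(),
                                         map = NULL,
                                         average = c("contributing", "all")) {
  average <- match.arg(average)
  sys <- traj$system
  pidx <- if (identical(probe, "all")) {
    probe_atoms(sys)
  } else if (is.numeric(probe) && length(probe) == 1 &&
             probe <= length(sys$probes)) {
    sys$probes[[probe]]
  } else {
    as.integer(probe)
  }
  if (length(pidx) == 0) abort("empty probe selection")
  ridx <- which(!sys$atoms$is_probe)
  if (length(ridx) == 0) abort("system has no receptor atoms")
  check_parameterized(sys, pidx)
  check_parameterized(sys, ridx)
  ra <- sys$atoms[ridx, ]
  pa_par <- atoms_to_param(sys$atoms[pidx, ])
  rc_par <- atoms_to_param(ra)
  heavy_r <- ra$element != "H"
  res_key <- paste(ra$chain, ra$resid)
  keys <- unique(res_key)
  keyf <- factor(res_key, levels = keys)
  nf <- n_frames(traj)

  e_mat <- matrix(0, length(keys), nf)
  v_mat <- matrix(0, length(keys), nf)
  shell <- matrix(FALSE, length(keys), nf)
  for (i in seq_len(nf)) {
    f <- traj$frames[[i]]
    per <- nb_per_atom_b_cpp(f[pidx, , drop = FALSE], f[ridx, , drop = FALSE],
                             pa_par$q, rc_par$q, pa_par$e, rc_par$e,
                             pa_par$r, rc_par$r,
                             model$coulomb_k, model$dielectric,
                             model_cut(model), model$switching,
                             model$switch_start)
    # residue in shell iff any heavy atom within cutoff of any probe atom
    md <- per$min_dist
    md[!heavy_r] <- Inf
    shell[, i] <- tapply(md, keyf, min) <= cutoff
    e_mat[, i] <- tapply(per$elec, keyf, sum)
    v_mat[, i] <- tapply(per$vdw, keyf, sum)
  }

  n_con_all <- rowSums(shell)
  keep <- n_con_all > 0
  if (!any(keep)) {
    out <- tibble::tibble(chain = character(), resid = integer(),
                          resname = character(), bw = character(),
                          elec_mean = numeric(), elec_sd = numeric(),
                          vdw_mean = numeric(), vdw_sd = numeric(),
                          total_mean = numeric(), n_frames = integer(),
                          n_total = integer())
    return(structure(out, class = c("hotspot_table", class(out))))
  }
  ks <- strsplit(keys[keep], " ", fixed = TRUE)
  # frames outside the shell contribute zero; under "contributing" they
  # are excluded from both mean and SD
  stat_row <- function(vals, in_shell) {
    v <- vals
    v[!in_shell] <- 0
    sel <- if (average == "all") rep(TRUE, length(v)) else in_shell
    x <- v[sel]
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  }
  rows <- which(keep)
  el <- t(vapply(rows, function(r) stat_row(e_mat[r, ], shell[r, ]),
                 numeric(2)))
  vd <- t(vapply(rows, function(r) stat_row(v_mat[r, ], shell[r, ]),
                 numeric(2)))
  out <- tibble::tibble(
    chain = vapply(ks, `[`, "", 1),
    resid = as.integer(vapply(ks, `[`, "", 2)),
    elec_mean = unname(el[, 1]), elec_sd = unname(el[, 2]),
    vdw_mean = unname(vd[, 1]), vdw_sd = unname(vd[, 2]),
    n_frames = as.integer(n_con_all[keep]), n_total = nf
  )
  res_info <- dplyr::distinct(ra, .data$chain, .data$resid, .data$resname)
  out <- dplyr::left_join(out, res_info, by = c("chain", "resid"))
  out$bw <- if (!is.null(map)) bw_label(map, out$resid, out$chain) else NA_character_
  out$total_mean <- out$elec_mean + out$vdw_mean
  out <- out[c("chain", "resid", "resname", "bw", "elec_mean", "elec_sd",
               "vdw_mean", "vdw_sd", "total_mean", "n_frames", "n_total")]
  out <- out[order(out$total_mean, out$resid), ]
  structure(out, class = c("hotspot_table", class(tibble::tibble())))
}

#' Rank hotspot residues
#'
#' Orders the table by mean interaction energy, most favourable (most
#' negative) first; ties are broken by ascending residue id.
#'
#' @param table a `hotspot_table`
#' @param key `"total"`, `"elec"` or `"vdw"`
#' @return the reordered table
#' @export
rank_hotspots <- function(table, key = c("total", "elec", "vdw")) {
  key <- match.arg(key)
  if (nrow(table) == 0) abort("hotspot table is empty")
  col <- paste0(key, "_mean")
  out <- table[order(table[[col]], table$resid), ]
  out
}

#' Write a hotspot table as CSV
#'
#' The header comment records the model cutoff conventions so the file
#' is self-describing.
#'
#' @param table a `hotspot_table`
#' @param path output path
#' @param cutoff the residue shell used, for the header
#' @return `path`, invisibly
#' @export
write_hotspots_csv <- function(table, path, cutoff = 5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# per-residue probe interaction energies (kcal/mol), residue shell %.1f A",
    cutoff), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}
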