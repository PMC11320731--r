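test_that("PDB parsing preserves atom records as written", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   2      10.000   5.000  -4.000  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  sys <- read_pdb(f)
  a <- atoms(sys)
  expect_equal(nrow(a), 3)
  expect_equal(a$name, c("N", "CA", "C"))
  expect_equal(a$resname, c("ALA", "ALA", "GLY"))
  expect_equal(a$resid, c(1L, 1L, 2L))
  expect_equal(a$chain, rep("A", 3))
  expect_equal(a$x, c(11.104, 11.639, 10.000))
  expect_true(all(is.na(a$charge)))
})

test_that("PDB write/read round-trips the atom table", {
  sys <- new_system(random_atoms(25, seed = 11))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, f)
  back <- read_pdb(f)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, f2)
  again <- read_pdb(f2)
  cols <- c("serial", "name", "element", "resname", "resid", "chain")
  expect_equal(atoms(back)[cols], atoms(again)[cols])
  expect_equal(system_coords(back), system_coords(again))
  # coordinates survive to the format's 3-decimal precision
  expect_lt(max(abs(system_coords(back) - system_coords(sys))), 5e-4)
})

test_that("PDB reader agrees with an independent reader", {
  sys <- new_system(random_atoms(10, seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(as.vector(t(system_coords(read_pdb(f)))),
               as.vector(ref$xyz), tolerance = 1e-6)
})

test_that("malformed and empty PDB files raise informative errors", {
  bad <- "ATOM      1  N   ALA A   1        XX.YYY   6.134  -6.504  1.00  0.00           N"
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(bad, "END"), f)
  expect_error(read_pdb(f), "line 1")
  writeLines(character(0), f)
  expect_error(read_pdb(f), "no ATOM")
  expect_error(read_pdb(file.path(tempdir(), "does-not-exist.pdb")),
               "no such file")
})

test_that("packaged probe templates load with the expected structure", {
  nms <- packaged_probe("nms")
  tab_file <- system.file("extdata", "nms.prb", package = "probemap")
  n_rows <- length(readLines(tab_file)) - 1  # header line
  expect_equal(nrow(nms$atoms), n_rows)
  # sulfonamide sulfur + ring sulfur, and the N-methyl nitrogen
  expect_equal(sum(nms$atoms$element == "S"), 2)
  expect_gte(sum(nms$atoms$element == "N"), 1)
  expect_lt(abs(nms$net_charge), 1e-6)
  mmi <- packaged_probe("mmi")
  expect_gte(sum(mmi$atoms$element == "N"), 2)  # indazole
  expect_gte(sum(mmi$atoms$element == "O"), 1)  # methoxy
})

test_that("probe definition validation rejects bad input", {
  bead <- bead_probe()
  expect_equal(nrow(bead$atoms), 1)
  expect_equal(bead$net_charge, 0)
  df <- bead$atoms
  expect_error(probe_template(df[setdiff(names(df), "charge")]),
               "missing column")
  df_bad <- df
  df_bad$x <- NaN
  expect_error(probe_template(df_bad), "non-finite")
  df_neg <- df
  df_neg$epsilon <- -0.1
  expect_error(probe_template(df_neg), "epsilon")
})

test_that("receptor annotation resolves the pocket and lock residues", {
  map <- read_bw_csv(system.file("extdata", "ccr4_bw.csv",
                                 package = "probemap"))
  expect_equal(bw_label(map, 310), "8.49")
  expect_equal(bw_label(map, 304), "7.53")
  expect_equal(bw_label(map, 243), "6.36")
  expect_equal(bw_label(map, 135), "3.50")
  expect_equal(bw_label(map, 134), "3.49")
  expect_true(is.na(bw_label(map, 999)))
  # inverse round-trip over every annotated residue
  tab <- map$table
  for (i in seq_len(nrow(tab))) {
    hit <- bw_residues(map, tab$bw[i])
    expect_equal(hit$resid, tab$resid[i])
  }
  expect_equal(nrow(bw_residues(map, "12.34")), 0)
})

test_that("annotation validation catches duplicates and bad labels", {
  expect_error(bw_map(data.frame(resid = c(1, 2), bw = c("3.50", "3.50"))),
               "duplicate label")
  expect_error(bw_map(data.frame(resid = c(1, 1), bw = c("3.50", "3.51"))),
               "duplicate residue")
  empty <- bw_map(data.frame(resid = integer(), bw = character()))
  expect_true(is.na(bw_label(empty, 310)))
})

test_that("XYZ round-trip and DCD agree on the same frames", {
  sys <- new_system(random_atoms(8, seed = 21))
  set.seed(9)
  frames <- lapply(1:5, function(i) {
    unname(system_coords(sys) + rnorm(24, sd = 0.5))
  })
  traj <- trajectory(sys, frames, dt = 0.4)
  fx <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, fx)
  back <- read_xyz(fx, sys)
  expect_equal(n_frames(back), 5)
  expect_equal(back$dt, 0.4)
  for (i in 1:5) expect_equal(back$frames[[i]], frames[[i]], tolerance = 1e-5)
  fd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd_fixture(frames, fd)
  from_dcd <- read_dcd(fd, sys, dt = 0.4)
  expect_equal(n_frames(from_dcd), 5)
  for (i in 1:5) {
    expect_lt(max(abs(from_dcd$frames[[i]] - back$frames[[i]])), 1e-3)
  }
})

test_that("run configs round-trip through files and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("temperature = 300", "friction = 2.0", "seed = 7",
               "n_steps = 500", "dt_integration = 0.001",
               "switching = off", "# a comment"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$temperature, 300)
  expect_equal(cfg$friction, 2)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$dt, 0.001)
  expect_false(cfg$switching)
  writeLines("tempreature = 300", f)
  expect_error(read_run_config(f), "unknown config key")
  writeLines("temperature = -5", f)
  expect_error(read_run_config(f), "temperature")
})

test_that("regions serialise into config files and back", {
  reg <- cylinder_region(c(1, 2, 3), c(0, 1, 1), radius = 5, length = 12,
                         k_wall = 8, closed_far_end = FALSE)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_region(reg, f)
  back <- read_region(f)
  expect_equal(back$base_point, reg$base_point, tolerance = 1e-6)
  expect_equal(back$axis, reg$axis, tolerance = 1e-8)
  expect_equal(back$radius, 5)
  expect_false(back$closed_far_end)
  # embedded in a full run config
  writeLines(c("temperature = 310", readLines(f)), f)
  cfg <- read_run_config(f)
  expect_s3_class(cfg$region, "cylinder_region")
  expect_equal(cfg$region$length, 12)
})

test_that("system constructor enforces its invariants", {
  a <- random_atoms(6, seed = 2)
  expect_error(new_system(a[setdiff(names(a), "element")]), "missing column")
  a_bad <- a
  a_bad$epsilon[2] <- -1
  expect_error(new_system(a_bad), "epsilon")
  expect_error(new_system(a, probes = list(1:3, 3:4)), "disjoint")
  sys <- new_system(a, probes = list(1:2, 5:6))
  expect_equal(probe_atoms(sys), c(1:2, 5:6))
  expect_true(all(atoms(sys)$is_probe[c(1, 2, 5, 6)]))
  # hydrophobicity is an element rule: C and S only
  expect_equal(atoms(sys)$hydrophobic, atoms(sys)$element %in% c("C", "S"))
})
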