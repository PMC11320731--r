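#' Read a PDB structure
#'
#' Parses `ATOM`/`HETATM` records of a PDB file into a [new_system()]
#' object. Only the coordinate section is interpreted (`TER`/`END` and all
#' other record types are ignored); charges and Lennard-Jones parameters
#' are left unset. Malformed numeric fields raise an error naming the
#' offending line.
#'
#' @param path path to a PDB file
#' @return a `prb_system` (parameters `NA`)
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0) abort(paste0("no ATOM/HETATM records in ", path))
  num_field <- function(txt, lineno, what) {
    txt <- trimws(txt)
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v) & nzchar(txt)
    bad <- bad | !nzchar(txt)
    if (any(bad)) {
      abort(sprintf("PDB parse error at line %d: bad %s field '%s'",
                    lineno[bad][1], what, txt[bad][1]))
    }
    v
  }
  ln <- lines[keep]
  element <- trimws(substr(ln, 77, 78))
  name <- trimws(substr(ln, 13, 16))
  # fall back to the first alphabetic character of the atom name
  noel <- !nzchar(element)
  element[noel] <- substr(gsub("[^A-Za-z]", "", name[noel]), 1, 1)
  atoms_tbl <- tibble::tibble(
    serial = as.integer(num_field(substr(ln, 7, 11), keep, "serial")),
    name = name,
    element = element,
    resname = trimws(substr(ln, 18, 20)),
    resid = as.integer(num_field(substr(ln, 23, 26), keep, "residue id")),
    chain = substr(ln, 22, 22),
    x = num_field(substr(ln, 31, 38), keep, "x-coordinate"),
    y = num_field(substr(ln, 39, 46), keep, "y-coordinate"),
    z = num_field(substr(ln, 47, 54), keep, "z-coordinate")
  )
  new_system(atoms_tbl)
}

#' Write a system to PDB
#'
#' Writes `ATOM` records (plus `TER`/`END`) in fixed-width PDB format.
#' Coordinates are written with 3 decimals, the format's precision.
#'
#' @param system a `prb_system`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(system, path) {
  a <- system$atoms
  name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                  substr(a$name, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name4, substr(a$resname, 1, 3), a$chain,
    a$resid %% 10000L, a$x, a$y, a$z, 1.0, 0.0, a$element
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
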