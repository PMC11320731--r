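#' Ballesteros-Weinstein residue annotation
#'
#' GPCR residues are conventionally labelled by helix.position relative
#' to the most conserved residue of each helix (e.g. `"8.49"`), plus
#' named segments such as `"IL1"`. A `bw_map` is a bijection between
#' `(chain, resid)` keys and labels, built from a two-column annotation
#' table (`resid,bw`; an optional `chain` column defaults to `"A"`).
#'
#' @param table data frame with columns `resid` and `bw` (optional
#'   `chain`)
#' @return a `bw_map`
#' @export
bw_map <- function(table) {
  table <- tibble::as_tibble(table)
  if (!all(c("resid", "bw") %in% names(table))) {
    abort("annotation needs columns `resid` and `bw`")
  }
  if (!"chain" %in% names(table)) table$chain <- "A"
  table <- table[c("chain", "resid", "bw")]
  table$resid <- as.integer(table$resid)
  table$bw <- as.character(table$bw)
  ok <- grepl("^[0-9]+\\.[0-9]+$", table$bw) | grepl("^[A-Za-z]", table$bw)
  if (any(!ok)) {
    abort(paste0("malformed label(s): ", paste(table$bw[!ok], collapse = ", ")))
  }
  dup_key <- duplicated(table[c("chain", "resid")])
  if (any(dup_key)) abort("duplicate residue key in annotation")
  dup_lab <- duplicated(table[c("chain", "bw")])
  if (any(dup_lab)) {
    abort(paste0("duplicate label for one chain: ",
                 paste(unique(table$bw[dup_lab]), collapse = ", ")))
  }
  structure(list(table = table), class = "bw_map")
}

#' @rdname bw_map
#' @param path CSV file with header `resid,bw` (optional `chain`)
#' @export
read_bw_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(bw = "character"))
  bw_map(tab)
}

#' @export
print.bw_map <- function(x, ...) {
  cat(sprintf("<bw_map> %d annotated residue(s)\n", nrow(x$table)))
  invisible(x)
}

#' Look up labels for residues
#'
#' @param map a `bw_map`
#' @param resid residue id(s)
#' @param chain chain (recycled)
#' @return character vector; `NA` where a residue is not annotated
#' @export
bw_label <- function(map, resid, chain = "A") {
  key <- paste(chain, resid)
  tab <- setNames(map$table$bw, paste(map$table$chain, map$table$resid))
  unname(tab[key])
}

#' Look up residues for labels (inverse)
#'
#' @param map a `bw_map`
#' @param bw label(s), e.g. `"8.49"`
#' @return tibble with `chain`, `resid`, `bw`; labels that are not in the
#'   map are dropped (zero rows if none match)
#' @export
bw_residues <- function(map, bw) {
  dplyr::semi_join(map$table, tibble::tibble(bw = bw), by = "bw")
}
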