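#' Read a genetic linkage map from a TSV file
#'
#' A linkage map is a plain tab-separated table with one row per genetic
#' marker and the header columns `marker`, `chromosome`, `genetic_cM`
#' (map position in centi-Morgans) and `physical_bp` (1-based assembly
#' position of the marker). Lines starting with `#` are ignored. Rows with
#' a missing or unparseable field are dropped with a warning.
#'
#' @param path Path to the map TSV.
#' @param map_id Identifier for this mapping population (e.g. the name of
#'   the cross); stored in the `map_id` column of the result.
#'
#' @return A tibble with columns `map_id`, `marker`, `chromosome`,
#'   `genetic_cM`, `physical_bp`, sorted by `genetic_cM` within chromosome
#'   (ties keep file order).
#'
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("marker\tchromosome\tgenetic_cM\tphysical_bp",
#'              "m1\tchr1\t0\t100001",
#'              "m2\tchr1\t5\t600001"), tsv)
#' read_map(tsv, map_id = "toy")
#' @export
read_map <- function(path, map_id) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0("cannot read map file: ", path), class = "recmapr_input_error")
  }
  raw <- tryCatch(
    suppressWarnings(readr::read_tsv(
      path,
      comment = "#",
      col_types = readr::cols(
        marker = readr::col_character(),
        chromosome = readr::col_character(),
        genetic_cM = readr::col_double(),
        physical_bp = readr::col_double()
      ),
      progress = FALSE
    )),
    error = function(e) abort(
      paste0("cannot parse map file ", path, ": ", conditionMessage(e)),
      class = "recmapr_input_error"
    )
  )
  required <- c("marker", "chromosome", "genetic_cM", "physical_bp")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("map file ", path, " lacks column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "recmapr_input_error"
    )
  }
  raw <- raw[required]
  bad <- !stats::complete.cases(raw)
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " row(s) with missing fields from ",
                path, " (first at data row ", which(bad)[1], ")"))
    raw <- raw[!bad, ]
  }
  if (nrow(raw) == 0) {
    abort(paste0("no valid marker rows in map file ", path,
                 " (first bad line: data row 1)"),
          class = "recmapr_input_error")
  }
  if (anyDuplicated(raw$marker)) {
    dup <- raw$marker[duplicated(raw$marker)][1]
    abort(paste0("duplicated marker name in ", path, ": ", dup),
          class = "recmapr_input_error")
  }
  if (any(raw$genetic_cM < 0) || any(raw$physical_bp < 1)) {
    i <- which(raw$genetic_cM < 0 | raw$physical_bp < 1)[1]
    abort(paste0("invalid coordinates in ", path, " at data row ", i,
                 " (genetic_cM must be >= 0, physical_bp >= 1)"),
          class = "recmapr_input_error")
  }
  raw$physical_bp <- as.integer(round(raw$physical_bp))
  out <- dplyr::mutate(raw, map_id = map_id, .before = 1)
  out <- dplyr::arrange(out, .data$chromosome, .data$genetic_cM)
  as_tibble(out)
}

#' Write a genetic map to TSV
#'
#' Inverse of [read_map()]: writes the four map columns in the documented
#' order (the `map_id` column is not written; it is supplied again on read).
#'
#' @param map A map tibble as returned by [read_map()] or [simulate_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map[c("marker", "chromosome", "genetic_cM", "physical_bp")],
                   path, progress = FALSE)
  invisible(path)
}
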