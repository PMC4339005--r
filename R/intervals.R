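#' Build inter-marker intervals with recombination rates
#'
#' Adjacent markers (in genetic-map order within each chromosome) bound an
#' interval whose recombination rate is its genetic length divided by its
#' physical length: `rate = genetic_cM / (bp / 1e6)` in cM/Mb. Intervals
#' bounded by a conflicting marker (see [find_order_conflicts()]) are
#' excluded outright -- no bridging interval is formed across a conflicting
#' marker, because its genetic position is unreliable. Intervals whose two
#' flanking markers share the same physical position are dropped with a
#' warning (zero physical span, rate undefined).
#'
#' Physical marker positions are 1-based; intervals are emitted 0-based
#' half-open (BED convention), so an interval between markers at bp
#' `p1 < p2` is `[p1 - 1, p2 - 1)` with length `p2 - p1`.
#'
#' @param map A map tibble (see [read_map()]).
#' @param conflicts Character vector of conflicting marker names, usually
#'   from [find_order_conflicts()].
#' @return A tibble with columns `map_id`, `chromosome`, `start`, `end`
#'   (0-based half-open), `genetic_cM` and `rate` (cM/Mb). Zero-rate
#'   intervals (equal genetic positions) are kept here; they are excluded
#'   downstream by [window_rates()].
#'
#' @examples
#' m <- tibble::tibble(map_id = "toy", marker = c("a", "b"),
#'                     chromosome = "chr1", genetic_cM = c(0, 5),
#'                     physical_bp = c(100001L, 600001L))
#' build_intervals(m)  # 5 cM over 0.5 Mb -> 10 cM/Mb
#' @export
build_intervals <- function(map, conflicts = character()) {
  stray <- setdiff(conflicts, map$marker)
  if (length(stray) > 0) {
    abort(paste0("conflict markers not in map: ", paste(stray, collapse = ", ")),
          class = "recmapr_input_error")
  }
  out <- split(seq_len(nrow(map)), map$chromosome) |>
    purrr::map(function(idx) {
      sub <- map[idx, ]
      sub <- sub[order(sub$genetic_cM), ]
      n <- nrow(sub)
      if (n < 2) return(NULL)
      a <- seq_len(n - 1L)
      b <- a + 1L
      ok <- !(sub$marker[a] %in% conflicts) & !(sub$marker[b] %in% conflicts)
      p1 <- sub$physical_bp[a]
      p2 <- sub$physical_bp[b]
      degenerate <- ok & p1 == p2
      if (any(degenerate)) {
        warn(paste0("dropping ", sum(degenerate), " interval(s) with zero ",
                    "physical span on ", sub$chromosome[1]))
        ok <- ok & !degenerate
      }
      if (!any(ok)) return(NULL)
      tibble(
        map_id = sub$map_id[1],
        chromosome = sub$chromosome[1],
        start = pmin(p1[ok], p2[ok]) - 1L,
        end = pmax(p1[ok], p2[ok]) - 1L,
        genetic_cM = abs(sub$genetic_cM[b][ok] - sub$genetic_cM[a][ok]),
        rate = abs(sub$genetic_cM[b][ok] - sub$genetic_cM[a][ok]) /
          (abs(p2[ok] - p1[ok]) / 1e6)
      )
    }) |>
    purrr::list_rbind()
  if (nrow(out) == 0) {
    out <- tibble(map_id = character(), chromosome = character(),
                  start = integer(), end = integer(),
                  genetic_cM = numeric(), rate = numeric())
  }
  dplyr::arrange(out, .data$chromosome, .data$start)
}

#' Write marker intervals as BED-like TSV
#'
#' Columns: `chromosome`, `start0`, `end`, `genetic_cM`, `rate_cM_per_Mb`
#' (coordinates 0-based half-open).
#'
#' @param intervals Interval tibble from [build_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  out <- tibble(
    chromosome = intervals$chromosome,
    start0 = intervals$start,
    end = intervals$end,
    genetic_cM = intervals$genetic_cM,
    rate_cM_per_Mb = intervals$rate
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
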