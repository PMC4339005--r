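#' Tile a genome into fixed-size windows
#'
#' Windows are the basic analysis unit: 0-based half-open tiles of
#' `window_size` bp (default 100 kb) covering each chromosome without gaps
#' or overlaps. The last window of a chromosome may be shorter and is
#' flagged `is_partial`; per-bp feature normalisation keeps partial windows
#' comparable downstream.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp,
#'   or a two-column data frame with `chromosome` and `length`.
#' @param window_size Window size in bp (default `100000`).
#' @return A tibble with columns `chromosome`, `start`, `end`, `index`
#'   (global 1-based window index) and `is_partial`.
#'
#' @examples
#' tile_genome(c(chr1 = 250000), window_size = 100000)
#' @export
tile_genome <- function(chrom_lengths, window_size = 100000) {
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size < 1) {
    abort("window_size must be a positive number of bp",
          class = "recmapr_parameter_error")
  }
  if (is.data.frame(chrom_lengths)) {
    lens <- stats::setNames(chrom_lengths$length, chrom_lengths$chromosome)
  } else {
    lens <- chrom_lengths
  }
  if (any(lens < 0)) {
    abort("chromosome lengths must be non-negative",
          class = "recmapr_parameter_error")
  }
  out <- purrr::imap(lens, function(len, chrom) {
    if (len < 1) return(NULL)
    starts <- seq(0, len - 1, by = window_size)
    tibble(
      chromosome = chrom,
      start = starts,
      end = pmin(starts + window_size, len)
    )
  }) |>
    purrr::list_rbind()
  out$index <- seq_len(nrow(out))
  out$is_partial <- (out$end - out$start) < window_size
  out
}

#' Per-window recombination rates for one map
#'
#' The rate of a window is the coverage-weighted average of the surviving
#' inter-marker interval rates overlapping it:
#' `sum(overlap_i * rate_i) / sum(overlap_i)`, with `overlap_i` the bp
#' intersection of interval `i` with the window. Intervals with a rate of
#' exactly zero are discarded *before* averaging -- such intervals are
#' artifacts of missing genotype data between physically close markers --
#' so a window whose only coverage was zero-rate is missing (`NA`), not 0.
#' Windows with no surviving coverage are `NA` as well.
#'
#' @param windows Window tibble from [tile_genome()].
#' @param intervals Interval tibble from [build_intervals()]; must come
#'   from a single map and be non-overlapping within each chromosome.
#' @return The window tibble with `map_id` and `rate` (cM/Mb, `NA` where
#'   missing) appended; one row per window.
#' @export
window_rates <- function(windows, intervals) {
  if (length(unique(intervals$map_id)) > 1) {
    abort("intervals must come from a single map",
          class = "recmapr_input_error")
  }
  # overlapping intervals within one map are a contract violation
  ovl_check <- split(intervals, intervals$chromosome)
  for (sub in ovl_check) {
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      abort(paste0("overlapping intervals on ", sub$chromosome[1]),
            class = "recmapr_input_error")
    }
  }
  map_id <- if (nrow(intervals) > 0) intervals$map_id[1] else NA_character_
  intervals <- intervals[intervals$rate != 0, , drop = FALSE]
  rate <- rep(NA_real_, nrow(windows))
  if (nrow(intervals) > 0) {
    for (chrom in intersect(unique(windows$chromosome),
                            unique(intervals$chromosome))) {
      wi <- which(windows$chromosome == chrom)
      ii <- which(intervals$chromosome == chrom)
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
        IRanges::IRanges(intervals$start[ii] + 1L, intervals$end[ii])
      )
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(windows$end[wi][qh], intervals$end[ii][sh]) -
        pmax(windows$start[wi][qh], intervals$start[ii][sh])
      num <- rowsum(ov * intervals$rate[ii][sh], qh)
      den <- rowsum(ov, qh)
      rate[wi[as.integer(rownames(den))]] <- num / den
    }
  }
  out <- windows
  out$map_id <- map_id
  out$rate <- as.numeric(rate)
  out
}

#' Cross-map mean and variance of window rates
#'
#' For every window, the mean and sample variance (denominator n - 1) of
#' the per-map rates with a present value. The mean is reported where at
#' least `min_maps` maps contribute; the variance where at least
#' `max(2, min_maps)` do.
#'
#' @param profiles A single long tibble of per-map window rates (rows from
#'   [window_rates()] over several maps bound together), or a list of such
#'   tibbles.
#' @param min_maps Minimum number of contributing maps (default 1).
#' @return A tibble keyed by window with `n_maps`, `mean_rate` and
#'   `var_rate` columns (`NA` where below the thresholds).
#' @export
summarize_across_maps <- function(profiles, min_maps = 1) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- purrr::list_rbind(profiles)
  }
  if (is.null(profiles) || nrow(profiles) == 0) {
    abort("no rate profiles supplied", class = "recmapr_parameter_error")
  }
  if (min_maps < 1) {
    abort("min_maps must be >= 1", class = "recmapr_parameter_error")
  }
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(window_key(), "index", "is_partial")))) |>
    dplyr::summarise(
      n_maps = sum(!is.na(.data$rate)),
      mean_rate = dplyr::if_else(
        .data$n_maps >= min_maps, mean(.data$rate, na.rm = TRUE), NA_real_),
      var_rate = dplyr::if_else(
        .data$n_maps >= max(2, min_maps),
        stats::var(.data$rate, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$index)
}

#' Write a per-window value track as TSV
#'
#' Columns `chromosome`, `start0`, `end`, `value`, with `NA` for missing;
#' 0-based half-open coordinates.
#'
#' @param windows A window tibble carrying the value column.
#' @param value Name of the value column (string).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(windows, value, path) {
  out <- tibble(
    chromosome = windows$chromosome,
    start0 = windows$start,
    end = windows$end,
    value = signif(windows[[value]], 6)
  )
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
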