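#' Find markers whose genetic and physical order conflict
#'
#' With the markers of each chromosome taken in genetic-map order, the
#' physical positions of a well-behaved map are strictly monotonic --
#' increasing, or decreasing when the chromosome is anchored to the
#' assembly in reverse orientation. Markers that break monotonicity
#' (typically mis-anchored loci) are identified as the complement of a
#' longest strictly monotonic subsequence of the physical positions, i.e.
#' the minimal set of markers whose removal restores a consistent
#' Marey map. The orientation (increasing vs decreasing) that needs fewer
#' removals is used per chromosome; ties between equally long subsequences
#' are broken by preferring to keep markers at smaller physical positions.
#'
#' @param map A map tibble (see [read_map()]).
#' @return A character vector of conflicting marker names (possibly empty).
#'
#' @examples
#' m <- tibble::tibble(map_id = "toy",
#'                     marker = c("a", "b", "c", "d"),
#'                     chromosome = "chr1",
#'                     genetic_cM = c(0, 1, 2, 3),
#'                     physical_bp = c(10L, 20L, 5L, 30L))
#' find_order_conflicts(m)  # "c": physically displaced
#' @export
find_order_conflicts <- function(map) {
  if (nrow(map) == 0) return(character())
  split(seq_len(nrow(map)), map$chromosome) |>
    purrr::map(function(idx) {
      sub <- map[idx, ]
      ord <- order(sub$genetic_cM)  # stable: ties keep stored order
      p <- as.numeric(sub$physical_bp[ord])
      if (length(p) < 2) return(character())
      keep_inc <- lis_indices(p, prefer_small = TRUE)
      keep_dec <- lis_indices(-p, prefer_small = FALSE)
      keep <- if (length(keep_dec) > length(keep_inc)) keep_dec else keep_inc
      sub$marker[ord][setdiff(seq_along(p), keep)]
    }) |>
    unlist(use.names = FALSE) %||% character()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# indices of a longest strictly increasing subsequence of v (O(n^2) DP).
# prefer_small: among equally long choices, favour elements with smaller v
# (used to break ties deterministically; pass -v / FALSE for decreasing).
lis_indices <- function(v, prefer_small = TRUE) {
  n <- length(v)
  len <- integer(n)
  prev <- integer(n)
  better <- if (prefer_small) `<` else `>`
  for (i in seq_len(n)) {
    len[i] <- 1L
    prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (v[j] < v[i]) {
        if (len[j] + 1L > len[i] ||
            (len[j] + 1L == len[i] && prev[i] > 0L && better(v[j], v[prev[i]]))) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
  }
  best <- which(len == max(len))
  end <- if (prefer_small) best[which.min(v[best])] else best[which.max(v[best])]
  keep <- integer(0)
  while (end > 0L) {
    keep <- c(end, keep)
    end <- prev[end]
  }
  keep
}
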