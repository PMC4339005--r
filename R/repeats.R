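#' Find perfect microsatellite (tandem repeat) tracts
#'
#' Maximal perfect tandem repeats with a unit of `unit_min`..`unit_max`
#' bp, a total tract length of at least `min_length_bp` and at least
#' `min_copies` complete unit copies. A tract may end in a partial unit
#' copy (the maximal perfect extension is reported). Candidate calls from
#' different unit sizes that overlap are merged: the reported interval is
#' their union and the reported unit is that of the longest candidate
#' (ties: smallest unit, then leftmost). Tracts containing `N` are never
#' called.
#'
#' @param seq A single DNA sequence.
#' @param unit_min,unit_max Repeat-unit size range in bp (defaults 1 and 6,
#'   the conventional microsatellite range).
#' @param min_length_bp Minimum tract length in bp (default 12).
#' @param min_copies Minimum number of complete unit copies (default 3).
#' @return A tibble with columns `start`, `end` (1-based, inclusive) and
#'   `unit`; zero rows when nothing is found. Total covered bp is the
#'   length of the union of the intervals.
#'
#' @examples
#' find_microsatellites("ACACACACACAC")  # one AC tract, 12 bp
#' @export
find_microsatellites <- function(seq, unit_min = 1, unit_max = 6,
                                 min_length_bp = 12, min_copies = 3) {
  if (unit_min < 1 || unit_max < unit_min || min_length_bp < 1 || min_copies < 1) {
    abort("repeat parameters must be positive with unit_min <= unit_max",
          class = "recmapr_parameter_error")
  }
  s <- strsplit(toupper(seq[[1]]), "", fixed = TRUE)[[1]]
  n <- length(s)
  b <- match(s, c("A", "C", "G", "T"))      # integer codes; NA for N etc.
  cand <- list()
  for (u in seq.int(unit_min, unit_max)) {
    if (n <= u) break
    b1 <- b[seq_len(n - u)]
    b2 <- b[seq.int(u + 1, n)]
    eq <- !is.na(b1) & !is.na(b2) & b1 == b2
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    tract_start <- starts[hit]
    tract_len <- r$lengths[hit] + u            # perfect span incl. partial copy
    ok <- tract_len >= min_length_bp & tract_len %/% u >= min_copies
    if (any(ok)) {
      cand[[length(cand) + 1L]] <- cbind(
        tract_start[ok], tract_start[ok] + tract_len[ok] - 1L,
        rep(u, sum(ok)))
    }
  }
  if (length(cand) == 0) {
    return(tibble(start = integer(), end = integer(), unit = character()))
  }
  cand <- do.call(rbind, cand)
  storage.mode(cand) <- "integer"
  ir <- IRanges::IRanges(cand[, 1], cand[, 2])
  red <- IRanges::reduce(ir, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- purrr::map(seq_along(red), function(i) {
    members <- revmap[[i]]
    m <- cand[members, , drop = FALSE]
    len <- m[, 2] - m[, 1] + 1L
    best <- order(-len, m[, 3], m[, 1])[1]
    tibble(
      start = as.integer(BiocGenerics::start(red)[i]),
      end = as.integer(BiocGenerics::end(red)[i]),
      unit = paste(s[seq.int(m[best, 1], m[best, 1] + m[best, 3] - 1L)],
                   collapse = "")
    )
  }) |>
    purrr::list_rbind()
  dplyr::arrange(out, .data$start)
}

#' Find low-complexity intervals (DUST-style)
#'
#' Scores sequence windows by triplet over-representation, as the classic
#' DUST masker does: within a `window`-bp frame with triplet counts
#' `c_t`, `score = sum(c_t * (c_t - 1) / 2) / (window - 3)`. Frames are
#' placed every `step` bp (half-overlapping by default) plus one final
#' frame flush with the sequence end; all positions inside frames whose
#' score exceeds `threshold` are merged into intervals. Triplets spanning
#' an `N` are ignored.
#'
#' A uniform-random sequence scores ~0.008 per frame, a homopolymer ~31,
#' so the default threshold of 2 separates the two cleanly.
#'
#' @param seq A single DNA sequence.
#' @param window Frame size in bp (default 64).
#' @param threshold Score above which a frame is low-complexity (default 2).
#' @param step Frame spacing in bp (default `window / 2`).
#' @return A tibble with columns `start`, `end` (1-based, inclusive);
#'   zero rows when nothing exceeds the threshold.
#'
#' @examples
#' find_low_complexity(strrep("A", 200))
#' @export
find_low_complexity <- function(seq, window = 64, threshold = 2,
                                step = window / 2) {
  s <- toupper(seq[[1]])
  n <- nchar(s)
  if (n < 8) return(tibble(start = integer(), end = integer()))
  b <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  if (n >= 3) {
    code <- b[seq_len(n - 2L)] * 16L + b[seq.int(2, n - 1L)] * 4L +
      b[seq.int(3, n)]
  } else {
    code <- integer(0)
  }
  win <- min(window, n)
  starts <- unique(c(seq.int(1L, max(1L, n - win + 1L), by = max(1L, round(step))),
                     n - win + 1L))
  flagged <- logical(length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]
    cds <- code[seq.int(a, a + win - 3L)]
    cds <- cds[!is.na(cds)]
    if (length(cds) == 0) next
    ct <- tabulate(cds + 1L, nbins = 64L)
    score <- sum(ct * (ct - 1) / 2) / (win - 3)
    flagged[i] <- score > threshold
  }
  if (!any(flagged)) return(tibble(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(starts[flagged],
                                         starts[flagged] + win - 1L))
  tibble(start = as.integer(BiocGenerics::start(ir)),
         end = as.integer(BiocGenerics::end(ir)))
}
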