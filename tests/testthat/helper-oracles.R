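# Independent oracles and fixture builders used across the suite.
# These deliberately use naive algorithms (substring scans, exhaustive
# subset search) so they share no code path with the package.

# naive overlapping-occurrence count by explicit position-by-position scan
naive_count_motif <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(0L)
  subs <- substring(seq, 1:(n - k + 1), k:n)
  sum(subs == motif)
}

# naive per-motif k-mer table: one substring scan per motif
naive_kmer_counts <- function(seq, k) {
  motifs <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                   stringsAsFactors = FALSE),
                       1, function(r) paste(rev(r), collapse = "")))
  n <- nchar(seq)
  subs <- if (n >= k) substring(toupper(seq), 1:(n - k + 1), k:n) else character()
  vapply(motifs, function(m) sum(subs == m), integer(1))
}

# exhaustive minimal-removal search: smallest number of elements whose
# removal leaves p strictly monotonic (increasing or decreasing)
brute_min_removals <- function(p) {
  n <- length(p)
  monotone <- function(v) {
    length(v) < 2 || all(diff(v) > 0) || all(diff(v) < 0)
  }
  for (size in 0:n) {
    if (size == 0) {
      if (monotone(p)) return(0L)
      next
    }
    sets <- utils::combn(n, size)
    for (j in seq_len(ncol(sets))) {
      if (monotone(p[-sets[, j]])) return(size)
    }
  }
  n
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# a tidy map tibble from parallel vectors
make_map <- function(chromosome, genetic_cM, physical_bp, map_id = "m",
                     marker = NULL) {
  tibble::tibble(
    map_id = map_id,
    marker = marker %||% paste0("mk", seq_along(genetic_cM)),
    chromosome = chromosome,
    genetic_cM = genetic_cM,
    physical_bp = as.integer(physical_bp)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_toy_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

write_toy_gff <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}
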