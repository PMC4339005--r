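#' GC content of a DNA sequence
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T); ambiguous bases (`N`) are
#' excluded from the denominator. `NA` when the sequence has no
#' unambiguous base.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`,
#'   case-insensitive.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#'
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGTN"))
#' @export
gc_content <- function(seq) {
  ds <- as_dna(seq)
  f <- Biostrings::letterFrequency(ds, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- (f[, "G"] + f[, "C"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}

# validate + uppercase; error names the first offending position
as_dna <- function(seq) {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(paste0("non-nucleotide character '",
                 substr(seq[i], bad[i], bad[i]),
                 "' at position ", bad[i],
                 if (length(seq) > 1) paste0(" of sequence ", i) else ""),
          class = "recmapr_input_error")
  }
  Biostrings::DNAStringSet(seq)
}

#' Count (possibly overlapping) motif occurrences
#'
#' Forward-strand, case-insensitive exact string search. Overlapping
#' occurrences all count; occurrences containing `N` never match.
#'
#' @param seq Character vector of DNA sequences.
#' @param motif A single motif over `{A,C,G,T}`.
#' @return Integer vector of occurrence counts.
#'
#' @examples
#' count_motif("CGCGCG", "CGC")  # 2, overlapping
#' @export
count_motif <- function(seq, motif) {
  if (length(motif) != 1 || is.na(motif) || nchar(motif) == 0) {
    abort("motif must be a single non-empty string",
          class = "recmapr_parameter_error")
  }
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    abort("motif must be over the alphabet {A,C,G,T}",
          class = "recmapr_parameter_error")
  }
  ds <- as_dna(seq)
  # fixed = TRUE: N in the subject matches nothing in an ACGT pattern
  Biostrings::vcountPattern(motif, ds, fixed = TRUE)
}

#' Counts of all k-mers of one length
#'
#' A single sliding pass counting every one of the `4^k` motifs;
#' positions whose k-mer spans an `N` contribute nothing. Identical to
#' calling [count_motif()] once per motif.
#'
#' @param seq A single DNA sequence.
#' @param k Motif length (the pipeline uses 2, 3 and 4).
#' @return Named integer vector of length `4^k`, names in lexicographic
#'   (A < C < G < T) order.
#'
#' @examples
#' all_kmer_counts("ACGT", 2)[c("AC", "CG", "GT")]
#' @export
all_kmer_counts <- function(seq, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("k must be a positive integer", class = "recmapr_parameter_error")
  }
  ds <- as_dna(seq)
  Biostrings::oligonucleotideFrequency(ds[[1]], width = as.integer(k))
}

#' CpG/GpC ratio
#'
#' Ratio of `CG` to `GC` dinucleotide counts, a commonly used indicator of
#' DNA methylation intensity (methylated CpG decays by deamination, so a
#' low ratio marks historically methylated sequence). `NA` when the
#' sequence contains no `GC`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of ratios.
#'
#' @examples
#' cpg_gpc_ratio("CGCG")  # 2 CG vs 1 GC -> 2
#' @export
cpg_gpc_ratio <- function(seq) {
  cg <- count_motif(seq, "CG")
  gc <- count_motif(seq, "GC")
  out <- cg / gc
  out[gc == 0] <- NA_real_
  out
}

#' Default set of longer motifs screened alongside k-mers
#'
#' Short motifs previously reported as recombination-associated in the
#' honey bee genome, screened per window in addition to the exhaustive
#' k-mer tables: `CGCA`, `GCCGC`, `CCAAT`, `CCGCA`, `CCTCCCT`, `CCAATCA`,
#' `CCCCGCAC`, `TGGGAAAGA`.
#'
#' @return Character vector of motifs.
#' @export
default_select_motifs <- function() {
  c("CGCA", "GCCGC", "CCAAT", "CCGCA", "CCTCCCT", "CCAATCA",
    "CCCCGCAC", "TGGGAAAGA")
}

#' Per-window sequence composition features
#'
#' Computes, for every window, GC content, CpG count, CpG/GpC ratio, the
#' full di-/tri-/tetra-nucleotide count tables (336 columns named by the
#' motif itself), counts of a configurable set of longer motifs
#' (`motif_*` columns), microsatellite and low-complexity coverage in bp,
#' and `effective_len` (unambiguous bases in the window).
#'
#' Motif and k-mer occurrences are credited to the window containing
#' their *start*: each window's scan extends `max(k) - 1` bases past its
#' end (within the chromosome) and only occurrences starting inside the
#' window are counted, so boundary-spanning occurrences are counted
#' exactly once, in the window where they begin.
#'
#' Soft-masking (lowercase) is ignored: sequence is uppercased before
#' counting. Precomputed repeat annotations can override the internal
#' detectors via `microsat_bed` / `lowcomp_bed` (BED3, 0-based half-open).
#'
#' @param windows Window tibble from [tile_genome()].
#' @param fasta Path to a genome FASTA or a [Biostrings::DNAStringSet];
#'   record names must match the window chromosome names.
#' @param select_motifs Character vector of longer motifs to count
#'   (default [default_select_motifs()]).
#' @param k Integer vector of exhaustive k-mer lengths (default `2:4`).
#' @param microsat_bed,lowcomp_bed Optional paths to BED files of
#'   precomputed repeat intervals; when given, coverage is computed from
#'   them instead of the internal detectors.
#' @param microsat_args,lowcomp_args Lists of arguments passed on to
#'   [find_microsatellites()] / [find_low_complexity()].
#' @return The window tibble with all feature columns appended; k-mer
#'   columns hold raw counts (see [normalize_kmer_columns()]).
#' @export
featurize_windows <- function(windows, fasta,
                              select_motifs = default_select_motifs(),
                              k = 2:4,
                              microsat_bed = NULL, lowcomp_bed = NULL,
                              microsat_args = list(), lowcomp_args = list()) {
  genome <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(windows$chromosome), names(genome))
  if (length(missing_chr) > 0) {
    abort(paste0("chromosome(s) absent from FASTA: ",
                 paste(missing_chr, collapse = ", ")),
          class = "recmapr_input_error")
  }
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(windows$end > chrlen[windows$chromosome])) {
    abort("windows extend beyond FASTA sequence bounds",
          class = "recmapr_input_error")
  }
  motifs <- toupper(select_motifs)
  ext <- max(c(k, nchar(motifs))) - 1L

  # plain window sequences (composition, repeats) ...
  win_seq <- Biostrings::DNAStringSet(toupper(as.character(Biostrings::subseq(
    genome[windows$chromosome], windows$start + 1L, windows$end))))
  # ... and right-extended ones for start-credited motif counting
  ext_end <- pmin(windows$end + ext, chrlen[windows$chromosome])
  ext_seq <- Biostrings::DNAStringSet(toupper(as.character(Biostrings::subseq(
    genome[windows$chromosome], windows$start + 1L, ext_end))))

  lf <- Biostrings::letterFrequency(win_seq, c("A", "C", "G", "T"))
  effective_len <- as.integer(rowSums(lf))
  gc <- (lf[, "G"] + lf[, "C"]) / effective_len
  gc[effective_len == 0] <- NA_real_

  count_started <- function(motif) {
    # occurrences of `motif` starting inside the window proper
    hits <- Biostrings::vmatchPattern(motif, ext_seq, fixed = TRUE)
    win_len <- windows$end - windows$start
    vapply(seq_along(hits), function(i) {
      sum(BiocGenerics::start(hits[[i]]) <= win_len[i])
    }, integer(1))
  }

  cpg <- count_started("CG")
  gpc <- count_started("GC")
  ratio <- cpg / gpc
  ratio[gpc == 0] <- NA_real_

  out <- windows
  out$effective_len <- effective_len
  out$gc_content <- unname(gc)
  out$cpg_count <- cpg
  out$cpg_gpc_ratio <- ratio

  for (m in motifs) out[[paste0("motif_", m)]] <- count_started(m)

  for (kk in sort(unique(as.integer(k)))) {
    # start-credited k-mer counts: count on the extended sequence, then
    # subtract k-mers starting in the extension tail
    full <- Biostrings::oligonucleotideFrequency(ext_seq, width = kk)
    if (ext - (kk - 1L) > 0) {
      tail_start <- (windows$end - windows$start) + 1L
      tail_seq <- Biostrings::DNAStringSet(substr(
        as.character(ext_seq), tail_start,
        Biostrings::width(ext_seq)))
      full <- full - Biostrings::oligonucleotideFrequency(tail_seq, width = kk)
    }
    for (j in colnames(full)) out[[j]] <- as.integer(full[, j])
  }

  out$microsat_bp <- repeat_coverage(
    win_seq, windows, microsat_bed,
    function(s) do.call(find_microsatellites, c(list(s), microsat_args)))
  out$lowcomp_bp <- repeat_coverage(
    win_seq, windows, lowcomp_bed,
    function(s) do.call(find_low_complexity, c(list(s), lowcomp_args)))
  out
}

# bp of each window covered by detector calls or by a BED override
repeat_coverage <- function(win_seq, windows, bed, detector) {
  if (!is.null(bed)) {
    b <- readr::read_tsv(bed, col_names = c("chromosome", "start", "end"),
                         col_types = "cii", comment = "#", progress = FALSE)
    cov <- integer(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      bi <- which(b$chromosome == windows$chromosome[i])
      if (length(bi) == 0) { cov[i] <- 0L; next }
      red <- IRanges::reduce(IRanges::IRanges(b$start[bi] + 1L, b$end[bi]))
      red <- IRanges::restrict(red, windows$start[i] + 1L, windows$end[i])
      cov[i] <- sum(IRanges::width(red))
    }
    return(cov)
  }
  vapply(as.character(win_seq), function(s) {
    calls <- detector(s)
    if (nrow(calls) == 0) return(0L)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(calls$start, calls$end))))
  }, integer(1), USE.NAMES = FALSE)
}

#' Convert k-mer count columns to per-bp frequencies
#'
#' Divides every k-mer count column (columns named by a pure-ACGT motif)
#' by the window's `effective_len`, so windows of different effective
#' length (partial tiles, N-containing sequence) stay comparable. Used
#' before correlation and PCA.
#'
#' @param features Feature tibble from [featurize_windows()].
#' @return The tibble with k-mer columns replaced by frequencies.
#' @export
normalize_kmer_columns <- function(features) {
  cols <- grep("^[ACGT]+$", names(features), value = TRUE)
  for (j in cols) {
    features[[j]] <- features[[j]] / features$effective_len
  }
  features
}
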