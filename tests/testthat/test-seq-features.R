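test_that("gc_content follows the ambiguity rule", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGTN"), 0.5)      # N excluded from denominator
  expect_true(is.na(gc_content("NNN")))
  expect_equal(gc_content("acgt"), 0.5)       # case folding
  expect_error(gc_content("ACGX"), class = "recmapr_input_error")
  expect_error(gc_content("ACGX"), "position 4")
})

test_that("count_motif counts overlapping forward-strand matches", {
  expect_equal(count_motif("CGCGCG", "CGC"), 2)
  expect_equal(count_motif("ACGT", "CG"), 1)
  expect_equal(count_motif("AAAA", "GCCGC"), 0)
  expect_equal(count_motif("ACNGT", "CG"), 0)  # N never matches
  expect_error(count_motif("ACGT", ""), class = "recmapr_parameter_error")
})

test_that("count_motif is strand-symmetric under joint reverse complement", {
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  withr::with_seed(7, {
    for (trial in 1:20) {
      s <- random_dna(200, p_n = 0.02)
      m <- random_dna(sample(2:4, 1))
      if (grepl("N", m)) next
      expect_equal(count_motif(s, m), count_motif(rc(s), rc(m)))
    }
  })
})

test_that("all_kmer_counts matches simple examples and sums correctly", {
  k2 <- all_kmer_counts("ACGT", 2)
  expect_equal(unname(k2[c("AC", "CG", "GT")]), c(1L, 1L, 1L))
  expect_equal(sum(k2), 3L)
  k3 <- all_kmer_counts("AAAA", 3)
  expect_equal(unname(k3["AAA"]), 2L)
  expect_equal(sum(k3), 2L)
})

test_that("all_kmer_counts equals the naive per-motif scanner, with N runs", {
  withr::with_seed(8, {
    for (trial in 1:15) {
      s <- random_dna(150, p_n = 0.05)
      for (k in 2:4) {
        expect_equal(all_kmer_counts(s, k), naive_kmer_counts(s, k))
      }
    }
  })
})

test_that("k-mer totals match unambiguous run arithmetic", {
  withr::with_seed(9, {
    for (trial in 1:10) {
      s <- random_dna(300, p_n = 0.05)
      runs <- nchar(strsplit(gsub("N", " ", s), " +")[[1]])
      for (k in 2:4) {
        expect_equal(sum(all_kmer_counts(s, k)),
                     sum(pmax(0L, runs - k + 1L)))
      }
    }
  })
})

test_that("cpg_gpc_ratio handles the zero-denominator case", {
  expect_equal(cpg_gpc_ratio("CGCG"), 2)
  expect_equal(cpg_gpc_ratio("GCGC"), 0.5)
  expect_true(is.na(cpg_gpc_ratio("AAAA")))
})

test_that("featurize_windows reproduces hand-computed composition", {
  # chr1 = two 10 bp windows with known content
  fa <- write_toy_fasta(c(chr1 = paste0("ACGTACGTAC", "GGGGCCCCGG")))
  w <- tile_genome(c(chr1 = 20), window_size = 10)
  f <- featurize_windows(w, fa, select_motifs = c("GCC"), k = 2)
  expect_equal(f$gc_content, c(0.5, 1))
  expect_equal(f$effective_len, c(10L, 10L))
  # window 1: CG at 2, 6; boundary AC..GG contributes AC at 9, CG at 10
  expect_equal(f$cpg_count[1], 3L)          # starts at 2, 6, 10 (boundary)
  expect_equal(f$cpg_count[2], 1L)          # CCGG -> one CG
  expect_equal(f$AC[1], 3L)
  expect_equal(f$motif_GCC[2], 1L)
  # start-credited counting: window 1 has 10 dinucleotide start positions
  expect_equal(sum(unlist(f[1, grep("^[ACGT]{2}$", names(f))])), 10L)
})

test_that("an all-N window has zero counts and missing ratios", {
  fa <- write_toy_fasta(c(chr1 = paste0(strrep("N", 10), "ACGTACGTAC")))
  w <- tile_genome(c(chr1 = 20), window_size = 10)
  f <- featurize_windows(w, fa, k = 2)
  expect_equal(f$effective_len[1], 0L)
  expect_true(is.na(f$gc_content[1]))
  expect_true(is.na(f$cpg_gpc_ratio[1]))
  expect_equal(f$cpg_count[1], 0L)
  expect_equal(sum(unlist(f[1, grep("^[ACGT]{2}$", names(f))])), 0L)
})

test_that("a boundary-spanning motif is credited to the window of its start", {
  fa <- write_toy_fasta(c(chr1 = paste0("AAAAAAAAAC", "GAAAAAAAAA")))
  w <- tile_genome(c(chr1 = 20), window_size = 10)
  f <- featurize_windows(w, fa, k = 2)
  expect_equal(f$cpg_count, c(1L, 0L))      # CG spans the boundary
  expect_equal(f$CG, c(1L, 0L))
})

test_that("missing chromosomes and out-of-bounds windows are input errors", {
  fa <- write_toy_fasta(c(chr1 = "ACGTACGT"))
  w <- tile_genome(c(chr2 = 8), window_size = 8)
  expect_error(featurize_windows(w, fa), class = "recmapr_input_error")
  w2 <- tile_genome(c(chr1 = 100), window_size = 100)
  expect_error(featurize_windows(w2, fa), class = "recmapr_input_error")
})

test_that("gc_content agrees with mononucleotide k-mer tallies", {
  withr::with_seed(10, {
    for (trial in 1:10) {
      s <- random_dna(200, p_n = 0.03)
      k1 <- all_kmer_counts(s, 1)
      expect_equal(gc_content(s),
                   (k1[["G"]] + k1[["C"]]) / sum(k1))
    }
  })
})

test_that("normalize_kmer_columns divides counts by effective length", {
  f <- tibble::tibble(effective_len = c(10L, 20L), AA = c(5L, 10L),
                      gc_content = c(0.5, 0.5))
  nf <- normalize_kmer_columns(f)
  expect_equal(nf$AA, c(0.5, 0.5))
  expect_equal(nf$gc_content, f$gc_content)  # non-k-mer columns untouched
})
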