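#' Run the full recombination-landscape pipeline
#'
#' Orchestrates the stages in order: read maps, screen for
#' genetic-vs-physical order conflicts, build inter-marker intervals,
#' tile the genome, compute per-window rates per map and the cross-map
#' mean/variance, extract sequence and gene features, and relate rates to
#' features (FDR-corrected correlations, backward stepwise regression,
#' per-k k-mer PCA). Every stage's output is written to `out_dir` as TSV
#' and returned; a run log records package version, settings hash and
#' per-stage row counts. Reruns with identical inputs and settings
#' produce byte-identical outputs.
#'
#' @param fasta Genome FASTA path (or `DNAStringSet`).
#' @param maps Named list: `map_id` -> map TSV path or map tibble.
#' @param gff Optional GFF3 path (or a gene tibble from [read_genes()]);
#'   when absent, gene features are skipped.
#' @param out_dir Output directory (created if needed).
#' @param window_size Window size in bp (default 100000).
#' @param select_motifs Longer motifs to count
#'   (default [default_select_motifs()]).
#' @param k k-mer lengths (default `2:4`).
#' @param method Correlation method (default `"pearson"`).
#' @param fdr FDR thresholds reported in the log (defaults 0.05, 0.01;
#'   the full q-values are always written).
#' @param p_remove Stepwise exclusion threshold (default 0.05).
#' @param n_pcs Retained principal components per k (default 2).
#' @param min_maps Minimum maps per window for the cross-map mean
#'   (default 1; the variance always needs >= 2).
#' @param stepwise_features Predictors for the stepwise model; default:
#'   the non-k-mer sequence and gene features.
#' @return Invisibly, a list with all stage outputs (`windows`,
#'   `conflicts`, `intervals`, `profiles`, `summary`, `features`,
#'   `correlations`, `stepwise`, `pca`, `paths`).
#' @export
run_pipeline <- function(fasta, maps, gff = NULL, out_dir,
                         window_size = 100000,
                         select_motifs = default_select_motifs(),
                         k = 2:4, method = "pearson",
                         fdr = c(0.05, 0.01), p_remove = 0.05, n_pcs = 2,
                         min_maps = 1, stepwise_features = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("recmapr ", as.character(utils::packageVersion("recmapr"))),
    paste0("window_size=", window_size, " k=", paste(k, collapse = ","),
           " method=", method, " p_remove=", p_remove, " n_pcs=", n_pcs,
           " min_maps=", min_maps),
    paste0("settings_hash=", rlang::hash(list(
      window_size, select_motifs, k, method, fdr, p_remove, n_pcs, min_maps)))
  )
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  genome <- if (inherits(fasta, "DNAStringSet")) fasta else {
    if (!file.exists(fasta)) {
      abort(paste0("FASTA not found: ", fasta), class = "recmapr_input_error")
    }
    Biostrings::readDNAStringSet(fasta)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))

  map_tbls <- purrr::imap(maps, function(m, id) {
    if (is.character(m)) read_map(m, id) else m
  })
  bad_chr <- setdiff(unique(unlist(purrr::map(map_tbls, "chromosome"))),
                     names(genome))
  if (length(bad_chr) > 0) {
    abort(paste0("map chromosome(s) not in FASTA: ",
                 paste(bad_chr, collapse = ", ")),
          class = "recmapr_input_error")
  }

  windows <- tile_genome(stats::setNames(Biostrings::width(genome),
                                         names(genome)), window_size)
  say("windows: ", nrow(windows))

  conflicts <- purrr::map(map_tbls, find_order_conflicts)
  intervals <- purrr::map2(map_tbls, conflicts, build_intervals)
  profiles <- purrr::map(intervals, function(iv) window_rates(windows, iv))
  for (id in names(map_tbls)) {
    say("map ", id, ": ", nrow(map_tbls[[id]]), " markers, ",
        length(conflicts[[id]]), " conflicts, ",
        nrow(intervals[[id]]), " intervals")
    write_intervals(intervals[[id]],
                    file.path(out_dir, paste0("intervals_", id, ".tsv")))
    write_track(profiles[[id]], "rate",
                file.path(out_dir, paste0("rate_", id, ".tsv")))
  }
  summary <- summarize_across_maps(profiles, min_maps = min_maps)
  write_track(summary, "mean_rate", file.path(out_dir, "mean.tsv"))
  write_track(summary, "var_rate", file.path(out_dir, "variance.tsv"))

  features <- featurize_windows(windows, genome,
                                select_motifs = select_motifs, k = k)
  if (!is.null(gff)) {
    genes <- if (is.character(gff)) read_genes(gff) else gff
    gene_chr_miss <- setdiff(unique(genes$chromosome), names(genome))
    if (length(gene_chr_miss) > 0) {
      abort(paste0("annotation chromosome(s) not in FASTA: ",
                   paste(gene_chr_miss, collapse = ", ")),
            class = "recmapr_input_error")
    }
    gf <- gene_window_features(genes, windows)
    features <- dplyr::left_join(
      features,
      gf[c(window_key(), "gene_number", "mean_gene_size_bp",
           "mean_gene_distance_bp", "mean_intron_size_bp",
           "mean_exon_size_bp")],
      by = window_key())
  }
  say("features: ", nrow(features), " windows x ",
      ncol(features) - ncol(windows), " columns")
  feat_out <- features
  num <- vapply(feat_out, is.double, logical(1))
  feat_out[num] <- lapply(feat_out[num], signif, digits = 6)
  readr::write_tsv(feat_out, file.path(out_dir, "features.tsv"),
                   na = "NA", progress = FALSE)

  norm_features <- normalize_kmer_columns(features)
  responses <- list(
    mean = dplyr::left_join(norm_features,
                            summary[c(window_key(), "mean_rate")],
                            by = window_key()),
    variance = dplyr::left_join(norm_features,
                                summary[c(window_key(), "var_rate")],
                                by = window_key())
  )
  resp_col <- c(mean = "mean_rate", variance = "var_rate")

  correlations <- purrr::imap(responses, function(d, nm) {
    ct <- correlate(d, !!resp_col[[nm]], method = method)
    out <- ct
    out[c("r", "p", "q")] <- lapply(out[c("r", "p", "q")], signif, 6)
    readr::write_tsv(out, file.path(out_dir,
                                    paste0("correlations_", nm, ".tsv")),
                     na = "NA", progress = FALSE)
    say("correlations_", nm, ": ",
        sum(ct$q < fdr[1], na.rm = TRUE), " at FDR<", fdr[1], ", ",
        sum(ct$q < fdr[2], na.rm = TRUE), " at FDR<", fdr[2])
    ct
  })

  if (is.null(stepwise_features)) {
    stepwise_features <- intersect(
      c("gc_content", "cpg_count", "cpg_gpc_ratio",
        paste0("motif_", toupper(select_motifs)),
        "microsat_bp", "lowcomp_bp",
        "gene_number", "mean_gene_size_bp", "mean_gene_distance_bp",
        "mean_intron_size_bp"),
      names(features))
  }
  stepwise <- purrr::imap(responses, function(d, nm) {
    fit <- suppressWarnings(
      backward_stepwise(d, !!resp_col[[nm]], stepwise_features,
                        p_remove = p_remove))
    out <- tidy(fit)
    out[c("beta", "p")] <- lapply(out[c("beta", "p")], signif, 6)
    readr::write_tsv(out, file.path(out_dir, paste0("stepwise_", nm, ".tsv")),
                     na = "NA", progress = FALSE)
    say("stepwise_", nm, ": retained ", nrow(fit$retained), "/",
        fit$n_start)
    fit
  })

  pca <- purrr::map(stats::setNames(k, paste0("k", k)), function(kk) {
    d <- responses$mean
    fit <- pca_kmers(d, mean_rate, k = kk, n_pcs = n_pcs,
                     normalize = FALSE)  # columns already frequencies
    bet <- tidy(fit)
    bet[c("beta", "p")] <- lapply(bet[c("beta", "p")], signif, 6)
    readr::write_tsv(bet, file.path(out_dir,
                                    paste0("pca_k", kk, "_mean.tsv")),
                     na = "NA", progress = FALSE)
    ld <- tidy(fit, "loadings")
    ld[-1] <- lapply(ld[-1], signif, 6)
    readr::write_tsv(ld, file.path(out_dir,
                                   paste0("pca_k", kk, "_loadings.tsv")),
                     na = "NA", progress = FALSE)
    ev <- tidy(fit, "eigenvalues")
    ev[-1] <- lapply(ev[-1], signif, 6)
    readr::write_tsv(ev, file.path(out_dir,
                                   paste0("pca_k", kk, "_eigenvalues.tsv")),
                     na = "NA", progress = FALSE)
    say("pca_k", kk, ": PC1+PC2 explain ",
        sprintf("%.1f%%", 100 * sum(fit$variance_explained[1:2])))
    fit
  })

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(
    windows = windows, conflicts = conflicts, intervals = intervals,
    profiles = profiles, summary = summary, features = features,
    correlations = correlations, stepwise = stepwise, pca = pca,
    out_dir = out_dir))
}
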