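#' Read gene models from a GFF3 file
#'
#' Parses `gene`, transcript (`mRNA`/`transcript`) and `exon` features
#' linked by `Parent` attributes. For each gene the exons of the
#' transcript with the greatest summed exon length are kept (merged where
#' overlapping); introns are the gaps between the sorted merged exons.
#' Genes without annotated transcripts/exons are treated as single-exon
#' genes spanning the gene body.
#'
#' @param gff Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `chromosome`,
#'   `start`, `end` (0-based half-open), `n_exons`, `exons` and `introns`
#'   (list-columns of tibbles with 0-based half-open `start`/`end`).
#' @export
read_genes <- function(gff) {
  gr <- tryCatch(
    rtracklayer::import(gff, format = "gff3"),
    error = function(e) abort(
      paste0("cannot parse GFF3 file ", gff, ": ", conditionMessage(e)),
      class = "recmapr_input_error"
    )
  )
  df <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(as.list(gr$Parent),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0) {
    abort(paste0("no gene features in ", gff), class = "recmapr_input_error")
  }
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  ex <- df[df$type == "exon", ]
  # exon -> gene, through the transcript layer when present
  ex$gene <- ifelse(ex$parent %in% genes$id, ex$parent,
                    tx$parent[match(ex$parent, tx$id)])

  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gex <- ex[!is.na(ex$gene) & ex$gene == g$id, ]
    if (nrow(gex) > 0 && nrow(tx) > 0 && any(gex$parent %in% tx$id)) {
      # pick the transcript with the greatest summed exon length
      by_tx <- split(gex, gex$parent)
      lens <- vapply(by_tx, function(x) sum(x$end - x$start), numeric(1))
      gex <- by_tx[[names(which.max(lens))]]
    }
    if (nrow(gex) == 0) {
      exons <- tibble(start = g$start, end = g$end)
    } else {
      red <- IRanges::reduce(IRanges::IRanges(gex$start + 1L, gex$end))
      exons <- tibble(start = BiocGenerics::start(red) - 1L,
                      end = BiocGenerics::end(red))
    }
    exons <- dplyr::arrange(exons, .data$start)
    introns <- if (nrow(exons) > 1) {
      tibble(start = exons$end[-nrow(exons)], end = exons$start[-1])
    } else {
      tibble(start = integer(), end = integer())
    }
    tibble(gene_id = g$id, chromosome = g$chromosome,
           start = g$start, end = g$end, n_exons = nrow(exons),
           exons = list(exons), introns = list(introns))
  }) |>
    purrr::list_rbind()
  dplyr::arrange(out, .data$chromosome, .data$start)
}

#' Per-window gene statistics
#'
#' A gene is assigned to the window containing its midpoint
#' (`floor((start + end) / 2)`), which keeps window gene counts integral
#' and their genome-wide sum equal to the number of genes in tiled
#' territory. Per window:
#' * `gene_number` -- count of assigned genes;
#' * `mean_gene_size_bp` -- mean `end - start` of assigned genes;
#' * `mean_gene_distance_bp` -- mean gap between consecutive genes
#'   (chromosome order) whose gap midpoint falls in the window;
#' * `mean_intron_size_bp`, `mean_exon_size_bp` -- mean intron/exon length
#'   over assigned genes.
#' All means are `NA` where no element contributes.
#'
#' @param genes Gene tibble from [read_genes()].
#' @param windows Window tibble from [tile_genome()].
#' @return The window tibble with the gene-feature columns appended.
#' @export
gene_window_features <- function(genes, windows) {
  win_of <- function(chrom, pos) {
    # window whose [start, end) contains pos (0-based)
    idx <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      wi <- which(windows$chromosome == ch)
      if (length(wi) == 0) next
      sel <- which(chrom == ch)
      j <- findInterval(pos[sel], windows$start[wi])
      ok <- j >= 1 & j <= length(wi)
      ok[ok] <- pos[sel][ok] < windows$end[wi][j[ok]]
      idx[sel[ok]] <- wi[j[ok]]
    }
    idx
  }

  out <- windows
  n <- nrow(windows)
  out$gene_number <- integer(n)
  out$mean_gene_size_bp <- rep(NA_real_, n)
  out$mean_gene_distance_bp <- rep(NA_real_, n)
  out$mean_intron_size_bp <- rep(NA_real_, n)
  out$mean_exon_size_bp <- rep(NA_real_, n)
  if (nrow(genes) == 0) return(out)

  mid <- (genes$start + genes$end) %/% 2
  gw <- win_of(genes$chromosome, mid)
  assigned <- which(!is.na(gw))
  if (length(assigned) > 0) {
    tab <- tapply(rep(1L, length(assigned)), gw[assigned], sum)
    out$gene_number[as.integer(names(tab))] <- as.integer(tab)
    size <- genes$end - genes$start
    ms <- tapply(size[assigned], gw[assigned], mean)
    out$mean_gene_size_bp[as.integer(names(ms))] <- as.numeric(ms)

    ilen <- vapply(genes$introns, function(x) sum(x$end - x$start), numeric(1))
    icnt <- vapply(genes$introns, nrow, integer(1))
    elen <- vapply(genes$exons, function(x) sum(x$end - x$start), numeric(1))
    ecnt <- vapply(genes$exons, nrow, integer(1))
    isum <- tapply(ilen[assigned], gw[assigned], sum)
    inum <- tapply(icnt[assigned], gw[assigned], sum)
    mi <- as.numeric(isum) / as.numeric(inum)
    out$mean_intron_size_bp[as.integer(names(isum))] <- ifelse(
      as.numeric(inum) > 0, mi, NA_real_)
    esum <- tapply(elen[assigned], gw[assigned], sum)
    enum <- tapply(ecnt[assigned], gw[assigned], sum)
    out$mean_exon_size_bp[as.integer(names(esum))] <-
      as.numeric(esum) / as.numeric(enum)
  }

  # inter-gene gaps, assigned to the window holding the gap midpoint
  for (ch in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) < 2) next
    gap_start <- g$end[-nrow(g)]
    gap_end <- g$start[-1]
    gap <- pmax(0, gap_end - gap_start)
    gmid <- (gap_start + gap_end) %/% 2
    gwin <- win_of(rep(ch, length(gmid)), gmid)
    ok <- !is.na(gwin)
    if (!any(ok)) next
    mg <- tapply(gap[ok], gwin[ok], mean)
    out$mean_gene_distance_bp[as.integer(names(mg))] <- as.numeric(mg)
  }
  out
}
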