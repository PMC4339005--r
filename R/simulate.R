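#' Simulation configuration
#'
#' Bundles the parameters of the toy-genome simulator. The defaults
#' describe the package's reference study scenario: a 5-chromosome,
#' 5 Mb-per-chromosome genome whose window-level GC content follows a
#' bimodal, AT-rich landscape (window GC between 0.1 and 0.7, emulating
#' the strongly bimodal 10-70% GC distribution of the honey bee genome),
#' a recombination rate coupled linearly to GC
#' (`rate = max(0, a + b * gc + noise)`, with intercept `a` = 5 cM/Mb,
#' slope `b` = 30 cM/Mb per GC unit and window noise sd 2 cM/Mb), and
#' four linkage maps of 150 kb mean marker spacing with map-level rate
#' noise sd 0.5 cM/Mb.
#'
#' @param seed Integer seed; fully determines every simulated output.
#' @param n_chromosomes,chrom_length Genome shape (bp per chromosome).
#' @param window_size Window size used for the GC/rate landscape (bp).
#' @param gc_profile `"bimodal"` (blockwise two-level landscape) or
#'   `"sinusoidal"`.
#' @param gc_range Admissible window GC range (clamped).
#' @param rate_intercept,rate_slope Rate model `a` (cM/Mb) and `b`
#'   (cM/Mb per unit GC).
#' @param rate_noise_sd Window-level rate noise sd (cM/Mb).
#' @param maps Tibble with one row per simulated map: `map_id`,
#'   `spacing` (mean marker spacing, bp), `noise_sd` (map-level rate
#'   noise, cM/Mb), `frac_shuffled` (fraction of markers whose physical
#'   positions are swapped with a neighbour to create order conflicts).
#' @param gene_density Genes per Mb.
#' @param microsat_density Planted microsatellite tracts per Mb.
#' @param markov_order Base-sampling model: 0 (default) draws bases
#'   i.i.d. from the window GC target, which keeps k-mer expectations
#'   analytic; 1 uses a CpG-depleting first-order Markov chain for richer
#'   composition nulls.
#' @return A list of class `recmap_sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 5,
                       chrom_length = 5e6,
                       window_size = 1e5,
                       gc_profile = c("bimodal", "sinusoidal"),
                       gc_range = c(0.1, 0.7),
                       rate_intercept = 5,
                       rate_slope = 30,
                       rate_noise_sd = 2,
                       maps = tibble(
                         map_id = paste0("map", 1:4),
                         spacing = 150000,
                         noise_sd = 0.5,
                         frac_shuffled = 0
                       ),
                       gene_density = 30,
                       microsat_density = 20,
                       markov_order = 0) {
  if (missing(seed)) abort("seed is mandatory", class = "recmapr_parameter_error")
  gc_profile <- match.arg(gc_profile)
  if (gc_range[1] < 0 || gc_range[2] > 1 || gc_range[1] >= gc_range[2]) {
    abort("gc_range must be within [0, 1]", class = "recmapr_parameter_error")
  }
  if (any(maps$spacing < 2)) {
    abort("mean marker spacing must be >= 2 bp",
          class = "recmapr_parameter_error")
  }
  structure(as.list(environment()), class = "recmap_sim_config")
}

# blockwise bimodal or sinusoidal per-window GC targets for one chromosome
gc_targets <- function(n_win, cfg) {
  g <- if (cfg$gc_profile == "sinusoidal") {
    0.4 + 0.3 * sin(2 * pi * seq_len(n_win) / 20)
  } else {
    out <- numeric(n_win)
    i <- 1L
    while (i <= n_win) {
      len <- 1L + stats::rgeom(1, 1 / 5)         # mean 5-window blocks
      level <- if (stats::runif(1) < 0.65) {
        stats::rnorm(1, 0.30, 0.05)              # AT-rich majority
      } else {
        stats::rnorm(1, 0.55, 0.05)              # GC-rich minority
      }
      out[i:min(n_win, i + len - 1L)] <- level
      i <- i + len
    }
    out
  }
  pmin(pmax(g, cfg$gc_range[1]), cfg$gc_range[2])
}

#' Simulate a toy genome with a GC-coupled recombination landscape
#'
#' Draws, per window, a target GC value from the configured landscape and
#' a true recombination rate `max(0, a + b * gc + noise)`; samples bases
#' accordingly; plants microsatellite tracts; places non-overlapping gene
#' models. Everything is recorded in a per-window truth table and
#' per-element tables so downstream estimates can be checked against
#' the generating values.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `truth` (per-window tibble: window key, `gc_target`, `true_rate`),
#'   `genes` (tibble as [read_genes()] returns), `microsats`
#'   (tibble `chromosome`, `start`, `end`, `unit`; 0-based half-open)
#'   and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "recmap_sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  windows <- tile_genome(stats::setNames(rep(cfg$chrom_length,
                                             cfg$n_chromosomes), chroms),
                         cfg$window_size)
  truth <- windows
  truth$gc_target <- NA_real_
  truth$true_rate <- NA_real_

  seqs <- character(cfg$n_chromosomes)
  bases <- c("A", "C", "G", "T")
  for (ci in seq_along(chroms)) {
    wi <- which(windows$chromosome == chroms[ci])
    g <- gc_targets(length(wi), cfg)
    truth$gc_target[wi] <- g
    truth$true_rate[wi] <- pmax(
      0, cfg$rate_intercept + cfg$rate_slope * g +
        stats::rnorm(length(wi), 0, cfg$rate_noise_sd))
    win_len <- windows$end[wi] - windows$start[wi]
    if (cfg$markov_order == 0) {
      # vectorized i.i.d. draw: GC-vs-AT per position, then 50/50 within
      p_gc <- rep(g, win_len)
      is_gc <- stats::runif(length(p_gc)) < p_gc
      second <- stats::runif(length(p_gc)) < 0.5
      # lookup: (AT, second)->A, (AT, first)->T, (GC, second)->C, (GC, first)->G
      idx <- c(1L, 4L, 2L, 3L)[1L + 2L * is_gc + !second]
      codes <- as.raw(utf8ToInt("ACGT"))
      seqs[ci] <- rawToChar(codes[idx])
    } else {
      chunk <- purrr::map2(g, win_len, function(gc, len) markov_bases(len, gc))
      seqs[ci] <- paste(unlist(chunk), collapse = "")
    }
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))

  microsats <- plant_microsats(genome, cfg)
  genome <- microsats$genome
  genes <- place_genes(cfg, chroms)

  list(genome = genome, truth = truth, genes = genes,
       microsats = microsats$table, config = cfg)
}

# first-order chain with CpG depletion (transition C->G damped 4x)
markov_bases <- function(len, gc) {
  bases <- c("A", "C", "G", "T")
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  P <- rbind(p0, p0, p0, p0)
  P[2, 3] <- P[2, 3] / 4                         # deplete CpG
  P <- P / rowSums(P)
  out <- integer(len)
  out[1] <- sample.int(4, 1, prob = p0)
  for (i in seq_len(len - 1)) {
    out[i + 1] <- sample.int(4, 1, prob = P[out[i], ])
  }
  bases[out]
}

plant_microsats <- function(genome, cfg) {
  units <- c("A", "AT", "AG", "AC", "AAT", "AGAT", "AAAT", "ACAG")
  rows <- list()
  for (chrom in names(genome)) {
    len <- Biostrings::width(genome[chrom])
    n <- stats::rpois(1, cfg$microsat_density * len / 1e6)
    if (n == 0) next
    for (i in seq_len(n)) {
      unit <- sample(units, 1)
      copies <- sample(4:12, 1)
      tract <- strrep(unit, copies)
      tlen <- nchar(tract)
      pos <- sample.int(len - tlen, 1)            # 0-based start
      Biostrings::subseq(genome[[chrom]], pos + 1L, pos + tlen) <-
        Biostrings::DNAString(tract)
      rows[[length(rows) + 1L]] <- tibble(
        chromosome = chrom, start = pos, end = pos + tlen, unit = unit)
    }
  }
  table <- purrr::list_rbind(rows) %||%
    tibble(chromosome = character(), start = integer(),
           end = integer(), unit = character())
  list(genome = genome, table = dplyr::arrange(table, .data$chromosome,
                                               .data$start))
}

place_genes <- function(cfg, chroms) {
  rows <- list()
  for (chrom in chroms) {
    n <- stats::rpois(1, cfg$gene_density * cfg$chrom_length / 1e6)
    if (n == 0) next
    sizes <- pmax(300, round(stats::rlnorm(n, log(3000), 0.6)))
    total <- sum(sizes)
    gap_budget <- max(cfg$chrom_length - total, n + 1)
    gaps <- stats::rmultinom(1, gap_budget, rep(1, n + 1))[, 1]
    starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, sizes[-n]))
    ok <- starts + sizes <= cfg$chrom_length
    starts <- starts[ok]; sizes <- sizes[ok]
    for (i in seq_along(starts)) {
      n_ex <- 1L + stats::rpois(1, 2)
      cuts <- sort(sample.int(sizes[i] - 1, min(2 * (n_ex - 1), sizes[i] - 1)))
      cuts <- cuts[seq_len(length(cuts) - (length(cuts) %% 2))]
      bounds <- c(0, cuts, sizes[i])
      ex <- matrix(bounds, ncol = 2, byrow = TRUE)
      exons <- tibble(start = starts[i] + ex[, 1], end = starts[i] + ex[, 2])
      exons <- exons[exons$end > exons$start, ]
      introns <- if (nrow(exons) > 1) {
        tibble(start = exons$end[-nrow(exons)], end = exons$start[-1])
      } else {
        tibble(start = integer(), end = integer())
      }
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = paste0("g_", chrom, "_", i), chromosome = chrom,
        start = starts[i], end = starts[i] + sizes[i],
        n_exons = nrow(exons), exons = list(exons), introns = list(introns))
    }
  }
  purrr::list_rbind(rows) %||%
    tibble(gene_id = character(), chromosome = character(),
           start = integer(), end = integer(), n_exons = integer(),
           exons = list(), introns = list())
}

#' Simulate one linkage map over a simulated genome
#'
#' Marker physical positions follow a Poisson process with the requested
#' mean spacing (with anchor markers at the first and last base of each
#' chromosome by default). The genetic position of a marker is the
#' cumulative integral, over physical distance, of the map-specific rate
#' `max(0, true_rate + noise)` (noise per window, sd `noise_sd`), in cM.
#' A fraction of markers can have their physical positions swapped with
#' their right neighbour to create genetic-vs-physical order conflicts
#' for testing the conflict screen.
#'
#' @param sim Output of [simulate_genome()].
#' @param map_id Map identifier.
#' @param spacing Mean marker spacing in bp.
#' @param noise_sd Map-level rate noise sd (cM/Mb).
#' @param frac_shuffled Fraction of markers to displace (default 0).
#' @param seed Integer seed for this map (defaults to a value derived
#'   from the simulation seed and `map_id`).
#' @param anchor Place markers at chromosome ends (default TRUE).
#' @return A map tibble as returned by [read_map()].
#' @export
simulate_map <- function(sim, map_id, spacing, noise_sd = 0,
                         frac_shuffled = 0, seed = NULL, anchor = TRUE) {
  if (is.null(seed)) {
    seed <- (sim$config$seed + 7919L * (sum(utf8ToInt(map_id)) %% 1000L)) %%
      .Machine$integer.max
  }
  withr::with_seed(seed, {
    truth <- sim$truth
    rows <- list()
    for (chrom in unique(truth$chromosome)) {
      tw <- truth[truth$chromosome == chrom, ]
      len <- max(tw$end)
      rate_m <- pmax(0, tw$true_rate + stats::rnorm(nrow(tw), 0, noise_sd))
      # cumulative cM at window boundaries
      cum <- c(0, cumsum(rate_m * (tw$end - tw$start) / 1e6))
      gpos_of <- function(p0) {
        # p0: 0-based physical coordinate
        w <- findInterval(p0, tw$start)
        cum[w] + rate_m[w] * (p0 - tw$start[w]) / 1e6
      }
      gaps <- stats::rexp(ceiling(3 * len / spacing) + 10, 1 / spacing)
      pos <- cumsum(gaps)
      pos <- unique(round(pos[pos < len - 1]))
      if (anchor) pos <- unique(c(0, pos, len - 1))
      pos <- sort(pos)
      if (length(pos) < 2) next
      gpos <- gpos_of(pos)
      phys <- pos + 1L                            # to 1-based bp
      # neighbour swaps to create order conflicts
      n_swap <- round(frac_shuffled * length(pos))
      if (n_swap > 0) {
        avail <- seq_len(length(pos) - 1)
        chosen <- integer(0)
        while (length(chosen) < n_swap && length(avail) > 0) {
          pick <- if (length(avail) == 1) avail else sample(avail, 1)
          chosen <- c(chosen, pick)
          avail <- setdiff(avail, (pick - 1):(pick + 1))
        }
        for (i in chosen) phys[c(i, i + 1)] <- phys[c(i + 1, i)]
      }
      rows[[length(rows) + 1L]] <- tibble(
        map_id = map_id,
        marker = paste0(map_id, "_", chrom, "_", seq_along(pos)),
        chromosome = chrom,
        genetic_cM = gpos,
        physical_bp = as.integer(phys))
    }
    dplyr::arrange(purrr::list_rbind(rows), .data$chromosome,
                   .data$genetic_cM)
  })
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_genome()] and [simulate_map()] for every configured map
#' and, optionally, writes the whole bundle to a directory as the file
#' formats the pipeline consumes: `genome.fa`, `genes.gff3`,
#' `map_<id>.tsv` and `truth.tsv`.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory (created if needed).
#' @return The [simulate_genome()] list, with a `maps` element (named
#'   list of map tibbles) and, when written, a `paths` element.
#' @export
simulate_study <- function(config, dir = NULL) {
  sim <- simulate_genome(config)
  sim$maps <- purrr::pmap(config$maps, function(map_id, spacing, noise_sd,
                                                frac_shuffled, ...) {
    simulate_map(sim, map_id, spacing, noise_sd, frac_shuffled)
  })
  names(sim$maps) <- config$maps$map_id
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "genome.fa"),
      gff = file.path(dir, "genes.gff3"),
      truth = file.path(dir, "truth.tsv"),
      maps = stats::setNames(
        file.path(dir, paste0("map_", names(sim$maps), ".tsv")),
        names(sim$maps))
    )
    Biostrings::writeXStringSet(sim$genome, paths$fasta)
    write_genes_gff3(sim$genes, paths$gff)
    readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
    purrr::walk2(sim$maps, paths$maps, write_map)
    sim$paths <- paths
  }
  sim
}

# minimal GFF3 writer for simulated gene models (gene/mRNA/exon)
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
      sprintf("%s\trecmapr\tgene\t%d\t%d\t.\t+\t.\tID=%s",
              g$chromosome, g$start + 1L, g$end, g$gene_id),
      sprintf("%s\trecmapr\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
              g$chromosome, g$start + 1L, g$end, g$gene_id, g$gene_id))
    ex <- g$exons[[1]]
    if (nrow(ex) > 0) {
      lines <- c(lines, sprintf(
        "%s\trecmapr\texon\t%d\t%d\t.\t+\t.\tParent=%s.t1",
        g$chromosome, ex$start + 1L, ex$end, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
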