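test_that("a null rate model yields a constant landscape", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 5e5,
                    rate_slope = 0, rate_noise_sd = 0)
  sim <- simulate_genome(cfg)
  expect_equal(sim$truth$true_rate, rep(cfg$rate_intercept, nrow(sim$truth)))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, n_chromosomes = 1, chrom_length = 3e5)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_map(s1, "m", spacing = 5e4, noise_sd = 0.3)
  m2 <- simulate_map(s2, "m", spacing = 5e4, noise_sd = 0.3)
  expect_identical(m1, m2)
})

test_that("realized window GC tracks the target within binomial bounds", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chrom_length = 1e6)
  sim <- simulate_genome(cfg)
  w <- sim$truth
  seqs <- substring(as.character(sim$genome[["chr1"]]),
                    w$start + 1, w$end)
  realized <- gc_content(seqs)
  len <- w$end - w$start
  # planted microsatellites perturb a few windows slightly; allow 4 sd
  sd_bin <- sqrt(w$gc_target * (1 - w$gc_target) / len)
  expect_true(all(abs(realized - w$gc_target) < 4 * sd_bin + 0.02))
})

test_that("map genetic length equals the rate integral when noise-free", {
  cfg <- sim_config(seed = 3, n_chromosomes = 2, chrom_length = 8e5)
  sim <- simulate_genome(cfg)
  map <- simulate_map(sim, "m", spacing = 1e5, noise_sd = 0)
  for (ch in unique(map$chromosome)) {
    tw <- sim$truth[sim$truth$chromosome == ch, ]
    expected <- sum(tw$true_rate * (tw$end - tw$start)) / 1e6
    got <- diff(range(map$genetic_cM[map$chromosome == ch]))
    # anchors sit at the first and last base, one bp short of full cover
    expect_equal(got, expected, tolerance = 1e-4)
  }
})

test_that("shuffled markers are recovered by the conflict screen", {
  cfg <- sim_config(seed = 4, n_chromosomes = 1, chrom_length = 5e6)
  sim <- simulate_genome(cfg)
  map <- simulate_map(sim, "m", spacing = 25000, noise_sd = 0,
                      frac_shuffled = 0.05)
  n <- nrow(map)
  conf <- find_order_conflicts(map)
  expected <- round(0.05 * n)
  # one removal per adjacent swap; binomial-ish tolerance around that
  expect_gte(length(conf), ceiling(expected * 0.5))
  expect_lte(length(conf), ceiling(expected * 1.5))
})

test_that("the study bundle writes re-loadable files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 3e5,
                    maps = tibble::tibble(map_id = c("a", "b"),
                                          spacing = 5e4, noise_sd = 0.2,
                                          frac_shuffled = 0))
  sim <- simulate_study(cfg, dir = dir)
  expect_true(file.exists(sim$paths$fasta))
  expect_true(all(file.exists(sim$paths$maps)))
  genome <- Biostrings::readDNAStringSet(sim$paths$fasta)
  expect_identical(as.character(genome), as.character(sim$genome))
  mp <- read_map(sim$paths$maps[["a"]], "a")
  expect_equal(nrow(mp), nrow(sim$maps$a))
  genes <- read_genes(sim$paths$gff)
  expect_equal(nrow(genes), nrow(sim$genes))
  expect_equal(genes$start, sim$genes$start)
})

test_that("planted microsatellites are found by the detector", {
  cfg <- sim_config(seed = 6, n_chromosomes = 1, chrom_length = 4e5,
                    microsat_density = 30)
  sim <- simulate_genome(cfg)
  s <- as.character(sim$genome[["chr1"]])
  calls <- find_microsatellites(s)
  planted <- sim$microsats
  # every sufficiently long planted tract (>= 12 bp) overlaps a call
  long <- planted[planted$end - planted$start >= 12, ]
  hit <- vapply(seq_len(nrow(long)), function(i) {
    any(calls$start <= long$end[i] & calls$end >= long$start[i] + 1)
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})

test_that("config validation catches bad parameters", {
  expect_error(sim_config(), class = "recmapr_parameter_error")
  expect_error(sim_config(seed = 1, gc_range = c(0.5, 0.2)),
               class = "recmapr_parameter_error")
  expect_error(sim_config(seed = 1, maps = tibble::tibble(
    map_id = "a", spacing = 1, noise_sd = 0, frac_shuffled = 0)),
    class = "recmapr_parameter_error")
})
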