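test_that("tile_genome tiles chromosomes without gaps or overlaps", {
  w <- tile_genome(c(chr1 = 250000), window_size = 100000)
  expect_equal(w$start, c(0, 100000, 200000))
  expect_equal(w$end, c(100000, 200000, 250000))
  expect_equal(w$is_partial, c(FALSE, FALSE, TRUE))

  expect_equal(nrow(tile_genome(c(chr1 = 100000))), 1)
  expect_equal(nrow(tile_genome(c(chr1 = 0))), 0)
  expect_error(tile_genome(c(chr1 = 10), window_size = 0),
               class = "recmapr_parameter_error")
})

test_that("window rate is the coverage-weighted mean of interval rates", {
  w <- tile_genome(c(chr1 = 100000))
  iv <- tibble::tibble(
    map_id = "m", chromosome = "chr1",
    start = c(0, 60000), end = c(60000, 100000),
    genetic_cM = c(0.6, 0.8), rate = c(10, 20))
  rp <- window_rates(w, iv)
  expect_equal(rp$rate, (60000 * 10 + 40000 * 20) / 100000)  # 14 cM/Mb

  # a single interval covering the window fully reproduces its rate
  one <- iv[1, ]; one$end <- 100000
  expect_equal(window_rates(w, one)$rate, 10)
})

test_that("zero-rate coverage yields missing, not zero", {
  w <- tile_genome(c(chr1 = 100000))
  iv <- tibble::tibble(map_id = "m", chromosome = "chr1",
                       start = 0, end = 100000, genetic_cM = 0, rate = 0)
  expect_true(is.na(window_rates(w, iv)$rate))
  # and an uncovered window is missing too
  none <- iv[0, ]
  expect_true(is.na(window_rates(w, none)$rate))
})

test_that("overlapping intervals within one map are rejected", {
  w <- tile_genome(c(chr1 = 100000))
  iv <- tibble::tibble(map_id = "m", chromosome = "chr1",
                       start = c(0, 40000), end = c(60000, 90000),
                       genetic_cM = 1, rate = c(5, 5))
  expect_error(window_rates(w, iv), class = "recmapr_input_error")
})

test_that("window rates are bounded by surviving interval rates and conserve mass", {
  withr::with_seed(4, {
    for (trial in 1:10) {
      len <- 1e6
      w <- tile_genome(c(chr1 = len), window_size = 1e5)
      bounds <- sort(sample.int(len - 1, 15))
      starts <- c(0, bounds)
      ends <- c(bounds, len)
      rates <- round(runif(16, 0, 30), 2)
      iv <- tibble::tibble(map_id = "m", chromosome = "chr1",
                           start = starts, end = ends,
                           genetic_cM = rates * (ends - starts) / 1e6,
                           rate = rates)
      rp <- window_rates(w, iv)
      surv <- iv[iv$rate != 0, ]
      expect_true(all(rp$rate >= min(surv$rate) - 1e-12, na.rm = TRUE))
      expect_true(all(rp$rate <= max(surv$rate) + 1e-12, na.rm = TRUE))

      # weight mass: per-window coverage sums back to interval lengths
      total_cov <- sum(vapply(seq_len(nrow(w)), function(i) {
        ov <- pmin(w$end[i], surv$end) - pmax(w$start[i], surv$start)
        sum(pmax(0, ov))
      }, numeric(1)))
      expect_equal(total_cov, sum(surv$end - surv$start))
    }
  })
})

test_that("doubling the window size gives coverage-weighted means of halves", {
  withr::with_seed(5, {
    len <- 8e5
    bounds <- sort(sample.int(len - 1, 11))
    starts <- c(0, bounds); ends <- c(bounds, len)
    rates <- round(runif(12, 0.5, 20), 2)
    iv <- tibble::tibble(map_id = "m", chromosome = "chr1",
                         start = starts, end = ends,
                         genetic_cM = rates * (ends - starts) / 1e6,
                         rate = rates)
    small <- window_rates(tile_genome(c(chr1 = len), 1e5), iv)
    big <- window_rates(tile_genome(c(chr1 = len), 2e5), iv)
    cov_of <- function(s, e) {
      sum(pmax(0, pmin(e, iv$end) - pmax(s, iv$start)))
    }
    for (i in seq_len(nrow(big))) {
      halves <- which(small$start >= big$start[i] & small$end <= big$end[i])
      covs <- vapply(halves, function(h) cov_of(small$start[h], small$end[h]),
                     numeric(1))
      expect_equal(big$rate[i],
                   sum(covs * small$rate[halves]) / sum(covs))
    }
  })
})

test_that("cross-map summary computes mean and sample variance with thresholds", {
  w <- tile_genome(c(chr1 = 100000))
  prof <- function(r, id) { p <- w; p$map_id <- id; p$rate <- r; p }
  s <- summarize_across_maps(list(prof(10, "a"), prof(20, "b")))
  expect_equal(s$mean_rate, 15)
  expect_equal(s$var_rate, 50)

  # a single contributing map: mean present, variance missing
  s1 <- summarize_across_maps(list(prof(7, "a"), prof(NA_real_, "b")),
                              min_maps = 1)
  expect_equal(s1$mean_rate, 7)
  expect_true(is.na(s1$var_rate))

  s3 <- summarize_across_maps(list(prof(5, "a"), prof(5, "b"), prof(5, "c")))
  expect_equal(s3$mean_rate, 5)
  expect_equal(s3$var_rate, 0)

  expect_error(summarize_across_maps(list()),
               class = "recmapr_parameter_error")
})

test_that("identical profiles give zero variance everywhere", {
  withr::with_seed(6, {
    w <- tile_genome(c(chr1 = 5e5))
    p <- w; p$map_id <- "a"; p$rate <- runif(nrow(w), 1, 30)
    p2 <- p; p2$map_id <- "b"
    s <- summarize_across_maps(list(p, p2))
    expect_equal(s$var_rate, rep(0, nrow(w)))
    expect_equal(s$mean_rate, p$rate)
  })
})
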