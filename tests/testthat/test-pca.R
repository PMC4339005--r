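kmer_table <- function(M, resp) {
  # wrap a numeric matrix as a k-mer frequency table (k inferred from cols)
  k <- round(log(ncol(M), 4))
  motifs <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                   stringsAsFactors = FALSE),
                       1, function(r) paste(rev(r), collapse = "")))
  d <- tibble::as_tibble(as.data.frame(M))
  names(d) <- motifs[seq_len(ncol(M))]
  d$effective_len <- 1L
  d$resp <- resp
  d
}

test_that("two perfectly correlated columns collapse onto PC1", {
  withr::with_seed(21, {
    x <- rnorm(40)
    M <- cbind(x, 2 * x, matrix(0, 40, 14))
    M <- M[, 1:2]
    d <- tibble::tibble(AA = M[, 1], AC = M[, 2], effective_len = 1L,
                        resp = rnorm(40))
    fit <- pca_kmers(d, resp, k = 2, n_pcs = 1, normalize = FALSE)
    expect_equal(fit$variance_explained[1], 1)
  })
})

test_that("isotropic noise spreads variance evenly over components", {
  withr::with_seed(22, {
    M <- matrix(rnorm(2000 * 16), 2000, 16)
    d <- kmer_table(M, rnorm(2000))
    fit <- pca_kmers(d, resp, k = 2, normalize = FALSE)
    expect_equal(fit$variance_explained,
                 rep(1 / 16, 16), tolerance = 0.15)
    expect_equal(sum(fit$variance_explained), 1)
  })
})

test_that("a response planted along PC1 is recovered, PC2 beta near zero", {
  withr::with_seed(23, {
    n <- 400
    latent <- rnorm(n)
    M <- outer(latent, runif(16, 0.5, 1)) + matrix(rnorm(n * 16, sd = 0.3),
                                                   n, 16)
    resp <- latent + rnorm(n, sd = 0.3)
    d <- kmer_table(M, resp)
    fit <- pca_kmers(d, resp, k = 2, normalize = FALSE)
    betas <- tidy(fit)
    expect_gt(abs(betas$beta[1]), 0.8)
    expect_lt(betas$p[1], 1e-6)
    expect_lt(abs(betas$beta[2]), 0.15)
    # sign convention makes PC1 positively loaded, hence beta positive here
    expect_gt(betas$beta[1], 0)
  })
})

test_that("loadings are orthonormal and scores reproduce standardized data", {
  withr::with_seed(24, {
    M <- matrix(rnorm(200 * 16), 200, 16) +
      outer(rnorm(200), rep(1, 16))
    d <- kmer_table(M, rnorm(200))
    fit <- pca_kmers(d, resp, k = 2, normalize = FALSE)
    L <- fit$loadings
    expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(fit$variance_explained), 1, tolerance = 1e-12)
    # full back-projection: scores %*% t(loadings) = standardized input
    Z <- scale(M)
    S <- as.matrix(stats::prcomp(M, center = TRUE, scale. = TRUE)$x)
    expect_equal(S %*% t(stats::prcomp(M, center = TRUE,
                                       scale. = TRUE)$rotation),
                 Z, tolerance = 1e-8, ignore_attr = TRUE)
    # and the sign convention holds for every component
    expect_true(all(colSums(L) >= 0))
  })
})

test_that("count normalization uses effective length", {
  withr::with_seed(25, {
    n <- 50
    counts <- matrix(rpois(n * 16, 40), n, 16)
    d <- kmer_table(counts, rnorm(n))
    d$effective_len <- sample(500:1000, n, replace = TRUE)
    fit_norm <- pca_kmers(d, resp, k = 2, normalize = TRUE)
    d2 <- d
    kcols <- grep("^[ACGT]{2}$", names(d2))
    d2[kcols] <- lapply(d2[kcols], function(x) x / d2$effective_len)
    fit_pre <- pca_kmers(d2, resp, k = 2, normalize = FALSE)
    expect_equal(fit_norm$variance_explained, fit_pre$variance_explained)
    expect_equal(tidy(fit_norm), tidy(fit_pre))
  })
})

test_that("too few windows for the requested components is an error", {
  d <- kmer_table(matrix(rnorm(2 * 16), 2, 16), rnorm(2))
  expect_error(pca_kmers(d, resp, k = 2, n_pcs = 2, normalize = FALSE),
               class = "recmapr_parameter_error")
})
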