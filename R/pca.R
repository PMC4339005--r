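#' PCA of k-mer composition with PC-vs-rate regression
#'
#' The exhaustive k-mer columns of one length are strongly collinear
#' (their counts share the underlying base composition), so they are
#' summarised by principal components before being related to
#' recombination rate. Counts are converted to per-bp frequencies
#' (`count / effective_len`), standardized, and decomposed via the
#' correlation matrix (`prcomp` with scaling). The standardized response
#' is then regressed jointly on the leading `n_pcs` standardized PC
#' scores, giving a standardized beta and p-value per component.
#'
#' The sign of each component is fixed so that its loading vector sums to
#' a positive value, making betas reproducible across runs and linear
#' algebra backends.
#'
#' @param data Per-window tibble holding the k-mer count columns,
#'   `effective_len` and the response ([featurize_windows()] output joined
#'   with a rate summary).
#' @param response Response column (bare name or string).
#' @param k Motif length whose `4^k` columns are decomposed.
#' @param n_pcs Number of leading components regressed against the
#'   response (default 2); the full spectrum is always retained in the
#'   result.
#' @param normalize Divide counts by `effective_len` first (default TRUE;
#'   set FALSE if the columns already are frequencies).
#' @return An object of class `recmap_pca` with `loadings` (motif x PC),
#'   `scores` (window x PC, with window keys), `variance_explained`,
#'   `pc_betas` (tibble `component`, `beta`, `p`), `k`, `n_pcs`, `n`.
#' @export
pca_kmers <- function(data, response, k, n_pcs = 2, normalize = TRUE) {
  response <- resolve_col(data, rlang::enquo(response))
  cols <- grep(paste0("^[ACGT]{", k, "}$"), names(data), value = TRUE)
  if (length(cols) == 0) {
    abort(paste0("no k-mer columns of length ", k, " in data"),
          class = "recmapr_input_error")
  }
  M <- as.matrix(data[cols])
  if (normalize) {
    if (!"effective_len" %in% names(data)) {
      abort("effective_len column required to normalize k-mer counts",
            class = "recmapr_input_error")
    }
    M <- M / data$effective_len
  }
  y <- data[[response]]
  cc <- stats::complete.cases(M, y) & apply(is.finite(M), 1, all)
  M <- M[cc, , drop = FALSE]
  y <- y[cc]
  if (nrow(M) <= n_pcs) {
    abort(paste0("fewer complete windows (", nrow(M),
                 ") than components requested (", n_pcs, ")"),
          class = "recmapr_parameter_error")
  }
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0),
                " constant k-mer column(s) before PCA"))
    M <- M[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  # sign convention: positive loading sum per component
  flip <- colSums(pc$rotation) < 0
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  scores_std <- scale(pc$x[, seq_len(n_pcs), drop = FALSE])
  fit <- stats::lm(scale(y) ~ scores_std)
  coefs <- summary(fit)$coefficients
  pc_betas <- tibble(
    component = paste0("PC", seq_len(n_pcs)),
    beta = unname(coefs[-1, 1]),
    p = unname(coefs[-1, 4])
  )
  keys <- intersect(c(window_key(), "index"), names(data))
  scores <- dplyr::bind_cols(
    data[cc, keys, drop = FALSE],
    as_tibble(pc$x[, seq_len(min(ncol(pc$x), max(n_pcs, 2))), drop = FALSE])
  )
  scores$.response <- y
  structure(
    list(loadings = pc$rotation, scores = scores, variance_explained = ve,
         pc_betas = pc_betas, k = k, n_pcs = n_pcs, n = nrow(M),
         response = response, model = fit),
    class = "recmap_pca"
  )
}

#' @export
print.recmap_pca <- function(x, ...) {
  cat("PCA of ", 4^x$k, " ", x$k, "-mer frequency columns over ", x$n,
      " windows\n", sep = "")
  cat("Variance explained by PC1..PC", x$n_pcs, ": ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(x$n_pcs)]),
            collapse = ", "), "\n", sep = "")
  print(x$pc_betas)
  invisible(x)
}

#' Tidy a k-mer PCA
#'
#' @param x A `recmap_pca` object.
#' @param matrix One of `"betas"` (PC-vs-rate regression, default),
#'   `"loadings"`, `"scores"` or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble of the requested quantity.
#' @method tidy recmap_pca
#' @export
tidy.recmap_pca <- function(x, matrix = c("betas", "loadings", "scores",
                                          "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    betas = x$pc_betas,
    loadings = dplyr::bind_cols(tibble(motif = rownames(x$loadings)),
                                as_tibble(x$loadings)),
    scores = x$scores,
    eigenvalues = tibble(
      component = paste0("PC", seq_along(x$variance_explained)),
      variance_explained = x$variance_explained,
      cumulative = cumsum(x$variance_explained))
  )
}

#' One-row summary of a k-mer PCA
#'
#' @param x A `recmap_pca` object.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `n_pcs` and the variance explained by
#'   the retained components (jointly and per component).
#' @method glance recmap_pca
#' @export
glance.recmap_pca <- function(x, ...) {
  tibble(
    k = x$k, n = x$n, n_pcs = x$n_pcs,
    var_explained_retained = sum(x$variance_explained[seq_len(x$n_pcs)]),
    var_explained_pc1 = x$variance_explained[1],
    var_explained_pc2 = if (length(x$variance_explained) > 1)
      x$variance_explained[2] else NA_real_
  )
}
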