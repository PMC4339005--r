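#' Feature-vs-rate bivariate correlations with FDR correction
#'
#' Correlates every feature column with a response column over
#' pairwise-complete windows and adjusts p-values by Benjamini-Hochberg
#' within FDR families. By default the exhaustive k-mer columns of each
#' length form their own family (`kmer2`, `kmer3`, `kmer4`) -- matching
#' their separate downstream reporting -- and all remaining features form
#' one `general` family. Constant features (or fewer than 3 complete
#' pairs) yield `NA` and are excluded from their family's adjustment.
#'
#' @param data A per-window tibble holding feature and response columns
#'   (typically [featurize_windows()] output joined with a rate profile
#'   or [summarize_across_maps()] summary, k-mer columns normalised via
#'   [normalize_kmer_columns()]).
#' @param response The response column (bare name or string), e.g.
#'   `mean_rate`.
#' @param features Character vector of feature columns; default: every
#'   numeric column except the response, window bookkeeping
#'   (`start`, `end`, `index`, `effective_len`, ...) and other rate
#'   summary columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param families Optional named character vector mapping feature ->
#'   family; defaults as described above.
#' @return A tibble with columns `feature`, `family`, `r`, `p`, `q`, `n`,
#'   sorted by `p` within family.
#' @export
correlate <- function(data, response, features = NULL,
                      method = c("pearson", "spearman"), families = NULL) {
  method <- match.arg(method)
  response <- resolve_col(data, rlang::enquo(response))
  if (is.null(features)) {
    bookkeeping <- c(window_key(), "index", "is_partial", "effective_len",
                     "map_id", "n_maps", "mean_rate", "var_rate", "rate",
                     response)
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        bookkeeping)
  }
  if (is.null(families)) {
    families <- stats::setNames(ifelse(
      grepl("^[ACGT]+$", features),
      paste0("kmer", nchar(features)), "general"), features)
  }
  y <- data[[response]]
  res <- purrr::map(features, function(f) {
    x <- data[[f]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble(feature = f, family = unname(families[f]),
                    r = NA_real_, p = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    tibble(feature = f, family = unname(families[f]),
           r = unname(ct$estimate), p = ct$p.value, n = n)
  }) |>
    purrr::list_rbind()
  res <- dplyr::group_by(res, .data$family)
  res <- dplyr::mutate(res, q = stats::p.adjust(.data$p, method = "BH"))
  res <- dplyr::ungroup(res)
  dplyr::arrange(res[c("feature", "family", "r", "p", "q", "n")],
                 .data$family, .data$p)
}

# accept bare column names or strings
resolve_col <- function(data, quo) {
  expr <- rlang::quo_get_expr(quo)
  nm <- if (rlang::is_string(expr) || rlang::is_character(expr)) {
    as.character(expr)
  } else {
    rlang::as_name(quo)
  }
  if (!nm %in% names(data)) {
    abort(paste0("column not found: ", nm), class = "recmapr_input_error")
  }
  nm
}

#' Rank motifs by correlation strength
#'
#' Ranks motifs by the absolute value of their correlation with a chosen
#' response, optionally placing the per-response ranks from several
#' analyses side by side (the classic multi-map comparison table). Ties
#' share the minimum rank.
#'
#' @param correlations A correlation tibble from [correlate()], or a named
#'   list of them (one per response/map); the first element orders the
#'   table.
#' @param top_n Keep the strongest `top_n` motifs (default all).
#' @return A tibble `feature`, then `r_<name>` and `rank_<name>` per
#'   input (or plain `r`, `rank` for a single input).
#' @export
rank_motifs <- function(correlations, top_n = Inf) {
  single <- is.data.frame(correlations)
  if (single) correlations <- list(r = correlations)
  if (is.null(names(correlations)) || any(names(correlations) == "")) {
    names(correlations) <- paste0("set", seq_along(correlations))
  }
  tabs <- purrr::imap(correlations, function(tb, nm) {
    tb <- tb[!is.na(tb$r), c("feature", "r")]
    tb$rank <- rank(-abs(tb$r), ties.method = "min")
    names(tb)[2:3] <- if (single) c("r", "rank") else
      paste0(c("r_", "rank_"), nm)
    tb
  })
  out <- purrr::reduce(tabs, dplyr::full_join, by = "feature")
  ord_col <- names(out)[3]
  out <- out[order(out[[ord_col]]), ]
  utils::head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}
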