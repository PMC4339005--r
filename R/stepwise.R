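#' Backward stepwise regression on standardized predictors
#'
#' Fits a full linear model of the standardized response on standardized
#' predictors (so coefficients are standardized betas), then iteratively
#' removes the predictor with the largest p-value while that p-value is
#' at or above `p_remove` (default 0.05), refitting after each removal.
#' Ties in p are broken by removing the predictor later in the supplied
#' column order, which makes the elimination path deterministic.
#' Exactly collinear columns (including constants) are dropped with a
#' warning before fitting.
#'
#' @param data Per-window tibble of features and response.
#' @param response Response column (bare name or string).
#' @param features Character vector of predictor columns.
#' @param p_remove Exclusion threshold: a predictor is removed while its
#'   p-value is `>= p_remove`.
#' @return An object of class `recmap_stepwise` with `retained`
#'   (tibble `feature`, `beta`, `p`), `trace` (tibble `step`, `removed`,
#'   `p_at_removal`), the final `model` (or `NULL` when empty), `n`, and
#'   settings. Use [tidy()] / [glance()] to extract tidy summaries.
#'
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100))
#' d$y <- 0.8 * d$x1 + rnorm(100, sd = 0.6)
#' fit <- backward_stepwise(d, y, c("x1", "x2"))
#' tidy(fit)
#' @export
backward_stepwise <- function(data, response, features, p_remove = 0.05) {
  response <- resolve_col(data, rlang::enquo(response))
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0) {
    abort(paste0("feature column(s) not found: ",
                 paste(missing_f, collapse = ", ")),
          class = "recmapr_input_error")
  }
  cc <- stats::complete.cases(data[c(features, response)])
  d <- data[cc, ]
  n <- nrow(d)
  if (n < 10 * length(features)) {
    warn(paste0("only ", n, " complete cases for ", length(features),
                " predictors (< 10 per predictor)"))
  }
  y <- as.numeric(scale(d[[response]]))
  X <- scale(as.matrix(d[features]))

  # drop constants and exactly collinear columns before fitting
  const <- features[apply(X, 2, function(v) !is.finite(stats::sd(v)) ||
                            stats::sd(v) == 0 || anyNA(v))]
  keep <- setdiff(features, const)
  if (length(const) > 0) {
    warn(paste0("dropping constant predictor(s): ",
                paste(const, collapse = ", ")))
    X <- scale(as.matrix(d[keep]))
  }
  if (length(keep) > 1) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      indep <- sort(qrX$pivot[seq_len(qrX$rank)])
      dropped <- keep[-indep]
      warn(paste0("dropping exactly collinear predictor(s): ",
                  paste(dropped, collapse = ", ")))
      keep <- keep[indep]
      X <- X[, keep, drop = FALSE]
    }
  }

  current <- keep
  trace <- list()
  step <- 0L
  model <- NULL
  while (length(current) > 0) {
    df <- data.frame(.y = y, X[, current, drop = FALSE], check.names = FALSE)
    model <- stats::lm(.y ~ ., data = df)
    coefs <- summary(model)$coefficients
    rows <- rownames(coefs)
    pv <- coefs[match(paste0("`", current, "`"), rows), 4]
    pv[is.na(pv)] <- coefs[match(current, rows), 4][is.na(pv)]
    pv[is.na(pv)] <- 1  # aliased coefficient: eliminate first
    worst_p <- max(pv)
    if (worst_p < p_remove) break
    # tie-break: remove the later column (larger index in supplied order)
    cand <- which(pv == worst_p)
    victim <- cand[length(cand)]
    step <- step + 1L
    trace[[step]] <- tibble(step = step, removed = current[victim],
                            p_at_removal = unname(worst_p))
    current <- current[-victim]
    model <- NULL
  }
  if (length(current) > 0 && is.null(model)) {
    df <- data.frame(.y = y, X[, current, drop = FALSE], check.names = FALSE)
    model <- stats::lm(.y ~ ., data = df)
  }
  retained <- if (length(current) > 0) {
    coefs <- summary(model)$coefficients
    rows <- rownames(coefs)
    idx <- match(paste0("`", current, "`"), rows)
    idx[is.na(idx)] <- match(current, rows)[is.na(idx)]
    tibble(feature = current,
           beta = unname(coefs[idx, 1]),
           p = unname(coefs[idx, 4]))
  } else {
    tibble(feature = character(), beta = numeric(), p = numeric())
  }
  structure(
    list(retained = retained,
         trace = purrr::list_rbind(trace) %||%
           tibble(step = integer(), removed = character(),
                  p_at_removal = numeric()),
         model = model, n = n, n_start = length(features),
         dropped_collinear = setdiff(features, c(keep, const)),
         p_remove = p_remove, response = response),
    class = "recmap_stepwise"
  )
}

#' @export
print.recmap_stepwise <- function(x, ...) {
  cat("Backward stepwise regression (p_remove = ", x$p_remove,
      ", n = ", x$n, ")\n", sep = "")
  cat("Started with ", x$n_start, " predictor(s); retained ",
      nrow(x$retained), ":\n", sep = "")
  print(x$retained)
  invisible(x)
}

#' Tidy a stepwise fit
#'
#' @param x A `recmap_stepwise` object.
#' @param ... Unused.
#' @return Tibble of retained predictors with standardized `beta` and `p`.
#' @method tidy recmap_stepwise
#' @export
tidy.recmap_stepwise <- function(x, ...) x$retained

#' One-row model summary of a stepwise fit
#'
#' @param x A `recmap_stepwise` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_start`, `n_retained`, `n_steps`,
#'   `r.squared`, `adj.r.squared`.
#' @method glance recmap_stepwise
#' @export
glance.recmap_stepwise <- function(x, ...) {
  s <- if (!is.null(x$model)) summary(x$model) else NULL
  tibble(
    n = x$n, n_start = x$n_start, n_retained = nrow(x$retained),
    n_steps = nrow(x$trace),
    r.squared = if (is.null(s)) 0 else s$r.squared,
    adj.r.squared = if (is.null(s)) 0 else s$adj.r.squared
  )
}
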