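#' Fixed-marginal null networks and z-score standardization
#'
#' Null networks are random integer matrices with exactly the observed row
#' and column totals, drawn uniformly from the conditional (multiple
#' hypergeometric) distribution on such tables — the encounter-probability
#' expectation for a network whose species keep their observed interaction
#' totals. An index is standardized as
#' `z = (observed - mean(nulls)) / sd(nulls)`; negative z means less
#' nested/overlapping/diverse than expected from abundance alone.
#'
#' @name null-models
NULL

#' Draw one fixed-margin random count matrix (Patefield algorithm)
#'
#' @param row_margins,col_margins positive integer vectors with equal sums.
#' @return integer matrix with exactly the requested margins, sampled from
#'   the uniform conditional distribution over all such tables. Uses the
#'   session RNG; wrap in [withr::with_seed()] or `set.seed()` for
#'   reproducibility.
#' @seealso [patefield_samples()] for many draws,
#'   [shuffle_pairing_sample()] for an independent sampler of the same
#'   distribution.
#' @export
patefield_sample <- function(row_margins, col_margins) {
  patefield_samples(1L, row_margins, col_margins)[[1L]]
}

#' @rdname patefield_sample
#' @param n number of tables to draw.
#' @return for `patefield_samples()`, a list of `n` matrices.
#' @export
patefield_samples <- function(n, row_margins, col_margins) {
  check_margins(row_margins, col_margins)
  if (length(row_margins) == 1L || length(col_margins) == 1L) {
    # a single row or column is fully determined by the margins
    forced <- matrix(as.integer(outer(row_margins, col_margins) / sum(row_margins)),
                     length(row_margins), length(col_margins))
    return(rep(list(forced), n))
  }
  r2dtable(n, as.integer(row_margins), as.integer(col_margins))
}

#' Fixed-margin table by random multiset pairing
#'
#' Independent sampler of the same conditional distribution as
#' [patefield_sample()]: the `S` interaction tokens are laid out as `S` row
#' labels and `S` column labels (each repeated to its margin), the column
#' labels are randomly permuted, and the paired labels are tabulated. Used
#' as a distributional cross-check of the Patefield sampler.
#'
#' @inheritParams patefield_sample
#' @return integer matrix with exactly the requested margins.
#' @export
shuffle_pairing_sample <- function(row_margins, col_margins) {
  check_margins(row_margins, col_margins)
  S <- sum(row_margins)
  rows <- rep(seq_along(row_margins), times = row_margins)
  cols <- rep(seq_along(col_margins), times = col_margins)
  cols <- cols[sample.int(S)]
  m <- unclass(table(factor(rows, levels = seq_along(row_margins)),
                     factor(cols, levels = seq_along(col_margins))))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

check_margins <- function(row_margins, col_margins) {
  stopifnot(length(row_margins) >= 1, length(col_margins) >= 1,
            all(row_margins >= 1), all(col_margins >= 1))
  if (sum(row_margins) != sum(col_margins)) {
    abort_sexnest("row and column margin sums differ", "sexnest_margin_error")
  }
  invisible(TRUE)
}

#' Standardize network indices against fixed-margin nulls
#'
#' Draws one shared set of `n_nulls` Patefield null matrices from the
#' observed matrix's margins and evaluates every requested metric on the
#' observed matrix and on each null, returning each index's observed
#' value, null mean and standard deviation (sample, n-1), and z score.
#' Sharing one null set across metrics is what makes the visitor-level and
#' plant-level partner-diversity z scores coincide exactly.
#'
#' Nulls on which a metric is undefined are excluded from that metric's
#' null distribution and counted in `n_failed` (with a warning). A
#' degenerate null distribution (`sd = 0`), or a metric undefined on the
#' observed matrix itself, yields `z = NA` with `z_defined = FALSE` rather
#' than an infinity or an error.
#'
#' @param m observed count matrix.
#' @param metrics named list of metric functions, or character names
#'   resolved in [metric_registry()]. Default: all registry metrics.
#' @param n_nulls number of null networks (>= 2); the study default is
#'   1000.
#' @param seed integer seed for the null draws; recorded in the output.
#' @return data frame with one row per metric: `metric`, `level`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `z_defined`, `n_nulls`,
#'   `n_failed`, `seed`.
#' @export
standardize_metrics <- function(m, metrics = metric_registry(),
                                n_nulls = 1000L, seed = 1L) {
  stopifnot(n_nulls >= 2)
  if (is.character(metrics)) {
    metrics <- metric_registry()[metrics]
    stopifnot(!anyNA(names(metrics)))
  }
  stopifnot(is.list(metrics), length(metrics) >= 1, !is.null(names(metrics)))
  m <- as_count_matrix(m)
  observed <- vapply(metrics, function(f) {
    tryCatch(as.numeric(f(m)),
             sexnest_undefined_metric = function(e) NA_real_)
  }, numeric(1))
  nulls <- withr::with_seed(seed,
                            patefield_samples(n_nulls, rowSums(m), colSums(m)))
  null_values <- vapply(nulls, function(nm) {
    dimnames(nm) <- dimnames(m)
    vapply(metrics, function(f) {
      tryCatch(as.numeric(f(nm)),
               sexnest_undefined_metric = function(e) NA_real_)
    }, numeric(1))
  }, numeric(length(metrics)))
  null_values <- matrix(null_values, nrow = length(metrics))
  n_failed <- rowSums(is.na(null_values))
  if (any(n_failed > 0)) {
    warning(sprintf("metric undefined on some null draws: %s",
                    paste(sprintf("%s (%d)", names(metrics)[n_failed > 0],
                                  n_failed[n_failed > 0]), collapse = ", ")))
  }
  null_mean <- suppressWarnings(rowMeans(null_values, na.rm = TRUE))
  null_sd <- suppressWarnings(apply(null_values, 1, sd, na.rm = TRUE))
  z_defined <- is.finite(observed) & is.finite(null_sd) & null_sd > 0
  z <- ifelse(z_defined, (observed - null_mean) / null_sd, NA_real_)
  lv <- metric_levels()
  data.frame(
    metric = names(metrics),
    level = ifelse(names(metrics) %in% names(lv), lv[names(metrics)], "network"),
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    z_defined = z_defined,
    n_nulls = as.integer(n_nulls),
    n_failed = as.integer(n_failed),
    seed = as.integer(seed),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname standardize_metrics
#' @param metric a single metric function or registry name.
#' @return for `standardize()`, a one-row data frame.
#' @export
standardize <- function(m, metric, n_nulls = 1000L, seed = 1L) {
  if (is.character(metric)) {
    metrics <- metric_registry()[metric]
  } else {
    metrics <- list(metric = metric)
  }
  standardize_metrics(m, metrics, n_nulls = n_nulls, seed = seed)
}
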