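#' Mixed-model comparisons of standardized indices across network types
#'
#' Network types (species, female, male) are compared with a Gaussian
#' mixed model with a random intercept per network origin; the omnibus
#' fixed effect is tested with a Satterthwaite F. If the omnibus test is
#' significant at `alpha`, all pairwise type contrasts are each refit on
#' the two-type subset and flagged against the Bonferroni-corrected
#' threshold `alpha / n_contrasts`. A singular mixed fit falls back to a
#' deterministic within-origin permutation test (sign flips on
#' origin-matched differences for pairs, exhaustive when feasible), with a
#' warning.
#'
#' @param data data frame with columns `origin`, `network_type`, and the
#'   response named by `response`.
#' @param response name of the numeric response column (a z score).
#' @param alpha omnibus significance level.
#' @param n_perm permutation count for the fallback omnibus test.
#' @param perm_seed seed for non-exhaustive fallback permutations.
#' @return object of class `comparison_result`: list with `response`,
#'   `omnibus` (statistic, df, p, method), `pairwise` data frame
#'   (`contrast`, `statistic`, `p`, `significant`), `correction_threshold`,
#'   `fallback` flag, and `type_means`.
#' @export
compare_index <- function(data, response = "z", alpha = 0.05,
                          n_perm = 4999L, perm_seed = 1L) {
  data <- check_comparison_frame(data, response)
  types <- sort(unique(data$network_type))
  stopifnot(length(types) >= 2, length(unique(data$origin)) >= 2)
  fit <- fit_lmm_type(data, response)
  fallback <- fit$fallback
  omnibus <- fit$test
  pairs <- utils::combn(types, 2, simplify = FALSE)
  threshold <- alpha / length(pairs)
  pairwise <- data.frame(contrast = character(0), statistic = numeric(0),
                         p = numeric(0), significant = logical(0),
                         stringsAsFactors = FALSE)
  if (is.finite(omnibus$p) && omnibus$p < alpha) {
    fits <- lapply(pairs, function(pr) {
      sub <- droplevels(data[data$network_type %in% pr, , drop = FALSE])
      res <- fit_lmm_type(sub, response, pairwise = TRUE,
                          n_perm = n_perm, perm_seed = perm_seed)
      list(row = data.frame(contrast = paste(pr, collapse = "-"),
                            statistic = res$test$statistic, p = res$test$p,
                            significant = is.finite(res$test$p) & res$test$p < threshold,
                            stringsAsFactors = FALSE),
           fallback = res$fallback)
    })
    pairwise <- do.call(rbind, lapply(fits, `[[`, "row"))
    fallback <- fallback || any(vapply(fits, `[[`, logical(1), "fallback"))
  }
  means <- tapply(data[[response]], data$network_type, mean)
  structure(list(response = response,
                 omnibus = omnibus,
                 pairwise = pairwise,
                 correction_threshold = threshold,
                 alpha = alpha,
                 fallback = fallback,
                 type_means = means),
            class = "comparison_result")
}

check_comparison_frame <- function(data, response) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  stopifnot(all(c("origin", "network_type", response) %in% names(data)))
  data$origin <- factor(data$origin)
  data$network_type <- factor(data$network_type)
  stopifnot(all(is.finite(data[[response]])))
  data
}

# Gaussian LMM z ~ type + (1|origin); Satterthwaite F. A singular or failed
# fit falls back to the simpler fixed-effect estimator (OLS with origin as a
# blocking factor, standard F); for a pairwise contrast with complete
# origin pairs the fallback is instead an exhaustive within-origin
# sign-flip permutation test on origin-matched differences, which is fully
# deterministic.
fit_lmm_type <- function(data, response, pairwise = FALSE,
                         n_perm = 4999L, perm_seed = 1L) {
  f <- as.formula(paste(response, "~ network_type + (1 | origin)"))
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(f, data = data,
                                    control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) NULL)
  a <- if (!is.null(fit) && !lme4::isSingular(fit)) {
    tryCatch(suppressMessages(stats::anova(fit)), error = function(e) NULL)
  }
  if (!is.null(a) && is.finite(a[["Pr(>F)"]][1])) {
    return(list(fallback = FALSE,
                test = list(statistic = a[["F value"]][1],
                            df = c(a[["NumDF"]][1], a[["DenDF"]][1]),
                            p = a[["Pr(>F)"]][1],
                            method = "lmm_satterthwaite_F")))
  }
  origins <- split(seq_len(nrow(data)), data$origin)
  if (pairwise && nlevels(data$network_type) == 2 &&
      all(vapply(origins, length, integer(1)) == 2) && length(origins) <= 14) {
    warning("singular or failed mixed fit; using exhaustive sign-flip permutation",
            call. = FALSE)
    return(list(fallback = TRUE,
                test = sign_flip_test(data, response, origins)))
  }
  warning("singular or failed mixed fit; using fixed-effect OLS with origin blocks",
          call. = FALSE)
  fit2 <- lm(as.formula(paste(response, "~ network_type + origin")), data = data)
  a2 <- stats::anova(fit2)
  list(fallback = TRUE,
       test = list(statistic = a2["network_type", "F value"],
                   df = c(a2["network_type", "Df"], a2["Residuals", "Df"]),
                   p = a2["network_type", "Pr(>F)"],
                   method = "ols_origin_blocks_F"))
}

# Exhaustive sign-flip permutation test on origin-matched differences
# between two network types: statistic is the mean difference, reference
# distribution is all 2^n_origins sign assignments.
sign_flip_test <- function(data, response, origins) {
  d <- vapply(origins, function(idx) {
    sub <- data[idx, ]
    sub[[response]][order(sub$network_type)]
  }, numeric(2))
  diffs <- d[1, ] - d[2, ]
  obs <- mean(diffs)
  n <- length(diffs)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- abs(signs %*% diffs) / n
  p <- mean(perm >= abs(obs) - 1e-12)
  list(statistic = obs, df = c(1, n - 1), p = p,
       method = "exhaustive_sign_flip_permutation")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison of '%s' across network types\n", x$response))
  cat(sprintf("  omnibus %s: statistic = %.3f, p = %.4g%s\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p,
              if (isTRUE(x$fallback)) " [fallback]" else ""))
  cat("  type means:", paste(sprintf("%s = %.3f", names(x$type_means),
                                     x$type_means), collapse = ", "), "\n")
  if (nrow(x$pairwise)) {
    cat(sprintf("  pairwise (Bonferroni threshold %.4g):\n",
                x$correction_threshold))
    print(x$pairwise, row.names = FALSE)
  } else {
    cat("  no pairwise contrasts (omnibus not significant)\n")
  }
  invisible(x)
}

#' Compare sex-composition category counts across origins
#'
#' Poisson mixed model for the number of visitor species per sex category
#' (all-female, all-male, both-sex) with a log offset of each origin's
#' visitor species richness and a random intercept per origin. The omnibus
#' category effect is a likelihood-ratio test; pairwise category contrasts
#' are refit on category pairs and Bonferroni-flagged at
#' `alpha / n_contrasts`. Singular fits fall back to a fixed-effect Poisson
#' GLM with origin as a blocking factor (likelihood-ratio tests), with a
#' warning.
#'
#' @param data data frame with columns `origin`, `category`, `count`,
#'   `total` (visitor species richness of the origin).
#' @param alpha omnibus significance level.
#' @return `comparison_result` (response `"sex_composition"`); `type_means`
#'   holds the mean observed proportions per category.
#' @export
compare_sex_composition <- function(data, alpha = 0.05) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  stopifnot(all(c("origin", "category", "count", "total") %in% names(data)))
  data$origin <- factor(data$origin)
  data$category <- factor(data$category)
  stopifnot(nlevels(data$category) >= 2)
  fit <- fit_poisson_category(data)
  cats <- levels(data$category)
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  threshold <- alpha / length(pairs)
  pairwise <- data.frame(contrast = character(0), statistic = numeric(0),
                         p = numeric(0), significant = logical(0),
                         stringsAsFactors = FALSE)
  if (is.finite(fit$test$p) && fit$test$p < alpha) {
    pairwise <- do.call(rbind, lapply(pairs, function(pr) {
      sub <- droplevels(data[data$category %in% pr, , drop = FALSE])
      res <- fit_poisson_category(sub)
      data.frame(contrast = paste(pr, collapse = "-"),
                 statistic = res$test$statistic, p = res$test$p,
                 significant = is.finite(res$test$p) & res$test$p < threshold,
                 stringsAsFactors = FALSE)
    }))
  }
  props <- tapply(data$count / data$total, data$category, mean)
  structure(list(response = "sex_composition",
                 omnibus = fit$test,
                 pairwise = pairwise,
                 correction_threshold = threshold,
                 alpha = alpha,
                 fallback = fit$fallback,
                 type_means = props),
            class = "comparison_result")
}

fit_poisson_category <- function(data) {
  full <- tryCatch(suppressMessages(
    lme4::glmer(count ~ category + offset(log(total)) + (1 | origin),
                data = data, family = poisson())), error = function(e) NULL)
  if (!is.null(full) && !lme4::isSingular(full)) {
    null <- suppressMessages(stats::update(full, . ~ . - category))
    a <- suppressMessages(stats::anova(full, null))
    return(list(fallback = FALSE,
                test = list(statistic = a$Chisq[2], df = a$Df[2],
                            p = a[["Pr(>Chisq)"]][2],
                            method = "glmm_poisson_LRT")))
  }
  warning("singular or failed Poisson mixed fit; using fixed-effect GLM",
          call. = FALSE)
  full <- stats::glm(count ~ category + origin + offset(log(total)),
                     data = data, family = poisson())
  null <- stats::glm(count ~ origin + offset(log(total)),
                     data = data, family = poisson())
  a <- stats::anova(null, full, test = "Chisq")
  list(fallback = TRUE,
       test = list(statistic = a$Deviance[2], df = a$Df[2],
                   p = a[["Pr(>Chi)"]][2], method = "glm_poisson_LRT"))
}

#' Mixed model of a standardized index on a covariate and network type
#'
#' Fits `z ~ covariate * network_type + (1 | origin)` and reports a
#' Satterthwaite F and p for each fixed term (covariate, type, and their
#' interaction). Used to ask whether network size, connectance, niche
#' overlap or partner diversity explains differences in standardized
#' nestedness. A singular fit falls back to the fixed-effect OLS with
#' origin as a blocking factor, with a warning.
#'
#' @param data data frame with columns `origin`, `network_type`, the
#'   response and the covariate.
#' @param response name of the response column.
#' @param covariate name of the covariate column.
#' @return list of class `covariate_model_result` with `terms` (one row per
#'   fixed term: `term`, `statistic`, `df1`, `df2`, `p`), `coefficients`
#'   (estimate and standard error per fixed coefficient) and `method`.
#' @export
covariate_model <- function(data, response = "z", covariate) {
  data <- check_comparison_frame(data, response)
  stopifnot(covariate %in% names(data), all(is.finite(data[[covariate]])))
  f <- as.formula(paste(response, "~", covariate, "* network_type + (1 | origin)"))
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(f, data = data,
                                    control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit)) {
    a <- suppressMessages(stats::anova(fit))
    cf <- summary(fit)$coefficients
    return(structure(list(
      terms = data.frame(term = rownames(a), statistic = a[["F value"]],
                         df1 = a[["NumDF"]], df2 = a[["DenDF"]],
                         p = a[["Pr(>F)"]],
                         row.names = NULL, stringsAsFactors = FALSE),
      coefficients = data.frame(coef = rownames(cf),
                                estimate = cf[, "Estimate"],
                                se = cf[, "Std. Error"],
                                row.names = NULL, stringsAsFactors = FALSE),
      method = "lmm_satterthwaite_F"), class = "covariate_model_result"))
  }
  warning("singular or failed mixed fit; using fixed-effect OLS with origin blocks",
          call. = FALSE)
  f2 <- as.formula(paste(response, "~ origin +", covariate, "* network_type"))
  fit2 <- lm(f2, data = data)
  a <- stats::anova(fit2)
  keep <- setdiff(rownames(a), c("origin", "Residuals"))
  cf <- summary(fit2)$coefficients
  structure(list(
    terms = data.frame(term = keep, statistic = a[keep, "F value"],
                       df1 = a[keep, "Df"], df2 = a["Residuals", "Df"],
                       p = a[keep, "Pr(>F)"],
                       row.names = NULL, stringsAsFactors = FALSE),
    coefficients = data.frame(coef = rownames(cf),
                              estimate = cf[, "Estimate"],
                              se = cf[, "Std. Error"],
                              row.names = NULL, stringsAsFactors = FALSE),
    method = "ols_origin_blocks_F"), class = "covariate_model_result")
}

#' @export
print.covariate_model_result <- function(x, ...) {
  cat(sprintf("Covariate model (%s)\n", x$method))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation between standardized nestedness and modularity
#'
#' Modularity z scores (sMOD) are external inputs; this simply tests their
#' product-moment correlation with the swNODF values.
#'
#' @param z_nodf,z_mod paired numeric vectors, length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_swnodf_smod <- function(z_nodf, z_mod) {
  stopifnot(length(z_nodf) == length(z_mod), length(z_nodf) >= 3,
            all(is.finite(z_nodf)), all(is.finite(z_mod)))
  if (sd(z_nodf) == 0 || sd(z_mod) == 0) {
    abort_sexnest("correlation undefined: zero variance input",
                  "sexnest_undefined_metric")
  }
  ct <- cor.test(z_nodf, z_mod, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(z_nodf))
}
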