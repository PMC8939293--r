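#' End-to-end analysis pipeline
#'
#' `run_all()` executes the full analysis: specimen records (read from file
#' or generated synthetically) are filtered, partitioned into (site, year)
#' origins, assembled into species / female / male count networks, every
#' network's indices are standardized against fixed-margin nulls, and the
#' standardized indices and sex-composition counts are compared across
#' network types. All outputs are plain text (TSV matrices, tidy CSVs,
#' JSON reports) under `outdir`, inventoried in a manifest with the seeds
#' that produced them; reruns with the same configuration are
#' bit-identical.
#'
#' @name pipeline
NULL

#' Build a pipeline run configuration
#'
#' @param records_path path to a specimen CSV/TSV, or `NULL` to use
#'   `synthetic`.
#' @param synthetic a [synthetic_config()] used when `records_path` is
#'   `NULL`.
#' @param column_map column mapping for [read_records()].
#' @param metrics registry names of indices to standardize.
#' @param n_nulls null networks per index (study default 1000).
#' @param master_seed master seed; per-network standardization seeds
#'   derive from it.
#' @param alpha omnibus significance level (pairwise threshold is
#'   `alpha / 3` for three network types).
#' @param outdir output directory, created if needed.
#' @return list of class `run_config`.
#' @export
run_config <- function(records_path = NULL,
                       synthetic = synthetic_config(),
                       column_map = default_column_map(),
                       metrics = names(metric_registry()),
                       n_nulls = 1000L,
                       master_seed = 1L,
                       alpha = 0.05,
                       outdir = tempfile("sexnest_run_")) {
  stopifnot(is.null(records_path) || is.character(records_path),
            n_nulls >= 2, alpha > 0, alpha < 1,
            all(metrics %in% names(metric_registry())))
  structure(list(records_path = records_path, synthetic = synthetic,
                 column_map = column_map, metrics = metrics,
                 n_nulls = as.integer(n_nulls),
                 master_seed = as.integer(master_seed),
                 alpha = alpha, outdir = outdir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] and [synthetic_config()]
#' arguments; a `synthetic:` block is passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @param outdir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic %||% list()
  if (!is.null(syn_args$origins)) {
    syn_args$origins <- as.data.frame(do.call(rbind.data.frame, syn_args$origins))
  }
  run_config(
    records_path = y$records_path,
    synthetic = do.call(synthetic_config, syn_args),
    column_map = utils::modifyList(default_column_map(),
                                   as.list(y$column_map %||% list())),
    metrics = y$metrics %||% names(metric_registry()),
    n_nulls = y$n_nulls %||% 1000L,
    master_seed = y$master_seed %||% 1L,
    alpha = y$alpha %||% 0.05,
    outdir = outdir %||% y$outdir %||% tempfile("sexnest_run_")
  )
}

#' Run the complete analysis
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `records`, `filter_report`, `networks`
#'   (list of interaction matrices), `indices` (tidy standardized-index
#'   data frame), `sex_composition`, `comparisons`, and `manifest`. The
#'   same objects are written under `config$outdir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$outdir, "matrices"), showWarnings = FALSE)
  manifest <- list(package = "sexnest",
                   version = as.character(packageVersion("sexnest")),
                   master_seed = config$master_seed,
                   n_nulls = config$n_nulls,
                   stages = list(), files = character(0), seeds = list(),
                   skipped_networks = character(0))

  # stage 1: records
  if (is.null(config$records_path)) {
    study <- generate_study(config$synthetic)
    records <- as_records(study)
    manifest$stages$records <- "synthetic"
  } else {
    if (!file.exists(config$records_path)) {
      abort_sexnest(sprintf("records file not found: %s", config$records_path),
                    "sexnest_io_error")
    }
    records <- read_records(config$records_path, config$column_map)
    manifest$stages$records <- config$records_path
  }

  # stage 2: filtering
  filt <- filter_records(records)
  manifest$files <- c(manifest$files, write_json_file(
    as.list(filt$report), file.path(config$outdir, "filter_report.json")))

  # stage 3: networks
  groups <- partition_by_origin(filt$records)
  networks <- list()
  for (key in names(groups)) {
    for (type in c("species", "female", "male")) {
      nm <- tryCatch(build_matrix(groups[[key]], type),
                     sexnest_empty_network = function(e) NULL)
      label <- paste(key, type, sep = "|")
      if (is.null(nm)) {
        manifest$skipped_networks <- c(manifest$skipped_networks, label)
        next
      }
      networks[[label]] <- nm
      path <- file.path(config$outdir, "matrices",
                        paste0(sanitize_label(label), ".tsv"))
      manifest$files <- c(manifest$files, write_matrix_tsv(nm, path))
    }
  }

  # stage 4: standardized indices, one derived seed per network so any
  # single network's standardization can be reproduced in isolation
  seeds <- derive_seeds(config$master_seed, max(1L, length(networks)),
                        "standardize")
  indices <- do.call(rbind, lapply(seq_along(networks), function(i) {
    nm <- networks[[i]]
    idx <- standardize_metrics(nm, config$metrics,
                               n_nulls = config$n_nulls, seed = seeds[i])
    cbind(data.frame(origin = origin_key(attr(nm, "site"), attr(nm, "year")),
                     network_type = attr(nm, "network_type"),
                     stringsAsFactors = FALSE),
          idx)
  }))
  manifest$seeds$standardize <- setNames(as.list(seeds[seq_along(networks)]),
                                         names(networks))
  manifest$files <- c(manifest$files, write_csv_file(
    indices, file.path(config$outdir, "indices.csv")))

  # stage 5: sex composition
  sexcomp <- do.call(rbind, lapply(names(groups), function(key) {
    sc <- sex_composition(groups[[key]])
    data.frame(origin = key, category = names(sc$counts),
               count = as.integer(sc$counts), total = sc$n_species,
               proportion = as.numeric(sc$proportions),
               stringsAsFactors = FALSE)
  }))
  manifest$files <- c(manifest$files, write_csv_file(
    sexcomp, file.path(config$outdir, "sex_composition.csv")))

  # stage 6: comparisons
  comparisons <- run_comparisons(indices, sexcomp, alpha = config$alpha)
  manifest$files <- c(manifest$files, write_json_file(
    comparisons_to_list(comparisons),
    file.path(config$outdir, "comparisons.json")))

  manifest$files <- c(manifest$files,
                      file.path(config$outdir, "manifest.json"))
  write_json_file(manifest, file.path(config$outdir, "manifest.json"))
  invisible(list(records = filt$records, filter_report = filt$report,
                 networks = networks, indices = indices,
                 sex_composition = sexcomp, comparisons = comparisons,
                 manifest = manifest))
}

#' Compare standardized indices and sex composition across network types
#'
#' The visitor- and plant-level partner-diversity z scores coincide under
#' shared nulls, so they are compared once, as the unified metric
#' `partner_diversity`. Covariate models ask whether network size or
#' connectance accounts for standardized-nestedness differences.
#'
#' @param indices tidy standardized-index data frame from [run_all()].
#' @param sexcomp sex-composition data frame (origin, category, count,
#'   total), or `NULL` to skip.
#' @param alpha omnibus significance level.
#' @return named list of [compare_index()] / [compare_sex_composition()] /
#'   [covariate_model()] results.
#' @export
run_comparisons <- function(indices, sexcomp = NULL, alpha = 0.05) {
  out <- list()
  z_of <- function(metric) {
    d <- indices[indices$metric == metric & indices$z_defined, ,
                 drop = FALSE]
    d[, c("origin", "network_type", "z")]
  }
  unified <- c(wnodf = "wnodf",
               niche_overlap_visitor = "niche_overlap_visitor",
               niche_overlap_plant = "niche_overlap_plant",
               partner_diversity = "partner_diversity_visitor")
  for (nm in names(unified)) {
    d <- z_of(unified[[nm]])
    if (nrow(d) >= 6 && length(unique(d$network_type)) >= 2) {
      res <- compare_index(d, "z", alpha = alpha)
      res$response <- nm
      out[[nm]] <- res
    }
  }
  if (!is.null(sexcomp)) {
    out$sex_composition <- compare_sex_composition(sexcomp, alpha = alpha)
  }
  zn <- z_of("wnodf")
  for (cov_metric in c("network_size", "connectance")) {
    obs <- indices[indices$metric == cov_metric,
                   c("origin", "network_type", "observed")]
    names(obs)[3] <- cov_metric
    d <- merge(zn, obs, by = c("origin", "network_type"))
    if (nrow(d) >= 9) {
      out[[paste0("wnodf_vs_", cov_metric)]] <-
        covariate_model(d, "z", cov_metric)
    }
  }
  out
}

comparisons_to_list <- function(comparisons) {
  lapply(comparisons, function(x) {
    if (inherits(x, "comparison_result")) {
      list(response = x$response, omnibus = x$omnibus,
           type_means = as.list(x$type_means),
           correction_threshold = x$correction_threshold,
           fallback = x$fallback, pairwise = x$pairwise)
    } else if (inherits(x, "covariate_model_result")) {
      list(terms = x$terms, coefficients = x$coefficients, method = x$method)
    } else x
  })
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9._-]+", "-", x)
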