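#' Specimen records: reading, filtering and network assembly
#'
#' A specimen record is one collected flower-visiting insect: the visitor
#' taxon label (species or "Genus sp." morphospecies), its sex, the plant
#' taxon it was collected on, and the collection site and year. Records are
#' held as a plain data frame with columns `visitor_taxon`, `sex`,
#' `plant_taxon`, `site`, `year`. Taxon identity is the verbatim label
#' string; no taxonomic normalization is attempted.
#'
#' @name specimen-records
NULL

#' Default mapping from logical record fields to file column names
#'
#' @return named list mapping the five logical fields to column names.
#' @export
default_column_map <- function() {
  list(visitor_taxon = "visitor_taxon", sex = "sex",
       plant_taxon = "plant_taxon", site = "site", year = "year")
}

#' Default sex synonym table
#'
#' Case-insensitive labels recognized as female or male; anything else
#' (including empty strings and NA) is kept as `"unknown"` and discarded by
#' [filter_records()].
#'
#' @return named character vector mapping lower-case synonyms to
#'   `"female"`/`"male"`.
#' @export
default_sex_synonyms <- function() {
  c(f = "female", female = "female", fem = "female", "♀" = "female",
    m = "male", male = "male", "♂" = "male")
}

#' Read specimen records from a delimited text file
#'
#' Reads a CSV or TSV specimen table (UTF-8, header row) and returns one
#' record per data row with sex labels normalized through a synonym table.
#' Unmapped extra columns are ignored.
#'
#' @param path path to the file. Field separator is taken from the
#'   extension (`.csv` is comma; anything else tab) unless `sep` is given.
#' @param column_map named list mapping the logical fields
#'   `visitor_taxon`, `sex`, `plant_taxon`, `site`, `year` to column names
#'   in the file; see [default_column_map()].
#' @param sex_synonyms named character vector of lower-case sex labels; see
#'   [default_sex_synonyms()].
#' @param sep optional field separator overriding the extension heuristic.
#' @return data frame of specimen records with normalized columns; sex is
#'   one of `"female"`, `"male"`, `"unknown"`. Rows whose year does not
#'   parse keep `NA` and are later discarded by [filter_records()].
#' @export
read_records <- function(path, column_map = default_column_map(),
                         sex_synonyms = default_sex_synonyms(), sep = NULL) {
  if (!file.exists(path)) {
    abort_sexnest(sprintf("records file not found: %s", path), "sexnest_io_error")
  }
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
  needed <- c("visitor_taxon", "sex", "plant_taxon", "site", "year")
  column_map <- utils::modifyList(default_column_map(), as.list(column_map))
  missing_cols <- vapply(needed, function(f) {
    !(column_map[[f]] %in% names(raw))
  }, logical(1))
  if (any(missing_cols)) {
    abort_sexnest(sprintf(
      "mapped column(s) absent from header: %s",
      paste(sprintf("%s -> '%s'", needed[missing_cols],
                    unlist(column_map[needed[missing_cols]])), collapse = ", ")),
      "sexnest_config_error")
  }
  out <- data.frame(
    visitor_taxon = trimws(raw[[column_map$visitor_taxon]]),
    sex = normalize_sex(raw[[column_map$sex]], sex_synonyms),
    plant_taxon = trimws(raw[[column_map$plant_taxon]]),
    site = trimws(raw[[column_map$site]]),
    year = suppressWarnings(as.integer(trimws(raw[[column_map$year]]))),
    stringsAsFactors = FALSE
  )
  out
}

normalize_sex <- function(x, synonyms = default_sex_synonyms()) {
  key <- tolower(trimws(as.character(x)))
  mapped <- unname(synonyms[key])
  mapped[is.na(mapped)] <- "unknown"
  mapped
}

#' Filter specimen records to analysis-ready completeness
#'
#' Discards records lacking any label needed to place them in a network:
#' missing visitor taxon, unidentifiable sex, missing plant taxon, missing
#' site, or missing/unparseable year. Genus-level ("sp.") visitor labels are
#' retained as distinct morphospecies. Each discarded record is counted
#' under the first rule it violates, in the order listed above.
#'
#' @param records data frame as returned by [read_records()].
#' @return list with `records` (the kept rows) and `report`, a named
#'   integer vector of discard counts by reason plus `kept` and `input`.
#' @export
filter_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(records)
  bad_visitor <- is.na(records$visitor_taxon) | records$visitor_taxon == ""
  bad_sex <- !(records$sex %in% c("female", "male"))
  bad_plant <- is.na(records$plant_taxon) | records$plant_taxon == ""
  bad_site <- is.na(records$site) | records$site == ""
  bad_year <- is.na(records$year)
  reason <- rep(NA_character_, n)
  reason[bad_year] <- "no_year"
  reason[bad_site] <- "no_site"
  reason[bad_plant] <- "no_plant"
  reason[bad_sex] <- "sex_unidentified"
  reason[bad_visitor] <- "no_visitor_taxon"
  keep <- is.na(reason)
  reasons <- c("no_visitor_taxon", "sex_unidentified", "no_plant",
               "no_site", "no_year")
  report <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  report <- c(report, kept = sum(keep), input = n)
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Partition filtered records into (site, year) origins
#'
#' @param records filtered specimen records.
#' @return named list of record data frames, one per non-empty
#'   `site:year` combination, sorted by site then year. Every input record
#'   appears in exactly one group.
#' @export
partition_by_origin <- function(records) {
  key <- origin_key(records$site, records$year)
  groups <- split(records, key)
  ord <- order(vapply(groups, function(g) g$site[1], character(1)),
               vapply(groups, function(g) g$year[1], integer(1)))
  groups[ord]
}

origin_key <- function(site, year) paste(site, year, sep = ":")

#' Build a plant x visitor interaction count matrix
#'
#' Counts specimens pairing each plant taxon (rows) with each visitor taxon
#' (columns) for one network origin. `network_type = "species"` pools both
#' sexes; `"female"`/`"male"` keep only that sex's specimens, so every
#' origin yields a species network and two sex subnetworks whose counts sum
#' to it. Species without any interaction under the sex filter do not
#' appear. Rows and columns are ordered lexicographically by taxon label;
#' all metrics in the package are invariant to this ordering.
#'
#' @param records one origin's filtered records.
#' @param network_type `"species"`, `"female"` or `"male"`.
#' @return integer matrix with plant taxa as rownames and visitor taxa as
#'   colnames, carrying attributes `site`, `year` and `network_type`;
#'   class `interaction_matrix`.
#' @export
build_matrix <- function(records, network_type = c("species", "female", "male")) {
  network_type <- match.arg(network_type)
  origin_label <- paste(unique(origin_key(records$site, records$year)),
                        collapse = ",")
  if (network_type != "species") {
    records <- records[records$sex == network_type, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    abort_sexnest(sprintf("empty network: no %s specimens for origin %s",
                          network_type, origin_label),
                  "sexnest_empty_network")
  }
  plants <- sort(unique(records$plant_taxon))
  visitors <- sort(unique(records$visitor_taxon))
  m <- unclass(table(factor(records$plant_taxon, levels = plants),
                     factor(records$visitor_taxon, levels = visitors)))
  dimnames(m) <- list(plants, visitors)
  storage.mode(m) <- "integer"
  interaction_matrix(m,
                     site = if (length(unique(records$site)) == 1L)
                       records$site[1] else NA_character_,
                     year = if (length(unique(records$year)) == 1L)
                       records$year[1] else NA_integer_,
                     network_type = network_type)
}

#' Construct an interaction_matrix object
#'
#' @param m non-negative integer matrix, plants in rows, visitors in
#'   columns, with dimnames.
#' @param site,year network origin labels (may be `NA`).
#' @param network_type `"species"`, `"female"` or `"male"`.
#' @return the matrix with class `interaction_matrix` and origin attributes.
#' @export
interaction_matrix <- function(m, site = NA_character_, year = NA_integer_,
                               network_type = "species") {
  stopifnot(is.matrix(m), all(m >= 0), !is.null(rownames(m)), !is.null(colnames(m)))
  structure(m, site = site, year = year, network_type = network_type,
            class = c("interaction_matrix", class(matrix())))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d plants x %d visitors, %d specimens (%s, %s, %s)\n",
              nrow(x), ncol(x), sum(x),
              attr(x, "site"), attr(x, "year"), attr(x, "network_type")))
  print(unclass(x), ...)
  invisible(x)
}

#' Classify visitor species by the sexes observed in a network
#'
#' Every visitor species in one origin's records is assigned to exactly one
#' of the categories all-female, all-male or both-sex, and the category
#' counts are expressed as proportions of the origin's visitor species
#' richness. Species represented by a single specimen necessarily fall in a
#' single-sex category.
#'
#' @param records one origin's filtered records.
#' @return list with `counts` (named integer vector over `all_female`,
#'   `all_male`, `both`), `proportions` (counts / richness) and
#'   `n_species`.
#' @export
sex_composition <- function(records) {
  stopifnot(all(records$sex %in% c("female", "male")))
  tab <- table(records$visitor_taxon, records$sex)
  has_f <- if ("female" %in% colnames(tab)) tab[, "female"] > 0 else rep(FALSE, nrow(tab))
  has_m <- if ("male" %in% colnames(tab)) tab[, "male"] > 0 else rep(FALSE, nrow(tab))
  counts <- c(all_female = sum(has_f & !has_m),
              all_male = sum(has_m & !has_f),
              both = sum(has_f & has_m))
  n_species <- nrow(tab)
  stopifnot(sum(counts) == n_species)
  list(counts = counts, proportions = counts / n_species, n_species = n_species)
}

#' Write / read an interaction matrix as TSV
#'
#' The format is one header row of visitor taxa preceded by a `plant`
#' column label, then one row per plant taxon with integer counts.
#' Round-trips bit-exactly through [read_matrix_tsv()].
#'
#' @param m interaction matrix (any integer matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(plant = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param site,year,network_type origin attributes to attach on read.
#' @export
read_matrix_tsv <- function(path, site = NA_character_, year = NA_integer_,
                            network_type = "species") {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  interaction_matrix(m, site = site, year = year, network_type = network_type)
}
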