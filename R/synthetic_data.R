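#' Synthetic flower-visitor specimen records
#'
#' The generator emulates the statistical structure the analysis assumes:
#' heavy-tailed (log-normal) species-abundance distributions for plants and
#' visitors, many visitor species represented by one or two specimens, a
#' female-biased specimen sex ratio, and sex-specific visitation rules.
#' Each visitor species carries a Dirichlet "preference" distribution over
#' plants; the realized flower-choice distribution of each sex is the
#' convex mixture `lambda * abundance + (1 - lambda) * preference`, where
#' `lambda` is that sex's neutrality. `lambda = 1` is pure
#' encounter-probability (abundance-proportional) visitation, the
#' behavior hypothesized for mate-searching males; `lambda = 0` is pure
#' preference-driven visitation, the behavior hypothesized for foraging
#' females. Specimens are then sampled per (site, year) origin exactly as a
#' net-collection census records them: one visitor individual, its sex, and
#' the plant it was caught on.
#'
#' @name synthetic-data
NULL

#' The default study design: 11 origins, three sites by four years
#'
#' Per-origin specimen totals follow the collection design the package's
#' defaults emulate (three Kyoto-area sites sampled 1984-1987 with no
#' collection at the Kyoto University site in 1984), totalling 5212
#' specimens across 11 (site, year) origins.
#'
#' @return data frame with columns `site`, `year`, `n_specimens`.
#' @export
flower_visitor_origins <- function() {
  data.frame(
    site = rep(c("Kibune", "Ashu", "KyotoUniversity"), times = c(4, 4, 3)),
    year = c(1984:1987, 1984:1987, 1985:1987),
    n_specimens = c(687L, 362L, 616L, 1098L,
                    458L, 168L, 531L, 217L,
                    384L, 468L, 223L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic specimen-record generator
#'
#' @param n_plants number of plant species in each origin's community.
#' @param n_visitor_species size of each origin's visitor species pool
#'   (realized per-network richness is lower; rare species go unsampled).
#' @param plant_abundance_shape,visitor_abundance_shape log-normal sigma of
#'   the species-abundance distributions (larger = heavier tail, more
#'   singletons).
#' @param female_fraction probability a sampled specimen is female;
#'   defaults to the female share of the emulated collection
#'   (3256/5212).
#' @param neutrality_female,neutrality_male per-sex mixing weight `lambda`
#'   in `[0, 1]` between abundance-proportional encounter (`1`) and the
#'   species' own plant preferences (`0`). Defaults encode the
#'   preference-driven-female / encounter-driven-male mechanism.
#' @param preference_concentration total Dirichlet concentration per plant
#'   (the Dirichlet parameter vector is
#'   `preference_concentration * n_plants * base`); small values give each
#'   species a few strongly preferred plants, large values shrink every
#'   species' preference toward the base measure.
#' @param preference_base base measure of the preference Dirichlet:
#'   `"abundance"` centers every species' preferences on floral
#'   availability (species deviate from the community profile, the
#'   default), `"uniform"` draws preferences blind to plant abundance.
#' @param origins data frame with columns `site`, `year`, `n_specimens`
#'   defining the study design; defaults to [flower_visitor_origins()].
#' @param n_origins,n_specimens_per_origin alternative uniform design: if
#'   either is supplied, `n_origins` origins with
#'   `n_specimens_per_origin` specimens each replace `origins`.
#' @param master_seed integer master seed; all per-origin seeds derive
#'   from it via [derive_seeds()].
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plants = 40L,
                             n_visitor_species = 1500L,
                             plant_abundance_shape = 2.0,
                             visitor_abundance_shape = 2.2,
                             female_fraction = 3256 / 5212,
                             neutrality_female = 0,
                             neutrality_male = 1,
                             preference_concentration = 0.02,
                             preference_base = c("abundance", "uniform"),
                             origins = flower_visitor_origins(),
                             n_origins = NULL,
                             n_specimens_per_origin = NULL,
                             master_seed = 1L) {
  if (!is.null(n_origins) || !is.null(n_specimens_per_origin)) {
    n_origins <- n_origins %||% 11L
    n_specimens_per_origin <- n_specimens_per_origin %||% 474L
    sites <- paste0("S", seq_len(min(3L, n_origins)))
    grid <- expand.grid(site = sites,
                        year = seq_len(ceiling(n_origins / length(sites))),
                        stringsAsFactors = FALSE)
    origins <- data.frame(site = grid$site[seq_len(n_origins)],
                          year = 2000L + grid$year[seq_len(n_origins)],
                          n_specimens = as.integer(n_specimens_per_origin),
                          stringsAsFactors = FALSE)
  }
  cfg <- list(n_plants = as.integer(n_plants),
              n_visitor_species = as.integer(n_visitor_species),
              plant_abundance_shape = plant_abundance_shape,
              visitor_abundance_shape = visitor_abundance_shape,
              female_fraction = female_fraction,
              neutrality_female = neutrality_female,
              neutrality_male = neutrality_male,
              preference_concentration = preference_concentration,
              preference_base = match.arg(preference_base),
              origins = origins,
              master_seed = as.integer(master_seed))
  stopifnot(cfg$n_plants >= 1, cfg$n_visitor_species >= 1,
            cfg$plant_abundance_shape >= 0, cfg$visitor_abundance_shape >= 0,
            cfg$female_fraction >= 0, cfg$female_fraction <= 1,
            cfg$neutrality_female >= 0, cfg$neutrality_female <= 1,
            cfg$neutrality_male >= 0, cfg$neutrality_male <= 1,
            cfg$preference_concentration > 0,
            is.data.frame(origins),
            all(c("site", "year", "n_specimens") %in% names(origins)),
            nrow(origins) >= 1, all(origins$n_specimens >= 0))
  structure(cfg, class = "synthetic_config")
}

#' Generate one origin's community
#'
#' Draws normalized log-normal plant and visitor abundances, a Dirichlet
#' preference vector over plants for every visitor species, and the per-sex
#' flower-choice distributions as neutrality mixtures of abundance and
#' preference.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed for this origin.
#' @return list with `plant_abundance`, `visitor_abundance` (named,
#'   normalized), `preference` and per-sex `choice_female`,
#'   `choice_male` matrices (visitor species x plants, rows summing to 1).
#' @export
generate_community <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, {
    nP <- config$n_plants
    nV <- config$n_visitor_species
    plant_ab <- rlnorm(nP, 0, config$plant_abundance_shape)
    plant_ab <- plant_ab / sum(plant_ab)
    names(plant_ab) <- sprintf("Plant_%02d", seq_len(nP))
    vis_ab <- rlnorm(nV, 0, config$visitor_abundance_shape)
    vis_ab <- vis_ab / sum(vis_ab)
    names(vis_ab) <- sprintf("Visitor_%04d", seq_len(nV))
    base <- if (config$preference_base == "abundance") plant_ab else rep(1 / nP, nP)
    alpha <- config$preference_concentration * nP * base
    pref <- matrix(rgamma(nV * nP, shape = rep(alpha, each = nV)),
                   nrow = nV, ncol = nP,
                   dimnames = list(names(vis_ab), names(plant_ab)))
    rs <- rowSums(pref)
    zero <- rs == 0  # gamma underflow guard for tiny concentrations
    pref[zero, ] <- rep(base, each = sum(zero))
    pref <- pref / rowSums(pref)
    mix <- function(lambda) {
      ch <- lambda * matrix(plant_ab, nV, nP, byrow = TRUE) + (1 - lambda) * pref
      dimnames(ch) <- dimnames(pref)
      ch
    }
    list(plant_abundance = plant_ab,
         visitor_abundance = vis_ab,
         preference = pref,
         choice_female = mix(config$neutrality_female),
         choice_male = mix(config$neutrality_male))
  })
}

#' Sample specimen records from a community
#'
#' Each record draws a visitor species proportional to visitor abundance,
#' a sex with probability `female_fraction`, and a plant from that
#' species-sex flower-choice distribution — one captured individual with
#' the plant it was collected on.
#'
#' @param community output of [generate_community()].
#' @param config the [synthetic_config()].
#' @param seed integer seed for this origin's sampling.
#' @param n number of specimens to draw.
#' @param site,year origin labels stamped on every record.
#' @return specimen-record data frame with columns `visitor_taxon`, `sex`,
#'   `plant_taxon`, `site`, `year`.
#' @export
simulate_specimens <- function(community, config, seed, n,
                               site = "S1", year = 2001L) {
  stopifnot(inherits(config, "synthetic_config"), n >= 0)
  if (n == 0L) {
    return(data.frame(visitor_taxon = character(0), sex = character(0),
                      plant_taxon = character(0), site = character(0),
                      year = integer(0), stringsAsFactors = FALSE))
  }
  withr::with_seed(seed, {
    nV <- length(community$visitor_abundance)
    nP <- length(community$plant_abundance)
    sp <- sample.int(nV, n, replace = TRUE, prob = community$visitor_abundance)
    female <- runif(n) < config$female_fraction
    plant <- integer(n)
    for (is_female in c(TRUE, FALSE)) {
      choice <- if (is_female) community$choice_female else community$choice_male
      idx <- which(female == is_female)
      for (s in unique(sp[idx])) {
        ii <- idx[sp[idx] == s]
        plant[ii] <- sample.int(nP, length(ii), replace = TRUE,
                                prob = choice[s, ])
      }
    }
    data.frame(
      visitor_taxon = names(community$visitor_abundance)[sp],
      sex = ifelse(female, "female", "male"),
      plant_taxon = names(community$plant_abundance)[plant],
      site = site,
      year = as.integer(year),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full multi-origin synthetic study
#'
#' Draws an independent community and specimen sample for every origin in
#' the design, with per-origin child seeds derived from the master seed, so
#' the whole study is reproducible bit-identically and each origin can be
#' regenerated in isolation.
#'
#' @param config a [synthetic_config()].
#' @return named list of specimen-record data frames keyed `site:year`,
#'   with the config attached as attribute `config`. Use [as_records()] to
#'   stack them into one table with the same schema as [read_records()]
#'   output.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(config$origins)
  community_seeds <- derive_seeds(config$master_seed, n, "community")
  specimen_seeds <- derive_seeds(config$master_seed, n, "specimens")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    community <- generate_community(config, community_seeds[i])
    out[[i]] <- simulate_specimens(community, config, specimen_seeds[i],
                                   n = config$origins$n_specimens[i],
                                   site = config$origins$site[i],
                                   year = config$origins$year[i])
  }
  names(out) <- origin_key(config$origins$site, config$origins$year)
  structure(out, config = config)
}

#' Stack a generated study into one specimen-record table
#'
#' @param study output of [generate_study()].
#' @return one data frame with the [read_records()] schema.
#' @export
as_records <- function(study) {
  do.call(rbind, c(unname(study), list(make.row.names = FALSE)))
}

#' Write specimen records to CSV
#'
#' @param records specimen-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
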