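# Independent oracles and small fixture builders, all generated in code.

# Naive weighted-NODF oracle: direct enumeration of every unordered
# row/column pair, contribution 100*k/N for the member with the strictly
# smaller marginal total, written straight from the metric's definition and
# kept free of the package's vectorized path.
oracle_wnodf <- function(m) {
  pair_sum <- function(X) {
    tot <- colSums(X)
    n <- ncol(X)
    s <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- i; b <- j
        if (tot[a] == tot[b]) next
        if (tot[a] < tot[b]) { a <- j; b <- i }
        nz <- which(X[, b] > 0)
        if (!length(nz)) next
        k <- sum(X[nz, b] < X[nz, a])
        s <- s + 100 * k / length(nz)
      }
    }
    s
  }
  nr <- nrow(m); nc <- ncol(m)
  2 * (pair_sum(m) + pair_sum(t(m))) / (nr * (nr - 1) + nc * (nc - 1))
}

# Naive pairwise niche overlap: explicit loop over species pairs.
oracle_niche_overlap <- function(m, level = "visitor") {
  X <- if (level == "visitor") m else t(m)
  pairs <- utils::combn(ncol(X), 2)
  mean(apply(pairs, 2, function(pr) {
    chao_jaccard_similarity(X[, pr[1]], X[, pr[2]])
  }))
}

# Random count matrix with all margins positive.
random_count_matrix <- function(nr, nc, lambda = 1.3) {
  repeat {
    m <- matrix(rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("p", seq_len(nr)), paste0("v", seq_len(nc)))
  m
}

nested_toy <- function() {
  matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, byrow = TRUE,
         dimnames = list(paste0("p", 1:3), paste0("v", 1:3)))
}

# Specimen-record fixture: one row per (visitor, sex, plant) triple.
toy_records <- function(triples, site = "SiteA", year = 1984L) {
  do.call(rbind, lapply(triples, function(tr) {
    data.frame(visitor_taxon = tr[[1]], sex = tr[[2]], plant_taxon = tr[[3]],
               site = site, year = year, stringsAsFactors = FALSE)
  }))
}

# Small synthetic study configuration used by pipeline-level tests.
toy_synth_config <- function(master_seed = 42L) {
  synthetic_config(n_plants = 12L, n_visitor_species = 60L,
                   visitor_abundance_shape = 1.5,
                   n_origins = 3L, n_specimens_per_origin = 120L,
                   master_seed = master_seed)
}
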