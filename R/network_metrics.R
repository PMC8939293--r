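#' Network indices for weighted bipartite interaction matrices
#'
#' The raw indices compared between female, male and species networks:
#' weighted NODF nestedness, connectance, Chao abundance-based niche
#' overlap, abundance-weighted Shannon partner diversity, and network size.
#' All functions take a plant x visitor count matrix (rows = plants,
#' columns = visitors) and are invariant to row/column permutations.
#'
#' @name network-indices
NULL

#' Weighted NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fill, computed on
#' count data. For every unordered pair of columns (and of rows), the pair
#' contributes `100 * k / N` where `k` is the number of cells in the member
#' with the strictly smaller marginal total that are non-empty and hold a
#' strictly lower value than the corresponding cell of the other member,
#' and `N` is the number of non-empty cells of the smaller member. Pairs
#' whose marginal totals tie contribute zero (the decreasing-fill
#' condition). The statistic is the mean pair contribution over all
#' `m(m-1)/2 + n(n-1)/2` pairs, ranging 0 (no unilateral overlap) to 100
#' (strict nestedness).
#'
#' @param m count matrix with at least 2 rows and 2 columns, every row and
#'   column total positive.
#' @return numeric scalar in `[0, 100]`.
#' @export
#' @examples
#' weighted_nodf(matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, byrow = TRUE,
#'               dimnames = list(paste0("p", 1:3), paste0("v", 1:3))))
weighted_nodf <- function(m) {
  m <- as_count_matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort_sexnest("weighted NODF undefined for matrices smaller than 2x2",
                  "sexnest_undefined_metric")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_sexnest("weighted NODF requires all row and column totals positive",
                  "sexnest_undefined_metric")
  }
  nr <- nrow(m); nc <- ncol(m)
  total <- wnodf_pair_sum(m) + wnodf_pair_sum(t(m))
  2 * total / (nr * (nr - 1) + nc * (nc - 1))
}

# Sum of 100*k/N over all unordered column pairs with strictly decreasing
# marginal totals. O(m * n^2) via one vector comparison block per column.
wnodf_pair_sum <- function(m) {
  ct <- colSums(m)
  n <- ncol(m)
  acc <- 0
  for (j in seq_len(n)) {
    nz <- m[, j] > 0
    Nj <- sum(nz)
    if (Nj == 0L) next
    larger <- which(ct > ct[j])
    if (!length(larger)) next
    # k for every partner with a strictly larger total, in one block
    k <- colSums(m[nz, larger, drop = FALSE] > m[nz, j])
    acc <- acc + sum(100 * k / Nj)
  }
  acc
}

#' Connectance of a bipartite count matrix
#'
#' Ratio of observed links (non-zero cells) to all possible links.
#'
#' @param m count matrix.
#' @return numeric scalar in `(0, 1]` for any matrix with at least one
#'   interaction.
#' @export
connectance <- function(m) {
  m <- as_count_matrix(m)
  sum(m > 0) / length(m)
}

#' Network size
#'
#' Total number of plant plus visitor species in the network.
#'
#' @param m count matrix.
#' @return integer scalar, `nrow(m) + ncol(m)`.
#' @export
network_size <- function(m) {
  m <- as_count_matrix(m)
  nrow(m) + ncol(m)
}

#' Chao abundance-based Jaccard similarity between two communities
#'
#' Estimates the probability that individuals drawn from two communities
#' belong to shared species, correcting for unseen shared species via
#' shared singletons and doubletons. With `U` and `V` the (truncated-at-1)
#' estimated total relative abundances of shared species in each community,
#' the similarity is `U*V / (U + V - U*V)`: 1 for identical abundant
#' communities, 0 when no species are shared. When the shared-doubleton
#' count is zero, 1 is substituted in the bias-correction denominator.
#'
#' @param x,y non-negative count vectors over a common species index.
#' @return numeric scalar in `[0, 1]`, symmetric in its arguments.
#' @export
#' @examples
#' chao_jaccard_similarity(c(3, 1, 0), c(2, 0, 2))
chao_jaccard_similarity <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0),
            sum(x) >= 1, sum(y) >= 1)
  U <- chao_shared_abundance(x, y)
  V <- chao_shared_abundance(y, x)
  if (U == 0 || V == 0) return(0)
  U * V / (U + V - U * V)
}

chao_shared_abundance <- function(x, y) {
  shared <- x > 0 & y > 0
  if (!any(shared)) return(0)
  nA <- sum(x); nB <- sum(y)
  p <- x[shared] / nA
  ys <- y[shared]
  f1 <- sum(ys == 1)
  f2 <- sum(ys == 2)
  U <- sum(p) + (nB - 1) / nB * f1 / (2 * max(f2, 1)) * sum(p[ys == 1])
  min(U, 1)
}

#' Mean pairwise Chao niche overlap at one guild level
#'
#' For `level = "visitor"` each visitor species' community is its column of
#' plant counts; overlap is the mean [chao_jaccard_similarity()] over all
#' unordered pairs of species at that level (high when diets coincide).
#' `level = "plant"` works on rows. The all-pairs computation is carried
#' out with four cross-products rather than an explicit pair loop.
#'
#' @param m count matrix.
#' @param level `"visitor"` (columns) or `"plant"` (rows).
#' @return numeric scalar in `[0, 1]`.
#' @export
niche_overlap <- function(m, level = c("visitor", "plant")) {
  level <- match.arg(level)
  m <- as_count_matrix(m)
  X <- if (level == "visitor") m else t(m)
  n <- ncol(X)
  if (n < 2L) {
    abort_sexnest(sprintf("niche overlap undefined with a single %s species", level),
                  "sexnest_undefined_metric")
  }
  tot <- colSums(X)
  stopifnot(all(tot > 0))
  P <- sweep(X, 2, tot, "/")
  Z <- (X > 0) * 1
  ones <- (X == 1) * 1
  twos <- (X == 2) * 1
  S1 <- crossprod(P, Z)      # [A,B] total shared relative abundance in A
  S2 <- crossprod(P, ones)   # [A,B] shared abundance in A over B-singletons
  F1 <- crossprod(Z, ones)   # [A,B] shared species that are singletons in B
  F2 <- crossprod(Z, twos)   # [A,B] shared species that are doubletons in B
  corr <- sweep(F1 / (2 * pmax(F2, 1)) * S2, 2, (tot - 1) / tot, "*")
  U <- pmin(S1 + corr, 1)
  Ut <- t(U)
  J <- matrix(0, n, n)
  ok <- U > 0 & Ut > 0
  J[ok] <- (U * Ut / (U + Ut - U * Ut))[ok]
  mean(J[upper.tri(J)])
}

#' Shannon entropy of a count vector
#'
#' Natural-log Shannon diversity of the normalized counts; zero counts are
#' ignored. A single partner gives 0; `k` equal counts give `log(k)`.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @return numeric scalar `>= 0`.
#' @export
shannon_entropy <- function(counts) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  if (!length(counts)) {
    abort_sexnest("Shannon entropy undefined for an all-zero vector",
                  "sexnest_undefined_metric")
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Abundance-weighted mean partner diversity at one guild level
#'
#' Each species' partner diversity is the Shannon entropy of its
#' interaction counts; the network-level value is the mean over species
#' weighted by each species' interaction total `n_j`, i.e.
#' `sum(n_j * H_j) / S` with `S` the grand total of interactions.
#' Singleton-margin species contribute `H = 0` with weight 1. The visitor-
#' and plant-level values differ only by a function of the matrix margins,
#' which is why their fixed-margin null z scores coincide.
#'
#' @param m count matrix.
#' @param level `"visitor"` (entropy of each column) or `"plant"` (rows).
#' @return numeric scalar `>= 0`.
#' @export
partner_diversity <- function(m, level = c("visitor", "plant")) {
  level <- match.arg(level)
  m <- as_count_matrix(m)
  X <- if (level == "visitor") m else t(m)
  n_j <- colSums(X)
  stopifnot(all(n_j > 0))
  H_j <- apply(X, 2, shannon_entropy)
  sum(n_j * H_j) / sum(n_j)
}

#' Compute the full index panel for one network
#'
#' @param m count matrix.
#' @return data frame with columns `metric`, `level`, `value`; indices that
#'   are undefined for the matrix (e.g. weighted NODF on a 1-column
#'   network) are reported as `NA`.
#' @export
network_metrics <- function(m) {
  m <- as_count_matrix(m)
  safe <- function(f) tryCatch(f(m), sexnest_undefined_metric = function(e) NA_real_)
  reg <- metric_registry()
  data.frame(
    metric = names(reg),
    level = metric_levels()[names(reg)],
    value = vapply(reg, function(f) as.numeric(safe(f)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Registry of standardizable network indices
#'
#' Named list of single-matrix metric functions used by
#' [standardize_metrics()] and the pipeline.
#'
#' @return named list of functions.
#' @export
metric_registry <- function() {
  list(
    wnodf = weighted_nodf,
    connectance = connectance,
    network_size = network_size,
    niche_overlap_visitor = function(m) niche_overlap(m, "visitor"),
    niche_overlap_plant = function(m) niche_overlap(m, "plant"),
    partner_diversity_visitor = function(m) partner_diversity(m, "visitor"),
    partner_diversity_plant = function(m) partner_diversity(m, "plant")
  )
}

metric_levels <- function() {
  c(wnodf = "network", connectance = "network", network_size = "network",
    niche_overlap_visitor = "visitor", niche_overlap_plant = "plant",
    partner_diversity_visitor = "visitor", partner_diversity_plant = "plant")
}

as_count_matrix <- function(m) {
  stopifnot(is.matrix(m), all(is.finite(m)), all(m >= 0))
  if (sum(m) == 0) {
    abort_sexnest("interaction matrix has no interactions", "sexnest_undefined_metric")
  }
  m
}
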