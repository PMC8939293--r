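test_that("weighted NODF hits its analytic endpoints", {
  expect_equal(weighted_nodf(nested_toy()), 100)
  # tied margins everywhere: the decreasing-fill condition never holds
  tied <- matrix(c(2, 1, 1, 2), 2, dimnames = list(c("p1", "p2"), c("v1", "v2")))
  expect_equal(weighted_nodf(tied), 0)
  expect_error(weighted_nodf(matrix(1:3, 1, dimnames = list("p", c("a", "b", "c")))),
               class = "sexnest_undefined_metric")
})

test_that("weighted NODF equals the naive pair-enumeration oracle", {
  set.seed(101)
  for (i in 1:150) {
    m <- random_count_matrix(sample(2:6, 1), sample(2:6, 1),
                             lambda = runif(1, 0.7, 2.5))
    expect_equal(weighted_nodf(m), oracle_wnodf(m), tolerance = 1e-12)
  }
})

test_that("weighted NODF matches vegan where the fill and margin orderings agree", {
  skip_if_not_installed("vegan")
  # vegan's weighted variant conditions pairs on binary fill; the two
  # definitions coincide whenever fill differences and margin-total
  # differences have matching signs for every pair
  consistent <- function(m) {
    ok <- function(X) {
      fills <- colSums(X > 0); tots <- colSums(X)
      all(outer(fills, fills, function(a, b) sign(a - b)) ==
            outer(tots, tots, function(a, b) sign(a - b)))
    }
    ok(m) && ok(t(m))
  }
  expect_equal(unname(vegan::nestednodf(nested_toy(), weighted = TRUE,
                                        order = TRUE)$statistic["NODF"]), 100)
  set.seed(77)
  checked <- 0
  while (checked < 40) {
    m <- random_count_matrix(sample(2:5, 1), sample(2:5, 1))
    if (!consistent(m)) next
    checked <- checked + 1
    expect_equal(weighted_nodf(m),
                 unname(vegan::nestednodf(m, weighted = TRUE,
                                          order = TRUE)$statistic["NODF"]),
                 tolerance = 1e-10)
  }
})

test_that("connectance and network size count links and species", {
  full <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("v1", "v2")))
  expect_equal(connectance(full), 1)
  one <- matrix(c(3, 0, 0, 0), 2, dimnames = list(c("p1", "p2"), c("v1", "v2")))
  expect_equal(connectance(one), 0.25)
  expect_equal(connectance(diag(3)), 3 / 9)
  expect_equal(network_size(matrix(1, 3, 5)), 8L)
  expect_equal(network_size(matrix(1, 1, 1)), 2L)
})

test_that("Chao similarity matches hand evaluation and its endpoints", {
  # identical abundant communities: no singleton correction, U = V = 1
  expect_equal(chao_jaccard_similarity(c(5, 3, 4), c(5, 3, 4)), 1)
  expect_equal(chao_jaccard_similarity(c(2, 0), c(0, 7)), 0)
  # A = {s1:3, s2:1}, B = {s1:2, s3:2}: U_A = 3/4, U_B = 1/2 (no shared
  # singletons so the correction vanishes), J = 0.375/0.875
  expect_equal(chao_jaccard_similarity(c(3, 1, 0), c(2, 0, 2)), 3 / 7)
})

test_that("Chao similarity is symmetric, bounded, and agrees with vegan", {
  has_vegan <- requireNamespace("vegan", quietly = TRUE)
  set.seed(5)
  for (i in 1:200) {
    a <- rpois(8, runif(1, 0.5, 3)); b <- rpois(8, runif(1, 0.5, 3))
    if (sum(a) == 0 || sum(b) == 0) next
    j1 <- chao_jaccard_similarity(a, b)
    expect_identical(j1, chao_jaccard_similarity(b, a))
    expect_gte(j1, 0); expect_lte(j1, 1)
    if (has_vegan) {
      expect_equal(j1, 1 - as.numeric(vegan::vegdist(rbind(a, b), method = "chao")),
                   tolerance = 1e-12)
    }
  }
})

test_that("niche overlap averages pairwise similarities at each level", {
  ident <- matrix(c(4, 3, 4, 3), 2, dimnames = list(c("p1", "p2"), c("v1", "v2")))
  expect_equal(niche_overlap(ident, "visitor"), 1)
  disjoint <- matrix(c(2, 0, 0, 3), 2, dimnames = list(c("p1", "p2"), c("v1", "v2")))
  expect_equal(niche_overlap(disjoint, "visitor"), 0)
  expect_error(niche_overlap(matrix(1:2, 2, 1, dimnames = list(c("a", "b"), "v")),
                             "visitor"),
               class = "sexnest_undefined_metric")
  set.seed(9)
  for (i in 1:25) {
    m <- random_count_matrix(sample(3:7, 1), sample(3:7, 1))
    expect_equal(niche_overlap(m, "visitor"), oracle_niche_overlap(m, "visitor"),
                 tolerance = 1e-12)
    expect_equal(niche_overlap(m, "plant"), oracle_niche_overlap(m, "plant"),
                 tolerance = 1e-12)
  }
})

test_that("Shannon entropy and partner diversity match hand arithmetic", {
  expect_equal(shannon_entropy(7), 0)
  expect_equal(shannon_entropy(rep(3, 6)), log(6))
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.0397207708399179)
  expect_error(shannon_entropy(c(0, 0)), class = "sexnest_undefined_metric")

  # every species one partner: zero everywhere
  expect_equal(partner_diversity(diag(4) * 3, "visitor"), 0)
  # single plant visited evenly by k visitors
  uni <- matrix(2, 1, 5, dimnames = list("p", paste0("v", 1:5)))
  expect_equal(partner_diversity(uni, "plant"), log(5))
  # [[2,1],[0,3]]: visitor level (2*0 + 4*H(1/4,3/4))/6; plant level
  # (3*H(2/3,1/3) + 3*0)/6
  m <- matrix(c(2, 0, 1, 3), 2, dimnames = list(c("p1", "p2"), c("v1", "v2")))
  H13 <- -(0.25 * log(0.25) + 0.75 * log(0.75))
  H23 <- -((2 / 3) * log(2 / 3) + (1 / 3) * log(1 / 3))
  expect_equal(partner_diversity(m, "visitor"), 4 * H13 / 6)
  expect_equal(partner_diversity(m, "plant"), 3 * H23 / 6)
})

test_that("partner diversity levels differ by a margins-only constant", {
  set.seed(21)
  for (i in 1:30) {
    m <- random_count_matrix(sample(2:8, 1), sample(2:8, 1))
    S <- sum(m)
    lhs <- S * partner_diversity(m, "visitor") - S * partner_diversity(m, "plant")
    rhs <- sum(colSums(m) * log(colSums(m))) - sum(rowSums(m) * log(rowSums(m)))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("all indices are invariant to row and column permutations", {
  set.seed(33)
  reg <- metric_registry()
  for (i in 1:20) {
    m <- random_count_matrix(sample(3:6, 1), sample(3:6, 1))
    p <- m[sample(nrow(m)), sample(ncol(m))]
    for (f in reg) expect_equal(f(p), f(m), tolerance = 1e-12)
  }
})

test_that("network_metrics reports the full panel with NA where undefined", {
  tab <- network_metrics(nested_toy())
  expect_setequal(tab$metric, names(metric_registry()))
  expect_equal(tab$value[tab$metric == "wnodf"], 100)
  narrow <- matrix(c(1, 2), 2, 1, dimnames = list(c("p1", "p2"), "v1"))
  tab2 <- network_metrics(narrow)
  expect_true(is.na(tab2$value[tab2$metric == "wnodf"]))
  expect_true(is.na(tab2$value[tab2$metric == "niche_overlap_visitor"]))
  expect_equal(tab2$value[tab2$metric == "network_size"], 3)
})
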