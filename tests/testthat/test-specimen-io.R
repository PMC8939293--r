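test_that("read_records parses delimited files and normalizes sex labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tsex\tplant\tsite\tyear\tnote",
               "Apis mellifera\tF\tTaraxacum officinale\tKibune\t1984\tx",
               "Bombus sp.\tM\tErigeron philadelphicus\tKibune\t1984\ty",
               "Eristalis tenax\t?\tTaraxacum officinale\tAshu\t1985\tz"),
             path)
  cmap <- list(visitor_taxon = "species", sex = "sex", plant_taxon = "plant",
               site = "site", year = "year")
  rec <- read_records(path, cmap)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$sex, c("female", "male", "unknown"))
  expect_equal(rec$visitor_taxon[2], "Bombus sp.")
  expect_equal(rec$year, c(1984L, 1984L, 1985L))
  expect_false("note" %in% names(rec))

  # CSV with default column names
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("visitor_taxon,sex,plant_taxon,site,year",
               "V1,female,P1,S,2001"), csv)
  expect_equal(read_records(csv)$plant_taxon, "P1")

  expect_error(read_records(path, list(sex = "gender")),
               "gender", class = "sexnest_config_error")
  expect_error(read_records("no/such/file.tsv"), class = "sexnest_io_error")
})

test_that("filter_records discards incomplete records with per-reason counts", {
  rec <- rbind(
    toy_records(list(list("V1", "female", "P1"), list("V2", "male", "P2"))),
    data.frame(visitor_taxon = "V3", sex = "unknown", plant_taxon = "P1",
               site = "SiteA", year = 1984L),
    data.frame(visitor_taxon = "V4", sex = "female", plant_taxon = "",
               site = "SiteA", year = 1984L),
    data.frame(visitor_taxon = "V5", sex = "male", plant_taxon = "P2",
               site = "SiteA", year = NA_integer_)
  )
  out <- filter_records(rec)
  expect_equal(nrow(out$records), 2L)
  expect_equal(unname(out$report[c("sex_unidentified", "no_plant", "no_year")]),
               c(1L, 1L, 1L))
  expect_equal(unname(out$report["kept"]), 2L)
  expect_equal(sum(out$report[c("no_visitor_taxon", "sex_unidentified",
                                "no_plant", "no_site", "no_year")]),
               unname(out$report["input"] - out$report["kept"]))
  # genus-level labels are retained as morphospecies
  sp <- filter_records(toy_records(list(list("Lasioglossum sp.", "female", "P1"))))
  expect_equal(sp$records$visitor_taxon, "Lasioglossum sp.")
})

test_that("partition_by_origin groups records by site and year exhaustively", {
  rec <- rbind(toy_records(list(list("V1", "female", "P1")), "A", 2001L),
               toy_records(list(list("V1", "male", "P1")), "A", 2002L),
               toy_records(list(list("V2", "female", "P2")), "B", 2001L),
               toy_records(list(list("V2", "male", "P2")), "B", 2002L))
  gr <- partition_by_origin(rec)
  expect_length(gr, 4L)
  expect_equal(sum(vapply(gr, nrow, integer(1))), nrow(rec))
  expect_setequal(names(gr), c("A:2001", "A:2002", "B:2001", "B:2002"))
  one <- partition_by_origin(rec[1, ])
  expect_length(one, 1L)
  expect_equal(one[[1]], rec[1, ], ignore_attr = TRUE)
})

test_that("build_matrix counts interactions under the sex filter", {
  rec <- toy_records(list(list("V1", "female", "P1"), list("V1", "female", "P1"),
                          list("V2", "male", "P2"), list("V2", "male", "P1")))
  f <- build_matrix(rec, "female")
  expect_equal(dim(f), c(1L, 1L))
  expect_equal(unclass(f)[1, 1], 2L, ignore_attr = TRUE)
  expect_equal(rownames(f), "P1")
  s <- build_matrix(rec, "species")
  expect_equal(dim(s), c(2L, 2L))
  expect_equal(sum(s), 4L)
  expect_equal(attr(s, "site"), "SiteA")
  single <- build_matrix(rec[1, ], "species")
  expect_equal(unclass(single), matrix(1L, 1, 1, dimnames = list("P1", "V1")),
               ignore_attr = TRUE)
  expect_error(build_matrix(rec[rec$sex == "male", ], "female"),
               "empty network", class = "sexnest_empty_network")
})

test_that("female and male subnetworks decompose the species network", {
  set.seed(11)
  study <- generate_study(toy_synth_config())
  for (g in study) {
    s <- build_matrix(g, "species")
    f <- build_matrix(g, "female")
    m <- build_matrix(g, "male")
    expect_equal(sum(f) + sum(m), sum(s))
    expect_equal(sum(s), nrow(g))
    # aligned cells sum; sex submatrices sit inside the species network
    for (sub in list(f, m)) {
      expect_true(all(rownames(sub) %in% rownames(s)))
      expect_true(all(colnames(sub) %in% colnames(s)))
      expect_true(all(unclass(s)[rownames(sub), colnames(sub)] >= unclass(sub)))
    }
    aligned <- matrix(0L, nrow(s), ncol(s), dimnames = dimnames(s))
    for (sub in list(f, m)) {
      aligned[rownames(sub), colnames(sub)] <-
        aligned[rownames(sub), colnames(sub)] + unclass(sub)
    }
    expect_equal(aligned, unclass(s), ignore_attr = TRUE)
  }
})

test_that("sex_composition partitions visitor species into three categories", {
  rec <- toy_records(list(list("V1", "female", "P1"), list("V1", "female", "P2"),
                          list("V2", "male", "P1"),
                          list("V3", "female", "P1"), list("V3", "male", "P1")))
  sc <- sex_composition(rec)
  expect_equal(unname(sc$counts), c(1L, 1L, 1L))
  expect_equal(unname(sc$proportions), rep(1 / 3, 3))
  expect_equal(sum(sc$counts), sc$n_species)

  allf <- sex_composition(toy_records(list(list("V1", "female", "P1"),
                                           list("V2", "female", "P2"))))
  expect_equal(unname(allf$proportions), c(1, 0, 0))

  # a singleton species is necessarily single-sex
  single <- sex_composition(toy_records(list(list("V9", "male", "P1"))))
  expect_equal(unname(single$counts["both"]), 0L)
})

test_that("matrix TSV round-trips bit-exactly", {
  set.seed(3)
  m <- interaction_matrix(random_count_matrix(5, 7), site = "A", year = 2001L,
                          network_type = "female")
  storage.mode(m) <- "integer"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_matrix_tsv(path, site = "A", year = 2001L, network_type = "female")
  expect_identical(unclass(back)[, , drop = FALSE],
                   unclass(m)[, , drop = FALSE])
  expect_identical(dimnames(back), dimnames(m))
})
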