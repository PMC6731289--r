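test_that("abundance/annotation TSVs round-trip and share a feature universe", {
  dir <- withr::local_tempdir()
  ab <- file.path(dir, "ab.tsv"); an <- file.path(dir, "an.tsv")
  writeLines(c("feature_id\tBP01:1\tBP01:2",
               "pg1\t1.5\t0", "pg2\t2\t3", "pg3\t0.5\t1"), ab)
  writeLines(c("feature_id\tspecies_id\tspecies_name\tfamily\tko_ids\tec_ids",
               "pg1\tS0001\tsp one\tfamA\tK00001;K00002\t1.1.1.1",
               "pg2\tS0002\tsp two\tfamB\t\t"), an)
  expect_warning(read_abundance_table(ab, an), "lack annotation")
  res <- suppressWarnings(read_abundance_table(ab, an))
  expect_equal(dim(res$matrix), c(3L, 2L))
  expect_equal(res$matrix$values["pg2", "BP01:2"], 3)
  expect_equal(res$matrix$plant, c("BP01:1" = "BP01", "BP01:2" = "BP01"))
  # unannotated feature retained with empty annotation
  expect_true("pg3" %in% res$annotation$feature_id)
  expect_equal(res$annotation$species_id[res$annotation$feature_id == "pg3"], "")

  # annotation row without abundance is dropped with a warning
  writeLines(c("feature_id\tspecies_id\tspecies_name\tfamily\tko_ids\tec_ids",
               "pg1\tS0001\tsp one\tfamA\t\t",
               "pg2\tS0002\tsp two\tfamB\t\t",
               "pg3\tS0003\tsp three\tfamB\t\t",
               "pg9\tS0009\tghost\tfamC\t\t"), an)
  expect_warning(read_abundance_table(ab, an), "without abundance")
})

test_that("malformed inputs are rejected with informative errors", {
  dir <- withr::local_tempdir()
  ab <- file.path(dir, "ab.tsv"); an <- file.path(dir, "an.tsv")
  writeLines(c("feature_id\tspecies_id\tspecies_name\tfamily\tko_ids\tec_ids",
               "pg1\tS0001\tsp\tf\t\t"), an)
  writeLines(c("feature_id\tBP01:1", "pg1\t-2"), ab)
  expect_error(read_abundance_table(ab, an), "negative abundance.*pg1")
  writeLines(c("id\tBP01:1", "pg1\t2"), ab)
  expect_error(read_abundance_table(ab, an), "line 1")
  writeLines(c("feature_id\tsampleX", "pg1\t2"), ab)
  expect_error(read_abundance_table(ab, an), "plant:replicate")
  writeLines(c("feature_id\tBP01:1", "pg1\t2", "pg1\t3"), ab)
  expect_error(read_abundance_table(ab, an), "duplicate feature_id")
})

test_that("replicate-presence filter keeps a feature if any plant passes", {
  # plant A: nonzero in 3/5; plant B: all zero -> kept globally
  v <- rbind(f1 = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
             f2 = c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0),  # 2/5 in both plants
             f3 = rep(0, 10),
             f4 = rep(1, 10))
  colnames(v) <- paste0(rep(c("A", "B"), each = 5), ":", rep(1:5, 2))
  m <- make_am(v)
  out <- filter_replicate_presence(m, min_present = 3)
  expect_setequal(rownames(out$values), c("f1", "f4"))
  expect_setequal(attr(out, "removed"), c("f2", "f3"))
  # per-plant masking zeroes the failing plant but keeps the feature
  masked <- filter_replicate_presence(m, 3, per_plant = TRUE)
  expect_equal(unname(masked$values["f1", 6:10]), rep(0, 5))
})

test_that("raising the presence threshold never adds features", {
  set.seed(42)
  v <- matrix(rbinom(30 * 20, 1, 0.4) * runif(600), 30, 20)
  colnames(v) <- paste0(rep(paste0("P", 1:4), each = 5), ":", rep(1:5, 4))
  rownames(v) <- paste0("f", 1:30)
  m <- make_am(v)
  prev <- rownames(v)
  for (k in 1:5) {
    kept <- rownames(filter_replicate_presence(m, k)$values)
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("normalization forces column totals and is idempotent", {
  m <- make_am(matrix(c(1, 1, 2, 5, 0, 5), 3, 2))
  n1 <- normalize_relative(m)
  expect_equal(unname(n1$values[, 1]), c(25, 25, 50))
  expect_equal(unname(colSums(n1$values)), c(100, 100))
  n2 <- normalize_relative(n1)
  expect_equal(n1$values, n2$values)
  set.seed(1)
  r <- make_am(matrix(runif(12, 0.1, 5), 4, 3))
  expect_equal(normalize_relative(normalize_relative(r))$values,
               normalize_relative(r)$values)
  bad <- make_am(matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(normalize_relative(bad), "all-zero sample")
})

test_that("aggregation sums members, handles multi-KO and conserves totals", {
  v <- matrix(c(2, 4, 3, 6, 4, 8), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("A:1", "A:2")))
  m <- make_am(v)
  ann <- data.frame(
    feature_id = c("p1", "p2", "p3"),
    species_id = c("S0001", "S0001", ""), species_name = c("x", "x", ""),
    family = c("famA", "famA", ""),
    ko_ids = c("K00001;K00002", "K00001", ""), ec_ids = "",
    stringsAsFactors = FALSE)
  sp <- aggregate_features(m, ann, "species")
  expect_equal(unname(sp$values["S0001", ]), c(5, 10))      # 2 + 3
  expect_true("unassigned" %in% rownames(sp$values))
  expect_equal(colSums(sp$values), colSums(m$values))        # conservation
  ko <- aggregate_features(m, ann, "ko")
  expect_equal(unname(ko$values["K00002", ]), c(2, 4))       # full abundance
  expect_equal(unname(ko$values["K00001", ]), c(5, 10))
  kos <- aggregate_features(m, ann, "ko", multi_ko = "split")
  expect_equal(unname(kos$values["K00002", ]), c(1, 2))      # evenly split
})

test_that("plant means average replicates and renormalize", {
  v <- matrix(c(10, 30, 20, 40), 2, 2,
              dimnames = list(c("f1", "f2"), c("A:1", "A:2")))
  m <- make_am(v)
  pm <- plant_means(m, renormalize = TRUE)
  expect_equal(unname(pm$values[, "A"]), c(30, 70))  # means 15,35 scaled
  raw <- plant_means(m, renormalize = FALSE)
  expect_equal(unname(raw$values[, "A"]), c(15, 35))
  # identical replicates: mean equals any single one
  v2 <- cbind("B:1" = c(3, 7), "B:2" = c(3, 7))
  rownames(v2) <- c("f1", "f2")
  expect_equal(unname(plant_means(make_am(v2), FALSE)$values[, "B"]), c(3, 7))
})
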