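test_that("simulation is deterministic and closed to 100", {
  cfg <- simulation_config(n_plants = 4, n_replicates = 3, n_species = 8,
                           F_true = c(0.1, 0.2, 4, 1), seed = 21,
                           planted_edges = data.frame(
                             a = 1L, b = 2L, sign = 1L, rho = 0.9),
                           metadata_links = no_links(), bulk_species = 3)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$metadata, s2$metadata)
  expect_equal(unname(colSums(s1$matrix$values)), rep(100, 12),
               tolerance = 1e-9)
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the data
  s3 <- simulate_dataset(simulation_config(
    n_plants = 4, n_replicates = 3, n_species = 8,
    F_true = c(0.1, 0.2, 4, 1), seed = 22,
    planted_edges = data.frame(a = 1L, b = 2L, sign = 1L, rho = 0.9),
    metadata_links = no_links(), bulk_species = 3))
  expect_false(identical(s1$matrix$values, s3$matrix$values))
})

test_that("simulated TSVs round-trip through the reader", {
  sim <- simulate_dataset(simulation_config(
    n_plants = 3, n_replicates = 3, n_species = 6, F_true = 0.2,
    planted_edges = no_edges(), metadata_links = no_links(),
    bulk_species = 2, seed = 9))
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  rd <- read_abundance_table(file.path(d, "abundance.tsv"),
                             file.path(d, "annotation.tsv"))
  expect_equal(dim(rd$matrix), dim(sim$matrix))
  expect_equal(rd$matrix$values, sim$matrix$values, tolerance = 1e-8)
  expect_setequal(rd$annotation$feature_id, sim$annotation$feature_id)
})

test_that("noiseless plants classify exactly as the planted F", {
  cfg <- simulation_config(n_plants = 6, n_replicates = 3, n_species = 8,
                           F_true = c(0.1, 0.39, 0.5, 1, 2.6, 8),
                           noise_sd = 0, dropout_prob = 0,
                           planted_edges = no_edges(),
                           metadata_links = no_links(), seed = 2)
  sim <- simulate_dataset(cfg)
  ko <- aggregate_features(sim$matrix, sim$annotation, "ko")
  calls <- classify_units(ko, mode = "per_plant")
  expect_equal(calls$label[match(sim$truth$plants$plant_id, calls$unit_id)],
               sim$truth$plants$label_true)
  # per-replicate F equals F_true exactly (no noise, closure cancels)
  per_rep <- classify_units(ko, mode = "per_replicate")
  f_expect <- sim$truth$plants$F_true[
    match(sub(":.*", "", per_rep$unit_id), sim$truth$plants$plant_id)]
  expect_equal(per_rep$F, f_expect, tolerance = 1e-9)
})

test_that("planted pairs realize strong rank correlations", {
  sim <- benchmark_sim(seed = 1)
  sp <- normalize_relative(
    aggregate_features(sim$matrix, sim$annotation, "species"), 100)
  tr <- sim$truth$edges
  rho <- vapply(seq_len(nrow(tr)), function(i)
    cor(sp$values[tr$a[i], ], sp$values[tr$b[i], ], method = "spearman"),
    numeric(1))
  expect_true(all(sign(rho) == tr$sign))
  # self-check on the ten co-presence pairs: at least 90% realize
  # Spearman >= 0.6 at 40 replicates
  expect_gte(mean(rho[tr$sign > 0] >= 0.6), 0.9)
  expect_true(all(abs(rho) >= 0.4))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_species = 4, planted_edges = data.frame(
    a = 1L, b = 9L, sign = 1L, rho = 0.9)), "beyond n_species")
  expect_error(simulation_config(n_species = 10, planted_edges = data.frame(
    a = c(1L, 1L), b = c(2L, 3L), sign = 1L, rho = 0.9)),
    "at most one planted edge")
  expect_error(simulation_config(F_true = c(1, -2), n_plants = 2))
})

test_that("recovery metrics are exact on perfect and empty results", {
  truth <- list(
    plants = data.frame(plant_id = c("BP01", "BP02"),
                        F_true = c(0.1, 5),
                        label_true = c("hydrogenotrophic", "acetoclastic")),
    edges = data.frame(a = "S0001", b = "S0002", pair = "S0001--S0002",
                       sign = 1L, rho = 0.9),
    metadata_links = data.frame(species_id = "S0003",
                                variable = "temperature", direction = 1L))
  calls <- data.frame(unit_id = c("BP01", "BP02"),
                      label = c("hydrogenotrophic", "acetoclastic"))
  net <- data.frame(a = "S0001", b = "S0002", pair = "S0001--S0002",
                    direction = "copresence")
  screen <- data.frame(feature_key = "S0003", variable = "temperature",
                       rho = 0.9, p = 0.001, significant = TRUE)
  r <- recovery_report(truth, calls = calls, network = net, screen = screen)
  expect_equal(r$label_accuracy, 1)
  expect_equal(r$edge_recall, 1)
  expect_equal(r$edge_precision, 1)
  expect_equal(r$metadata_link_recall, 1)
  # empty network against nonempty truth: zero recall
  r0 <- recovery_report(truth, network = net[0, ])
  expect_equal(r0$edge_recall, 0)
  # wrong sign counts as a miss
  net_wrong <- transform(net, direction = "exclusion")
  expect_equal(recovery_report(truth, network = net_wrong)$edge_recall, 0)
})
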