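mk_scores <- function(pairs, scores, directions, method = "pearson") {
  ab <- do.call(rbind, strsplit(pairs, "--"))
  data.frame(a = ab[, 1], b = ab[, 2], pair = pairs, method = method,
             score = scores, null_value = 0, direction = directions,
             stringsAsFactors = FALSE)
}

test_that("candidate selection takes top/bottom with lexicographic ties", {
  sc <- mk_scores(c("a--b", "a--c", "a--d", "b--c", "b--d", "c--d"),
                  c(0.9, 0.8, 0.5, -0.7, -0.5, 0.5),
                  c("copresence", "copresence", "copresence",
                    "exclusion", "exclusion", "copresence"))
  out <- select_candidates(sc, n_top = 3, n_bottom = 1)
  expect_equal(sum(out$direction == "copresence"), 3)
  expect_equal(sum(out$direction == "exclusion"), 1)
  # tie at 0.5 between a--d and c--d at the rank boundary: a--d wins
  expect_true("a--d" %in% out$pair)
  expect_false("c--d" %in% out$pair)
  expect_true("b--c" %in% out$pair)   # strongest exclusion
  # more requested than available: everything returned
  all_out <- select_candidates(sc, n_top = 100, n_bottom = 100)
  expect_equal(nrow(all_out), 6)
})

test_that("dissimilarity candidates rank small values as strong co-presence", {
  sc <- mk_scores(c("a--b", "a--c", "b--c"), c(0.1, 0.4, 0.8),
                  c("copresence", "copresence", "exclusion"),
                  method = "braycurtis")
  out <- select_candidates(sc, n_top = 1, n_bottom = 1)
  expect_setequal(out$pair, c("a--b", "b--c"))
})

test_that("support filter requires agreeing methods and majority direction", {
  cand <- rbind(
    mk_scores(rep("a--b", 5), c(.9, .8, .7, .2, .3),
              c(rep("copresence", 3), rep("exclusion", 2)),
              method = NA)[, ],
    mk_scores("a--c", .5, "copresence"),
    mk_scores("a--c", .5, "copresence", method = "spearman"),
    mk_scores(rep("b--c", 5), rep(.9, 5), rep("copresence", 5)))
  cand$method[1:5] <- c("pearson", "spearman", "kendall", "braycurtis", "kl")
  cand$method[8:12] <- c("pearson", "spearman", "kendall", "braycurtis", "kl")
  out <- support_filter(cand, min_support = 3)
  ab <- out[out$pair == "a--b", ]
  expect_equal(ab$direction, "copresence")   # 3 vs 2 majority
  expect_equal(ab$support, 3L)
  expect_false("a--c" %in% out$pair)         # only 2 methods
  expect_equal(out$support[out$pair == "b--c"], 5L)
  # direction tie drops the edge
  tie <- mk_scores(rep("x--y", 4), c(.9, .8, .2, .1),
                   rep(c("copresence", "exclusion"), each = 2))
  tie$method <- c("pearson", "spearman", "kendall", "kl")
  expect_equal(nrow(support_filter(tie, 2)), 0)
})

test_that("bootstrap p-values are deterministic and handle degeneracy", {
  v <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12),
             c = c(6, 1, 5, 2, 4, 3))
  colnames(v) <- paste0("A:", 1:6)
  m <- make_am(v)
  # perfectly correlated pair: all bootstrap scores 1, sigma 0, p 0
  r <- bootstrap_pvalue(m, "a", "b", "pearson", iterations = 50, seed = 5)
  expect_equal(r$score, 1)
  expect_equal(r$sigma, 0)
  expect_equal(r$p, 0)
  r1 <- bootstrap_pvalue(m, "a", "c", "spearman", iterations = 50, seed = 9)
  r2 <- bootstrap_pvalue(m, "a", "c", "spearman", iterations = 50, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_true(r1$p > 0 && r1$p <= 1)
  r3 <- bootstrap_pvalue(m, "a", "c", "spearman", iterations = 50, seed = 10)
  expect_false(identical(r1$p, r3$p))
  # dissimilarities use a permutation-mean null value
  rb <- bootstrap_pvalue(m, "a", "c", "braycurtis", iterations = 50, seed = 5)
  expect_gt(rb$null_value, 0)
})

test_that("Brown's method has the Fisher and total-dependence limits", {
  p <- c(pearson = 0.03, spearman = 0.2, kendall = 0.07)
  k <- length(p)
  fisher <- pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
  expect_equal(brown_merge(p, diag(0, k)), fisher, tolerance = 1e-12)
  expect_equal(brown_merge(p), fisher, tolerance = 1e-12)  # default indep.
  # perfect dependence: all methods share one p; cov(-2 log p) = 4
  shared <- c(a = 0.042, b = 0.042, c = 0.042, d = 0.042)
  cm <- matrix(4, 4, 4, dimnames = list(names(shared), names(shared)))
  expect_equal(brown_merge(shared, cm), 0.042, tolerance = 1e-10)
  expect_equal(brown_merge(c(x = 0.123)), 0.123, tolerance = 1e-12)
  expect_silent(pz <- brown_merge(c(a = 0, b = 0.5), diag(0, 2)))
  expect_true(pz >= 0)
})

test_that("BH adjustment matches the hand-computed step-up", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(out$q, rep(0.04, 4))
  expect_true(all(out$keep))
  single <- bh_adjust(0.03)
  expect_equal(single$q, 0.03)
  set.seed(2)
  p <- runif(50)
  k1 <- sum(bh_adjust(p, 0.10)$keep)
  k2 <- sum(bh_adjust(p, 0.05)$keep)
  expect_lte(k2, k1)   # shrinking alpha never enlarges the keep set
})

test_that("network inference is deterministic and structurally sound", {
  sim <- simulate_dataset(simulation_config(
    n_plants = 1, n_replicates = 20, n_species = 10, F_true = 0.1,
    planted_edges = data.frame(a = c(1, 3), b = c(2, 4),
                               sign = c(1L, -1L), rho = 0.9),
    metadata_links = no_links(), bulk_species = 4, seed = 8))
  sp <- normalize_relative(
    aggregate_features(sim$matrix, sim$annotation, "species"), 100)
  cfgn <- network_config(seed = 3)
  n1 <- infer_network(sp, cfgn)
  n2 <- infer_network(sp, cfgn)
  expect_identical(n1$edges, n2$edges)
  # retained edges are a subset of support-filtered candidates
  expect_true(all(n1$edges$pair %in% n1$tested$pair))
  expect_true(all(n1$edges$q < cfgn$alpha))
  expect_true(all(n1$edges$support >= cfgn$min_support))
  g <- n1$graph
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  # the two strongly planted pairs come out with the right sign
  rr <- recovery_report(sim$truth, network = n1)
  expect_equal(rr$edge_recall, 1)
  expect_error(infer_network(make_am(matrix(1:4, 2, 2)), cfgn),
               "at least 3")
})
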