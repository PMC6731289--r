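#' Select top/bottom candidate edges per method
#'
#' For one method's score table, ranks co-presence-direction pairs by the
#' strength of their co-presence signal (largest positive correlation;
#' smallest dissimilarity) and exclusion-direction pairs by exclusion
#' strength (most negative correlation; largest dissimilarity), and keeps
#' the `n_top` / `n_bottom` strongest of each. Ties at a rank boundary are
#' broken lexicographically by pair id. If fewer pairs exist than
#' requested, all are taken.
#'
#' @param scores data.frame from [pairwise_scores()] (one method).
#' @param n_top,n_bottom candidate counts (the study default is 2,500
#'   each; automatically capped at the number of available pairs).
#' @return subset of `scores` flagged as candidates.
#' @export
select_candidates <- function(scores, n_top = 2500, n_bottom = 2500) {
  stopifnot(n_top >= 1, n_bottom >= 1)
  if (!nrow(scores)) return(scores)
  method <- scores$method[1]
  strength <- if (is_dissimilarity(method)) {
    ifelse(scores$direction == "copresence", -scores$score, scores$score)
  } else {
    abs(scores$score)
  }
  pick <- function(dir, n) {
    sub <- scores[scores$direction == dir, , drop = FALSE]
    st <- strength[scores$direction == dir]
    ord <- order(-st, sub$pair)
    sub[ord[seq_len(min(n, nrow(sub)))], , drop = FALSE]
  }
  out <- rbind(pick("copresence", n_top), pick("exclusion", n_bottom))
  rownames(out) <- NULL
  out
}

#' Consensus support filter over per-method candidate sets
#'
#' An edge survives if at least `min_support` methods selected the same
#' pair with the same direction. When methods disagree on direction, the
#' majority direction is used; a direction tie drops the edge (sign
#' disagreement means no consensus interaction type).
#'
#' @param candidates data.frame, row-bound per-method outputs of
#'   [select_candidates()].
#' @param min_support minimum number of agreeing methods (study default 3
#'   of 5).
#' @return data.frame with one row per surviving edge: `a`, `b`, `pair`,
#'   `direction`, `support`, `methods` (semicolon-joined supporting
#'   methods).
#' @export
support_filter <- function(candidates, min_support = 3) {
  stopifnot(min_support >= 1)
  if (!nrow(candidates))
    return(data.frame(a = character(), b = character(), pair = character(),
                      direction = character(), support = integer(),
                      methods = character()))
  out <- lapply(split(candidates, candidates$pair), function(d) {
    tab <- table(d$direction)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NULL)  # direction tie
    dir <- names(tab)[which.max(tab)]
    sup <- d[d$direction == dir, , drop = FALSE]
    if (nrow(sup) < min_support) return(NULL)
    data.frame(a = sup$a[1], b = sup$b[1], pair = sup$pair[1],
               direction = dir, support = nrow(sup),
               methods = paste(sort(sup$method), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(a = character(), b = character(), pair = character(),
                      direction = character(), support = integer(),
                      methods = character()))
  out <- out[order(out$pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap-normal p-value for one edge under one method
#'
#' Resamples the sample columns with replacement `iterations` times,
#' recomputes the association score each time, and fits a normal
#' distribution to the bootstrap scores. The p-value is the two-sided
#' tail probability of the fitted normal beyond the method's
#' no-association value (0 for correlations; the permutation-mean
#' dissimilarity, estimated with the same iteration count from the same
#' seeded stream, for Bray-Curtis and KL), i.e. twice the tail on the
#' side opposite the observed effect, capped at 1. A degenerate bootstrap
#' (zero spread) gives p = 0 when the observed score differs from the
#' null value and p = 1 otherwise. Resamples that make a vector constant
#' under a correlation method are redrawn (at most 10 times each).
#'
#' @param m an [abundance_matrix()].
#' @param a,b feature (species) ids of the pair.
#' @param method association method.
#' @param iterations bootstrap iterations (study default 100).
#' @param seed integer seed for this (pair, method) evaluation.
#' @return list with `p`, `score` (observed), `null_value`, `mu`, `sigma`.
#' @export
bootstrap_pvalue <- function(m, a, b, method, iterations = 100, seed = 1) {
  stopifnot(iterations >= 2)
  x <- m$values[a, ]
  y <- m$values[b, ]
  n <- length(x)
  corr <- !is_dissimilarity(method)
  with_seed(seed, {
    nv <- if (corr) 0 else
      mean(vapply(seq_len(iterations), function(i)
        association_score(x, sample(y), method), numeric(1)))
    boot <- numeric(iterations)
    for (it in seq_len(iterations)) {
      for (try in seq_len(11L)) {
        if (try == 11L)
          stop("pair ", a, "--", b, " degenerate under resampling")
        idx <- sample.int(n, n, replace = TRUE)
        if (corr && (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0)) next
        boot[it] <- association_score(x[idx], y[idx], method)
        break
      }
    }
    s_obs <- association_score(x, y, method)
    mu <- mean(boot)
    sigma <- stats::sd(boot)
    p <- if (sigma == 0) {
      if (s_obs != nv) 0 else 1
    } else {
      tail1 <- if (s_obs <= nv)
        stats::pnorm(nv, mu, sigma, lower.tail = FALSE)
      else stats::pnorm(nv, mu, sigma)
      min(1, 2 * tail1)
    }
    list(p = p, score = s_obs, null_value = nv, mu = mu, sigma = sigma)
  })
}

#' Combine dependent p-values with Brown's method
#'
#' Brown's extension of Fisher's method for dependent tests: with
#' X = -2 * sum(log p_i) over k methods, E\[X\] = 2k and
#' Var\[X\] = 4k + 2 * sum_(i<j) cov_ij, where cov_ij is the covariance of
#' -2 log p_i and -2 log p_j. X / c is referred to a chi-square with
#' f = 2 E^2 / Var degrees of freedom, c = Var / (2 E). With all
#' covariances zero this is exactly Fisher's method; with perfect
#' dependence (cov_ij = 4) it returns the shared p-value.
#'
#' @param pvals named numeric vector of per-method p-values in (0, 1\];
#'   zeros are clamped to the smallest positive double.
#' @param cov_mat covariance matrix of the -2 log p statistics across
#'   methods (rows/cols named like `pvals`); defaults to independence.
#'   Off-diagonal entries are clamped to \[0, 4\].
#' @return the merged p-value.
#' @export
brown_merge <- function(pvals, cov_mat = NULL) {
  k <- length(pvals)
  stopifnot(k >= 1, all(pvals <= 1))
  if (any(pvals <= 0)) {
    bgn_log("p-value of 0 clamped for Brown merge")
    pvals <- pmax(pvals, .Machine$double.xmin)
  }
  X <- -2 * sum(log(pvals))
  covsum <- 0
  if (!is.null(cov_mat) && k > 1) {
    cm <- if (is.null(dimnames(cov_mat)) || is.null(names(pvals))) cov_mat
          else cov_mat[names(pvals), names(pvals), drop = FALSE]
    off <- cm[upper.tri(cm)]
    covsum <- sum(pmin(pmax(off, 0), 4))
  }
  E <- 2 * k
  V <- 4 * k + 2 * covsum
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  stats::pchisq(X / cc, df = f, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with a keep mask
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @param alpha significance level (edges with q < alpha are kept).
#' @return list with `q` (BH-adjusted p-values) and `keep` (logical).
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, keep = q < alpha)
}

#' Default configuration for ensemble network inference
#'
#' @param methods association methods to use.
#' @param min_prevalence minimum fraction of samples with nonzero
#'   abundance (default 0.6).
#' @param n_top,n_bottom per-method candidate counts (default 2,500 each).
#' @param min_support minimum agreeing methods (default 3).
#' @param bootstrap_iters bootstrap iterations (default 100).
#' @param alpha BH significance level (default 0.05).
#' @param seed master seed; all per-(pair, method) streams derive from it.
#' @return list of parameters for [infer_network()].
#' @export
network_config <- function(methods = ASSOC_METHODS, min_prevalence = 0.6,
                           n_top = 2500, n_bottom = 2500, min_support = 3,
                           bootstrap_iters = 100, alpha = 0.05, seed = 1) {
  list(methods = methods, min_prevalence = min_prevalence, n_top = n_top,
       n_bottom = n_bottom, min_support = min_support,
       bootstrap_iters = bootstrap_iters, alpha = alpha, seed = seed)
}

#' Ensemble co-occurrence network inference
#'
#' Full inference chain on a species-level replicate table (all replicates
#' of one methanogenic-pathway class): prevalence filter, pairwise scores
#' under each method, per-method top/bottom candidate selection, consensus
#' support filter, bootstrap-normal p-value per surviving (pair, method),
#' Brown merge of the per-method p-values (with the covariance of the
#' -2 log p statistics estimated empirically, pooled across all tested
#' edges), and Benjamini-Hochberg control. The result is an undirected
#' simple graph whose edges carry a co-presence/exclusion sign.
#'
#' @param m an [abundance_matrix()], rows = species, columns = replicates,
#'   relative abundances.
#' @param config list from [network_config()].
#' @return object of class `cooccurrence_network`: list with `graph` (an
#'   igraph with edge attributes `sign`, `support`, `p_brown`, `q`),
#'   `edges` (data.frame of retained edges), `tested` (all
#'   support-filtered candidates with per-method p-values, merged p and
#'   q), `config`, and `n_species` after the prevalence filter.
#' @export
infer_network <- function(m, config = network_config()) {
  if (ncol(m$values) < 3) stop("need at least 3 replicate samples")
  mf <- prevalence_filter(m, config$min_prevalence)
  cand <- do.call(rbind, lapply(config$methods, function(meth) {
    sc <- pairwise_scores(mf, meth, n_perm = config$bootstrap_iters,
                          seed = config$seed)
    select_candidates(sc, config$n_top, config$n_bottom)
  }))
  edges <- support_filter(cand, config$min_support)
  empty <- function() {
    g <- igraph::make_empty_graph(n = nrow(mf$values), directed = FALSE)
    igraph::V(g)$name <- rownames(mf$values)
    structure(list(graph = g, edges = edges[0, , drop = FALSE],
                   tested = edges, config = config,
                   n_species = nrow(mf$values)),
              class = "cooccurrence_network")
  }
  if (!nrow(edges)) return(empty())

  ## per-method bootstrap p for each surviving edge (supporting methods)
  pv <- matrix(NA_real_, nrow(edges), length(config$methods),
               dimnames = list(edges$pair, config$methods))
  for (i in seq_len(nrow(edges))) {
    for (meth in strsplit(edges$methods[i], ";", fixed = TRUE)[[1]]) {
      bp <- bootstrap_pvalue(mf, edges$a[i], edges$b[i], meth,
                             iterations = config$bootstrap_iters,
                             seed = derive_seed(config$seed, edges$pair[i],
                                                meth, "boot"))
      pv[i, meth] <- bp$p
    }
  }
  ## pooled empirical covariance of -2 log p across tested edges
  logp <- -2 * log(pmax(pv, .Machine$double.xmin))
  cov_mat <- stats::cov(logp, use = "pairwise.complete.obs")
  cov_mat[is.na(cov_mat)] <- 0
  merged <- vapply(seq_len(nrow(edges)), function(i) {
    p_i <- pv[i, !is.na(pv[i, ]), drop = TRUE]
    brown_merge(p_i, cov_mat)
  }, numeric(1))
  adj <- bh_adjust(merged, config$alpha)
  edges$p_brown <- merged
  edges$q <- adj$q
  for (meth in config$methods) edges[[paste0("p_", meth)]] <- pv[, meth]
  kept <- edges[adj$keep, , drop = FALSE]
  rownames(kept) <- NULL

  g <- igraph::graph_from_data_frame(
    kept[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = rownames(mf$values)))
  if (nrow(kept)) {
    igraph::E(g)$sign <- ifelse(kept$direction == "copresence", 1L, -1L)
    igraph::E(g)$support <- kept$support
    igraph::E(g)$p_brown <- kept$p_brown
    igraph::E(g)$q <- kept$q
  }
  structure(list(graph = g, edges = kept, tested = edges, config = config,
                 n_species = nrow(mf$values)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(paste0("cooccurrence_network: %d species, %d edges retained",
                     " (of %d tested candidates)\n"),
              x$n_species, nrow(x$edges), nrow(x$tested)))
  invisible(x)
}

#' Write a network edge table (and optional GraphML) to disk
#'
#' @param net a `cooccurrence_network` from [infer_network()].
#' @param path output TSV path for the edge table.
#' @param graphml_path optional path for a GraphML export of the graph.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  tab <- net$edges
  if (nrow(tab)) {
    tab$sign <- ifelse(tab$direction == "copresence", "+", "-")
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(path)
}
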