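## Association measures between two species abundance vectors across
## samples. Correlations come from stats::cor; Bray-Curtis from
## vegan::vegdist; symmetrized Kullback-Leibler is computed here on
## pseudocounted sample distributions (CoNet practice: zeros otherwise
## give infinite divergences).

KL_PSEUDOCOUNT <- 1e-6

## normalize a species vector across samples to a probability distribution
as_distribution <- function(x, eps = KL_PSEUDOCOUNT) {
  x <- x + eps
  x / sum(x)
}

kl_symmetric <- function(x, y, eps = KL_PSEUDOCOUNT) {
  p <- as_distribution(x, eps)
  q <- as_distribution(y, eps)
  (sum(p * log(p / q)) + sum(q * log(q / p))) / 2
}

bray_curtis <- function(x, y) {
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Association score between two abundance vectors
#'
#' @param x,y numeric vectors (one species each, across the same samples).
#' @param method one of `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"braycurtis"`, `"kl"`.
#' @return a single numeric score (correlation in \[-1, 1\], Bray-Curtis
#'   in \[0, 1\], symmetrized KL >= 0).
#' @export
association_score <- function(x, y, method) {
  switch(method,
         pearson = stats::cor(x, y, method = "pearson"),
         spearman = stats::cor(x, y, method = "spearman"),
         kendall = stats::cor(x, y, method = "kendall"),
         braycurtis = bray_curtis(x, y),
         kl = kl_symmetric(x, y),
         stop("unknown method: ", method))
}

ASSOC_METHODS <- c("pearson", "spearman", "kendall", "braycurtis", "kl")
is_dissimilarity <- function(method) method %in% c("braycurtis", "kl")

## Null (no-association) reference value of a measure for a given pair:
## 0 for correlations; for dissimilarities the mean over random
## permutations of one member (least-assumption null point).
dissimilarity_null_mean <- function(x, y, method, n_perm = 100, seed = 1) {
  with_seed(seed, {
    mean(vapply(seq_len(n_perm), function(i)
      association_score(x, sample(y), method), numeric(1)))
  })
}

#' All pairwise association scores under one method
#'
#' Computes the method's score for every unordered pair of features
#' (species) and the co-presence/exclusion direction: positive
#' correlation means co-presence, negative means exclusion; a
#' dissimilarity below its permutation-mean null value means co-presence,
#' above means exclusion. Pairs whose score is undefined (a constant
#' vector under a correlation method) are skipped with a message.
#'
#' @param m an [abundance_matrix()] (rows = species, relative abundances).
#' @param method association method, see [association_score()].
#' @param n_perm permutations used to estimate the dissimilarity null
#'   value.
#' @param seed master seed for the permutation null (per-pair substreams
#'   are derived deterministically).
#' @return data.frame with columns `a`, `b`, `pair`, `method`, `score`,
#'   `null_value`, `direction`.
#' @export
pairwise_scores <- function(m, method, n_perm = 100, seed = 1) {
  vals <- m$values
  if (ncol(vals) < 3) stop("need at least 3 samples")
  ids <- rownames(vals)
  n <- length(ids)
  if (n < 2) return(data.frame())
  idx <- utils::combn(n, 2)
  res <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    x <- vals[i, ]; y <- vals[j, ]
    if (!is_dissimilarity(method) &&
        (stats::sd(x) == 0 || stats::sd(y) == 0)) {
      bgn_log("constant vector: skipping pair ", ids[i], "--", ids[j],
              " under ", method)
      next
    }
    s <- association_score(x, y, method)
    if (is.na(s)) next
    if (is_dissimilarity(method)) {
      nv <- dissimilarity_null_mean(
        x, y, method, n_perm,
        seed = derive_seed(seed, ids[i], ids[j], method, "null"))
      dir <- if (s <= nv) "copresence" else "exclusion"
    } else {
      nv <- 0
      dir <- if (s >= 0) "copresence" else "exclusion"
    }
    res[[k]] <- data.frame(a = ids[i], b = ids[j],
                           pair = pair_id(ids[i], ids[j]),
                           method = method, score = s, null_value = nv,
                           direction = dir, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(a = character(), b = character(),
                                      pair = character(), method = character(),
                                      score = numeric(), null_value = numeric(),
                                      direction = character())
  rownames(out) <- NULL
  out
}

#' Prevalence filter for network input
#'
#' Keeps species nonzero in at least `ceiling(min_fraction * n_samples)`
#' samples of the replicate set (e.g. 60% of 40, 25 and 15 replicates
#' means 24, 15 and 9 observations).
#'
#' @param m an [abundance_matrix()].
#' @param min_fraction minimum fraction of samples with nonzero abundance.
#' @return filtered `abundance_matrix` with attribute `"n_removed"`.
#' @export
prevalence_filter <- function(m, min_fraction = 0.6) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(m$values))
  keep <- rowSums(m$values > 0) >= need
  bgn_log(sum(!keep), " species below ", min_fraction * 100,
          "% prevalence removed (need ", need, " observations)")
  out <- am_subset_features(m, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}
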