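#' Mean-abundance floor
#'
#' Keeps rows whose mean relative abundance across samples is at least
#' `min_mean` percent (inclusive). Used to reduce complexity before the
#' environmental correlation screen.
#'
#' @param m an [abundance_matrix()] normalized to 100 per sample.
#' @param min_mean minimum mean abundance in percent (default 0.1).
#' @return filtered `abundance_matrix`.
#' @export
abundance_floor <- function(m, min_mean = 0.1) {
  keep <- rowMeans(m$values) >= min_mean
  am_subset_features(m, keep)
}

#' Spearman screen of abundances against process parameters
#'
#' Rank correlation of each feature (taxon or function at a chosen
#' aggregation level) against each numeric metadata variable. Replicates
#' share their plant's metadata; with `use = "replicates"` the
#' correlation runs across all samples, with `use = "plant_means"`
#' across per-plant mean profiles. Ties get average ranks; constant
#' features or variables are excluded with a message.
#'
#' @param m an [abundance_matrix()].
#' @param meta data.frame of plant metadata with a `plant_id` column and
#'   numeric variables.
#' @param alpha significance level on the raw p-value (default 0.01).
#' @param use `"replicates"` or `"plant_means"`.
#' @param adjust optional multiple-testing method for [stats::p.adjust()]
#'   (e.g. "BH"); `"none"` (default) reproduces a raw-p screen.
#' @return data.frame: `feature_key`, `variable`, `rho`, `p`,
#'   `significant`.
#' @export
spearman_screen <- function(m, meta, alpha = 0.01,
                            use = c("replicates", "plant_means"),
                            adjust = "none") {
  use <- match.arg(use)
  stopifnot("plant_id" %in% names(meta))
  if (use == "plant_means") m <- plant_means(m, renormalize = TRUE)
  idx <- match(m$plant, meta$plant_id)
  if (anyNA(idx)) stop("metadata missing for plant(s): ",
                       paste(unique(m$plant[is.na(idx)]), collapse = ", "))
  vars <- names(meta)[vapply(meta, is.numeric, logical(1))]
  res <- list()
  for (v in vars) {
    yv <- meta[[v]][idx]
    if (stats::sd(yv) == 0) {
      bgn_log("constant metadata variable excluded: ", v)
      next
    }
    for (f in rownames(m$values)) {
      xv <- m$values[f, ]
      if (stats::sd(xv) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(xv, yv, method = "spearman", exact = FALSE))
      res[[length(res) + 1L]] <- data.frame(
        feature_key = f, variable = v, rho = unname(ct$estimate),
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(feature_key = character(), variable = character(),
                      rho = numeric(), p = numeric(),
                      significant = logical()))
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p <= alpha
  rownames(out) <- NULL
  out
}

#' Variance-inflation-factor screen of metadata variables
#'
#' VIF_j = 1 / (1 - R^2_j) from the least-squares regression of variable
#' j on all the others. In iterative mode (the default) the variable with
#' the highest VIF at or above `threshold` is removed and VIFs are
#' recomputed until all remaining VIFs are below the threshold; perfectly
#' collinear variables (infinite VIF) are removed first.
#'
#' @param meta data.frame of plant metadata (numeric columns are
#'   screened; `plant_id` is ignored).
#' @param threshold VIF cutoff (default 10, i.e. keep VIF < 10).
#' @param iterative remove one variable at a time and recompute.
#' @return list with `kept` (variable names), `removed`, and `vif`
#'   (named vector of final VIFs of the kept variables).
#' @export
vif_screen <- function(meta, threshold = 10, iterative = TRUE) {
  num <- meta[vapply(meta, is.numeric, logical(1))]
  num <- num[, vapply(num, function(x) stats::sd(x) > 0, logical(1)),
             drop = FALSE]
  if (ncol(num) < 2) stop("need at least 2 non-constant numeric variables")
  if (nrow(num) <= ncol(num))
    stop("need more observations than variables for the VIF regressions")
  vif_of <- function(d) {
    vapply(names(d), function(j) {
      fit <- stats::lm(stats::reformulate(names(d)[names(d) != j], j),
                       data = d)
      r2 <- summary(fit)$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- character(0)
  repeat {
    v <- if (ncol(num) >= 2) vif_of(num)
         else stats::setNames(1, names(num))  # a lone variable is collinearity-free
    if (!iterative || all(v < threshold)) break
    worst <- names(which.max(v))
    removed <- c(removed, worst)
    num <- num[, names(num) != worst, drop = FALSE]
  }
  list(kept = names(v)[names(v) %in% names(num)],
       removed = removed,
       vif = v[names(v) %in% names(num)])
}
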