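#' Pipeline configuration with study defaults
#'
#' Collects every stage parameter with its study default: replicate
#' presence >= 3 of 5, prevalence 60%, 2,500 top/bottom candidate edges,
#' MinSupport 3, 100 bootstrap iterations, BH alpha 0.05, factor-F
#' thresholds 0.4/2.5, role thresholds z 2.5 / P 0.62, Spearman alpha
#' 0.01 with a 0.1% mean-abundance floor, VIF cutoff 10.
#'
#' @param abundance,annotation,metadata input TSV paths (may be `NULL`
#'   when calling [run_pipeline()] with in-memory data).
#' @param outdir output directory for the run.
#' @param min_present replicate-presence threshold.
#' @param min_prevalence,n_top,n_bottom,min_support,bootstrap_iters,alpha
#'   network-inference parameters, see [network_config()].
#' @param f_lo,f_hi factor-F thresholds.
#' @param z_thresh,p_thresh topological-role thresholds.
#' @param spearman_alpha,min_mean_abundance,vif_threshold
#'   environmental-screen parameters.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(abundance = NULL, annotation = NULL,
                            metadata = NULL, outdir = tempfile("bgnrun"),
                            min_present = 3, min_prevalence = 0.6,
                            n_top = 2500, n_bottom = 2500, min_support = 3,
                            bootstrap_iters = 100, alpha = 0.05,
                            f_lo = 0.4, f_hi = 2.5,
                            z_thresh = 2.5, p_thresh = 0.62,
                            spearman_alpha = 0.01, min_mean_abundance = 0.1,
                            vif_threshold = 10, seed = 1) {
  structure(list(abundance = abundance, annotation = annotation,
                 metadata = metadata, outdir = outdir,
                 min_present = min_present, min_prevalence = min_prevalence,
                 n_top = n_top, n_bottom = n_bottom,
                 min_support = min_support,
                 bootstrap_iters = bootstrap_iters, alpha = alpha,
                 f_lo = f_lo, f_hi = f_hi, z_thresh = z_thresh,
                 p_thresh = p_thresh, spearman_alpha = spearman_alpha,
                 min_mean_abundance = min_mean_abundance,
                 vif_threshold = vif_threshold, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Preprocess (replicate-presence filter, normalization), classify every
#' replicate by dominant methanogenic pathway (factor F), partition the
#' replicates into acetoclastic / hydrogenotrophic / both sets, infer one
#' co-occurrence network per set (a class with fewer than 3 replicates is
#' skipped with a warning), compute modules and topological roles per
#' network, and screen species abundances against the plant metadata
#' (Spearman, after the mean-abundance floor) and the metadata against
#' itself (VIF). Writes per-stage TSVs plus a `manifest.json` recording
#' the configuration, seed and per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with `matrix`, `annotation`, `metadata` (as
#'   from [simulate_dataset()]) to run in-memory instead of reading the
#'   configured paths.
#' @return (invisibly) list with `calls`, `networks`, `roles`,
#'   `summaries`, `screen`, `vif`, `manifest`, `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(data)) {
    data <- stage("read", {
      rd <- read_abundance_table(config$abundance, config$annotation)
      list(matrix = rd$matrix, annotation = rd$annotation,
           metadata = utils::read.delim(config$metadata,
                                        stringsAsFactors = FALSE))
    })
  }
  m <- stage("preprocess", {
    mf <- filter_replicate_presence(data$matrix, config$min_present)
    normalize_relative(mf, 100)
  })
  calls <- stage("classify", {
    ko <- aggregate_features(m, data$annotation, level = "ko")
    classify_units(ko, mode = "per_replicate",
                   lo = config$f_lo, hi = config$f_hi)
  })
  utils::write.table(calls, file.path(config$outdir, "pathway_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sp <- stage("aggregate", aggregate_features(m, data$annotation, "species"))
  classes <- c(acetoclastic = "AcMe", hydrogenotrophic = "HyMe",
               both = "BoMe")
  networks <- list(); roles <- list(); summaries <- list()
  for (cl in names(classes)) {
    cols <- calls$unit_id[!is.na(calls$label) & calls$label == cl]
    if (!length(cols)) next
    if (length(cols) < 3) {
      warning("pathway class ", classes[cl], " has ", length(cols),
              " replicate(s) (<3); network skipped")
      next
    }
    tag <- classes[cl]
    net <- stage(paste0("network_", tag), {
      sub <- normalize_relative(am_subset_samples(sp, cols), 100)
      infer_network(sub, network_config(
        min_prevalence = config$min_prevalence, n_top = config$n_top,
        n_bottom = config$n_bottom, min_support = config$min_support,
        bootstrap_iters = config$bootstrap_iters, alpha = config$alpha,
        seed = derive_seed(config$seed, "network", tag)))
    })
    rt <- stage(paste0("topology_", tag),
                role_table(net, seed = derive_seed(config$seed, "mod", tag),
                           z_thresh = config$z_thresh,
                           p_thresh = config$p_thresh))
    networks[[tag]] <- net
    roles[[tag]] <- rt
    summaries[[tag]] <- cbind(network = tag, summarize_network(net, rt))
    write_network(net, file.path(config$outdir,
                                 paste0("edges_", tag, ".tsv")))
    utils::write.table(rt, file.path(config$outdir,
                                     paste0("roles_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(summaries)) {
    summary_tab <- do.call(rbind, summaries)
    utils::write.table(summary_tab,
                       file.path(config$outdir, "network_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else summary_tab <- NULL

  screen <- stage("env_correlate", {
    flo <- abundance_floor(sp, config$min_mean_abundance)
    spearman_screen(flo, data$metadata, alpha = config$spearman_alpha)
  })
  utils::write.table(screen, file.path(config$outdir, "spearman_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_numeric <- sum(vapply(data$metadata, is.numeric, logical(1)))
  if (nrow(data$metadata) > n_numeric) {
    vif <- stage("vif", vif_screen(data$metadata, config$vif_threshold))
    utils::write.table(
      data.frame(variable = names(vif$vif), vif = unname(vif$vif)),
      file.path(config$outdir, "vif_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("VIF screen skipped: need more plants than metadata variables")
    vif <- list(kept = character(0), removed = character(0), vif = numeric(0))
  }

  manifest <- list(
    package = "biogasnet",
    version = as.character(utils::packageVersion("biogasnet")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config),
                                         c("abundance", "annotation",
                                           "metadata", "outdir"))],
    n_features = nrow(m$values),
    n_samples = ncol(m$values),
    replicates_per_class = as.list(table(calls$label)),
    networks = lapply(networks, function(n)
      list(species = n$n_species, edges = nrow(n$edges),
           tested = nrow(n$tested))),
    n_significant_correlations = sum(screen$significant),
    vif_kept = vif$kept)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(calls = calls, networks = networks, roles = roles,
                 summaries = summary_tab, screen = screen, vif = vif,
                 manifest = manifest, outdir = config$outdir))
}
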