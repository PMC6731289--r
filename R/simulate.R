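#' Simulation configuration for synthetic digester metaproteomes
#'
#' Defines the conditions of the emulated study design: a multi-plant,
#' five-replicate protein-group abundance table with two methanogen
#' species whose unique-KO protein mass realizes a prescribed factor F
#' per plant, a background bacterial community with planted
#' co-presence/exclusion structure, per-protein-group log-normal
#' measurement noise, feature-replicate dropout, compositional closure to
#' 100, and plant metadata with planted monotone abundance links.
#'
#' The default emulates the 16-plant study design: 8 hydrogenotrophic
#' plants (F well below 0.4), 5 acetoclastic (F well above 2.5) and 3
#' mixed plants, with 30 background species, 10 planted co-presence and 5
#' planted exclusion pairs at latent correlation 0.9.
#'
#' @param n_plants number of plants.
#' @param n_replicates replicates per plant (default 5).
#' @param n_species number of background (non-methanogen) species.
#' @param pg_range integer range of protein groups per background
#'   species.
#' @param F_true numeric vector (length `n_plants`): target acetoclastic
#'   to hydrogenotrophic unique-KO abundance ratio per plant, realized
#'   exactly before noise.
#' @param planted_edges data.frame with columns `a`, `b` (background
#'   species indices), `sign` (+1 co-presence, -1 exclusion), `rho`
#'   (latent correlation in (0, 1\]).
#' @param dropout_prob mean probability that a feature goes unobserved
#'   (zero) in a replicate. Missingness is left-censored: the drop
#'   probability declines linearly with the value's within-feature
#'   abundance rank, emulating the detection-limit behaviour of LC-MS
#'   proteomics.
#' @param noise_sd log-normal measurement noise per protein group and
#'   replicate (log scale sd).
#' @param plant_sd,rep_sd log-scale sd of the plant-level and
#'   replicate-level biological variation of background species.
#' @param metadata_links data.frame with columns `species` (background
#'   species index), `variable` (metadata column name), `direction`
#'   (+1 or -1): planted monotone abundance-metadata links.
#' @param hydro_mass expected unique-KO protein mass of the
#'   hydrogenotrophic methanogen (abundance units before closure; the
#'   acetoclastic side gets `F_true * hydro_mass`).
#' @param bulk_species,bulk_mass,bulk_sd the stable community remainder:
#'   number of non-focal "bulk" species sharing `bulk_mass` abundance
#'   units, each with independent log-normal variation of sd `bulk_sd`.
#'   Real abundance tables contain hundreds of species beyond any focal
#'   panel; this pool reproduces their main statistical effect, a column
#'   total whose fluctuations are small relative to any one species.
#' @param seed master seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_plants = 16, n_replicates = 5,
                              n_species = 30, pg_range = c(1, 4),
                              F_true = c(0.15, 0.2, 0.18, 0.22, 1.0, 0.12,
                                         0.2, 4.0, 0.05, 5.0, 7.5, 5.0,
                                         0.1, 3.5, 1.2, 0.9),
                              planted_edges = default_planted_edges(),
                              dropout_prob = 0.05, noise_sd = 0.3,
                              plant_sd = 0.6, rep_sd = 0.7,
                              metadata_links = default_metadata_links(),
                              hydro_mass = 10, bulk_species = 12,
                              bulk_mass = 200, bulk_sd = 0.5, seed = 1) {
  if (length(F_true) == 1) F_true <- rep(F_true, n_plants)
  stopifnot(length(F_true) == n_plants, all(F_true > 0))
  cfg <- list(n_plants = n_plants, n_replicates = n_replicates,
              n_species = n_species, pg_range = pg_range, F_true = F_true,
              planted_edges = planted_edges, dropout_prob = dropout_prob,
              noise_sd = noise_sd, plant_sd = plant_sd, rep_sd = rep_sd,
              metadata_links = metadata_links, hydro_mass = hydro_mass,
              bulk_species = bulk_species, bulk_mass = bulk_mass,
              bulk_sd = bulk_sd, seed = seed)
  class(cfg) <- "simulation_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @export
default_planted_edges <- function() {
  data.frame(a = c(seq(1, 19, 2), seq(21, 29, 2)),
             b = c(seq(2, 20, 2), seq(22, 30, 2)),
             sign = c(rep(1L, 10), rep(-1L, 5)),
             rho = 0.9)
}

#' @rdname simulation_config
#' @export
default_metadata_links <- function() {
  data.frame(species = c(1L, 3L),
             variable = c("temperature", "vfa"),
             direction = c(1L, -1L),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  pe <- cfg$planted_edges
  if (nrow(pe)) {
    stopifnot(all(pe$a != pe$b), all(pe$rho > 0), all(pe$rho <= 1),
              all(pe$sign %in% c(-1L, 1L)))
    if (max(c(pe$a, pe$b)) > cfg$n_species)
      stop("planted edge refers to species index beyond n_species")
    if (anyDuplicated(c(pe$a, pe$b)))
      stop("a species may appear in at most one planted edge")
    if (nrow(pe) > choose(cfg$n_species, 2))
      stop("more planted edges than species pairs")
  }
  invisible(cfg)
}

species_id <- function(i) sprintf("S%04d", i)

#' Simulate a replicate-level metaproteome dataset with known truth
#'
#' See [simulation_config()] for the generative model. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (an [abundance_matrix()], columns closed to
#'   100), `annotation` (feature annotation data.frame), `metadata`
#'   (per-plant process parameters), and `truth` (list: `plants` with
#'   `F_true`/`label_true` per plant, `edges` with planted species-id
#'   pairs and signs, `metadata_links`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    P <- config$n_plants; R <- config$n_replicates
    nS <- config$n_species
    plants <- sprintf("BP%02d", seq_len(P))
    samples <- paste(rep(plants, each = R), rep(seq_len(R), P), sep = ":")
    plant_of <- rep(plants, each = R)
    nsamp <- length(samples)

    ## --- background species latents ------------------------------------
    base <- stats::rnorm(nS, 0, 1)
    u <- matrix(stats::rnorm(nS * P), nS, P)        # plant effects
    e <- matrix(stats::rnorm(nS * nsamp), nS, nsamp) # replicate effects
    pe <- config$planted_edges
    for (k in seq_len(nrow(pe))) {
      a <- pe$a[k]; b <- pe$b[k]; rho <- pe$rho[k]; sgn <- pe$sign[k]
      Up <- stats::rnorm(P); Lj <- stats::rnorm(nsamp)
      u[a, ] <- sqrt(rho) * Up + sqrt(1 - rho) * u[a, ]
      u[b, ] <- sgn * sqrt(rho) * Up + sqrt(1 - rho) * u[b, ]
      e[a, ] <- sqrt(rho) * Lj + sqrt(1 - rho) * e[a, ]
      e[b, ] <- sgn * sqrt(rho) * Lj + sqrt(1 - rho) * e[b, ]
    }
    latent <- base + config$plant_sd * u[, match(plant_of, plants)] +
      config$rep_sd * e
    sp_abund <- exp(latent)   # nS x nsamp

    ## --- protein groups of background species --------------------------
    npg <- sample(seq(config$pg_range[1], config$pg_range[2]), nS,
                  replace = TRUE)
    feat_rows <- list(); ann_rows <- list()
    families <- c("Clostridiaceae", "Peptococcaceae", "Thermoanaerobacteraceae",
                  "Bacillaceae", "Petrotogaceae", "Pseudomonadaceae")
    fam_of <- sample(families, nS, replace = TRUE)
    for (i in seq_len(nS)) {
      w <- stats::runif(npg[i]); w <- w / sum(w)
      for (g in seq_len(npg[i])) {
        fid <- sprintf("PG_%s_%02d", species_id(i), g)
        noise <- exp(config$noise_sd * stats::rnorm(nsamp))
        feat_rows[[fid]] <- sp_abund[i, ] * w[g] * noise
        ann_rows[[fid]] <- data.frame(
          feature_id = fid, species_id = species_id(i),
          species_name = sprintf("synthetic bacterium %s", species_id(i)),
          family = fam_of[i], ko_ids = "", ec_ids = "",
          stringsAsFactors = FALSE)
      }
    }

    ## --- methanogens: KO mass realizing F_true per plant ----------------
    sets <- methanogenesis_ko_sets()
    aceto_id <- species_id(nS + 1); hydro_id <- species_id(nS + 2)
    F_of_sample <- config$F_true[match(plant_of, plants)]
    add_methanogen <- function(sp, name, fam, kos, side_mass, common_mass) {
      ## whole-species replicate variation (part of the noise model, so
      ## the noiseless ratio of the two sides stays exactly F_true)
      act <- exp(config$noise_sd * stats::rnorm(nsamp))
      side_mass <- side_mass * act
      common_mass <- common_mass * act
      wk <- stats::runif(length(kos)); wk <- wk / sum(wk)
      for (g in seq_along(kos)) {
        fid <- sprintf("PG_%s_%s", sp, kos[g])
        noise <- exp(config$noise_sd * stats::rnorm(nsamp))
        feat_rows[[fid]] <<- side_mass * wk[g] * noise
        ann_rows[[fid]] <<- data.frame(
          feature_id = fid, species_id = sp, species_name = name,
          family = fam, ko_ids = kos[g], ec_ids = "",
          stringsAsFactors = FALSE)
      }
      kos_c <- sets$common[seq_len(3)]
      for (g in seq_along(kos_c)) {
        fid <- sprintf("PG_%s_%s", sp, kos_c[g])
        noise <- exp(config$noise_sd * stats::rnorm(nsamp))
        feat_rows[[fid]] <<- (common_mass / 3) * noise
        ann_rows[[fid]] <<- data.frame(
          feature_id = fid, species_id = sp, species_name = name,
          family = fam, ko_ids = kos_c[g], ec_ids = "",
          stringsAsFactors = FALSE)
      }
    }
    add_methanogen(aceto_id, "synthetic Methanosarcina", "Methanosarcinaceae",
                   sets$acetoclastic_unique,
                   config$hydro_mass * F_of_sample, common_mass = 2.5)
    add_methanogen(hydro_id, "synthetic Methanoculleus", "Methanomicrobiaceae",
                   sets$hydrogenotrophic_unique,
                   rep(config$hydro_mass, nsamp), common_mass = 2.5)

    ## --- bulk community pool (stable remainder of the community) --------
    for (i in seq_len(config$bulk_species)) {
      sp <- species_id(nS + 2 + i)
      per_sp <- config$bulk_mass / config$bulk_species
      for (g in 1:2) {
        fid <- sprintf("PG_%s_%02d", sp, g)
        feat_rows[[fid]] <- (per_sp / 2) *
          exp(config$bulk_sd * stats::rnorm(nsamp))
        ann_rows[[fid]] <- data.frame(
          feature_id = fid, species_id = sp,
          species_name = sprintf("synthetic community bacterium %s", sp),
          family = "uncharacterized", ko_ids = "", ec_ids = "",
          stringsAsFactors = FALSE)
      }
    }

    vals <- do.call(rbind, feat_rows)
    colnames(vals) <- samples
    ann <- do.call(rbind, ann_rows); rownames(ann) <- NULL

    m <- abundance_matrix(vals, plant_of, rep(seq_len(R), P))
    m <- normalize_relative(m, 100)                 # closure
    if (config$dropout_prob > 0) {
      ## left-censored missingness: a feature-replicate goes unobserved
      ## with probability declining in its within-feature abundance rank
      ## (detection-limit behaviour of LC-MS); the mean rate is
      ## dropout_prob
      pr <- t(apply(m$values, 1, function(x) (rank(x) - 0.5) / length(x)))
      pdrop <- pmin(1, 2 * config$dropout_prob * (1 - pr))
      drop <- matrix(stats::runif(length(m$values)), nrow(m$values)) < pdrop
      m$values[drop] <- 0
      m <- normalize_relative(m, 100)               # re-closure
    }

    ## --- metadata -------------------------------------------------------
    meta <- data.frame(
      plant_id = plants,
      temperature = stats::rnorm(P, 42, 4),
      ph = stats::rnorm(P, 7.8, 0.3),
      vfa = exp(stats::rnorm(P, log(300), 0.6)),
      cn_ratio = stats::rnorm(P, 25, 4),
      stringsAsFactors = FALSE)
    subs <- matrix(stats::rgamma(P * 6, shape = 0.8), P, 6)
    subs <- subs / rowSums(subs)
    colnames(subs) <- c("maize_silage", "grass_silage", "cow_manure",
                        "dry_manure", "corn", "food_residues")
    meta <- cbind(meta, as.data.frame(subs))
    ranges <- list(temperature = c(37, 52), ph = c(7.2, 8.4),
                   vfa = c(100, 2500), cn_ratio = c(15, 35))
    ml <- config$metadata_links
    for (k in seq_len(nrow(ml))) {
      sp <- ml$species[k]
      pm <- base[sp] + config$plant_sd * u[sp, ]    # plant-level latent
      r01 <- (rank(pm) - 0.5) / P
      if (ml$direction[k] < 0) r01 <- 1 - r01
      rg <- ranges[[ml$variable[k]]]
      if (is.null(rg)) rg <- c(0, 1)
      meta[[ml$variable[k]]] <-
        rg[1] + (rg[2] - rg[1]) * (0.9 * r01 + 0.1 * stats::runif(P))
    }

    truth <- list(
      plants = data.frame(plant_id = plants, F_true = config$F_true,
                          label_true = classify_F(config$F_true),
                          stringsAsFactors = FALSE),
      edges = if (nrow(pe)) data.frame(
        a = species_id(pe$a), b = species_id(pe$b),
        pair = pair_id(species_id(pe$a), species_id(pe$b)),
        sign = pe$sign, rho = pe$rho, stringsAsFactors = FALSE)
      else data.frame(a = character(), b = character(), pair = character(),
                      sign = integer(), rho = numeric()),
      metadata_links = if (nrow(ml)) data.frame(
        species_id = species_id(ml$species), variable = ml$variable,
        direction = ml$direction, stringsAsFactors = FALSE)
      else data.frame(species_id = character(), variable = character(),
                      direction = integer()))
    list(matrix = m, annotation = ann, metadata = meta, truth = truth)
  })
}

#' Write a simulated dataset to TSV files
#'
#' Writes `abundance.tsv`, `annotation.tsv`, `metadata.tsv`,
#' `truth_plants.tsv`, `truth_edges.tsv` and `truth_metadata_links.tsv`
#' in the package's TSV dialects. Output is byte-identical for the same
#' configuration and seed.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- data.frame(feature_id = rownames(sim$matrix$values),
                   signif(sim$matrix$values, 10), check.names = FALSE,
                   stringsAsFactors = FALSE)
  w(ab, "abundance.tsv")
  w(sim$annotation, "annotation.tsv")
  w(data.frame(lapply(sim$metadata, function(x)
    if (is.numeric(x)) signif(x, 10) else x), stringsAsFactors = FALSE),
    "metadata.tsv")
  w(sim$truth$plants, "truth_plants.tsv")
  w(sim$truth$edges, "truth_edges.tsv")
  w(sim$truth$metadata_links, "truth_metadata_links.tsv")
  invisible(outdir)
}

#' Score pipeline outputs against simulation ground truth
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param calls optional per-plant classification (data.frame from
#'   [classify_units()], `mode = "per_plant"`).
#' @param network optional `cooccurrence_network` (or its `edges`
#'   data.frame) inferred at species level.
#' @param screen optional [spearman_screen()] output at species level.
#' @return list of metrics: `label_accuracy`, `edge_recall`,
#'   `edge_precision` (planted edges, sign-aware), `edge_recall_positive`,
#'   `edge_recall_negative`, `metadata_link_recall` (only the components
#'   whose inputs were supplied).
#' @export
recovery_report <- function(truth, calls = NULL, network = NULL,
                            screen = NULL) {
  out <- list()
  if (!is.null(calls)) {
    idx <- match(truth$plants$plant_id, calls$unit_id)
    out$label_accuracy <-
      mean(calls$label[idx] == truth$plants$label_true, na.rm = FALSE)
  }
  if (!is.null(network)) {
    edges <- if (inherits(network, "cooccurrence_network")) network$edges
             else network
    pred_pair <- edges$pair
    pred_sign <- ifelse(edges$direction == "copresence", 1L, -1L)
    tr <- truth$edges
    hit <- vapply(seq_len(nrow(tr)), function(i) {
      j <- match(tr$pair[i], pred_pair)
      !is.na(j) && pred_sign[j] == tr$sign[i]
    }, logical(1))
    out$edge_recall <- if (nrow(tr)) mean(hit) else NA_real_
    out$edge_recall_positive <-
      if (any(tr$sign > 0)) mean(hit[tr$sign > 0]) else NA_real_
    out$edge_recall_negative <-
      if (any(tr$sign < 0)) mean(hit[tr$sign < 0]) else NA_real_
    correct_pred <- vapply(seq_along(pred_pair), function(j) {
      i <- match(pred_pair[j], tr$pair)
      !is.na(i) && tr$sign[i] == pred_sign[j]
    }, logical(1))
    out$edge_precision <-
      if (length(pred_pair)) mean(correct_pred) else NA_real_
  }
  if (!is.null(screen)) {
    ml <- truth$metadata_links
    found <- vapply(seq_len(nrow(ml)), function(i) {
      rec <- screen[screen$feature_key == ml$species_id[i] &
                    screen$variable == ml$variable[i], , drop = FALSE]
      nrow(rec) > 0 && any(rec$significant &
                           sign(rec$rho) == ml$direction[i])
    }, logical(1))
    out$metadata_link_recall <- if (nrow(ml)) mean(found) else NA_real_
  }
  out
}
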