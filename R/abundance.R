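#' Construct a protein-group abundance matrix
#'
#' Container for a nonnegative feature x sample table of relative
#' protein-group abundances with the plant/replicate design attached to the
#' columns. Absence is encoded as 0; missing cells are not allowed.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param plant character vector, plant id per sample (recycled names from
#'   columns if unnamed).
#' @param replicate integer vector, replicate index per sample (1..R).
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values`, `plant`, `replicate`.
#' @export
abundance_matrix <- function(values, plant, replicate) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature_id in abundance matrix: ",
         rownames(values)[anyDuplicated(rownames(values))])
  if (anyNA(values)) stop("abundance matrix contains missing cells")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  plant <- as.character(plant)
  replicate <- as.integer(replicate)
  if (length(plant) != ncol(values) || length(replicate) != ncol(values))
    stop("plant/replicate must have one entry per sample column")
  names(plant) <- names(replicate) <- colnames(values)
  structure(list(values = values, plant = plant, replicate = replicate),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d samples (%d plants)\n",
              nrow(x$values), ncol(x$values), length(unique(x$plant))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

## subset columns, keeping design in sync
am_subset_samples <- function(m, keep) {
  abundance_matrix(m$values[, keep, drop = FALSE],
                   m$plant[keep], m$replicate[keep])
}

am_subset_features <- function(m, keep) {
  abundance_matrix(m$values[keep, , drop = FALSE], m$plant, m$replicate)
}

#' Read abundance and annotation tables from TSV
#'
#' The abundance table has header `feature_id<TAB><plant>:<replicate>...`;
#' the annotation table has columns `feature_id`, `species_id`,
#' `species_name`, `family`, `ko_ids`, `ec_ids` (the last two
#' semicolon-joined, possibly empty). Features present in the abundance
#' table but absent from the annotation are retained with empty annotation
#' (with a warning); annotation rows without abundance are dropped (with a
#' warning).
#'
#' @param path path to the abundance TSV.
#' @param annotation_path path to the annotation TSV.
#' @return list with elements `matrix` (an [abundance_matrix()]) and
#'   `annotation` (a data.frame).
#' @export
read_abundance_table <- function(path, annotation_path) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature_id")
    stop("malformed abundance header at line 1: first column must be 'feature_id'")
  samples <- header[-1]
  bad <- !grepl("^[^:]+:[0-9]+$", samples)
  if (any(bad))
    stop("malformed abundance header at line 1: sample id(s) not of form plant:replicate: ",
         paste(samples[bad], collapse = ", "))
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$feature_id))
    stop("duplicate feature_id in abundance table: ",
         tab$feature_id[duplicated(tab$feature_id)][1])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$feature_id
  if (!is.numeric(vals)) stop("non-numeric abundance values in ", path)
  plant <- sub(":[0-9]+$", "", samples)
  repl <- as.integer(sub("^.*:", "", samples))
  m <- abundance_matrix(vals, plant, repl)

  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("feature_id", "species_id", "species_name", "family",
            "ko_ids", "ec_ids")
  if (!all(need %in% names(ann)))
    stop("annotation is missing column(s): ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  if (anyDuplicated(ann$feature_id))
    stop("duplicate feature_id in annotation: ",
         ann$feature_id[duplicated(ann$feature_id)][1])
  sp <- unique(ann[, c("species_id", "species_name")])
  if (anyDuplicated(sp$species_id))
    stop("species_id maps to more than one species_name")

  extra_ann <- setdiff(ann$feature_id, rownames(vals))
  if (length(extra_ann)) {
    warning(length(extra_ann),
            " annotated feature(s) without abundance dropped")
    ann <- ann[!ann$feature_id %in% extra_ann, , drop = FALSE]
  }
  missing_ann <- setdiff(rownames(vals), ann$feature_id)
  if (length(missing_ann)) {
    warning(length(missing_ann),
            " feature(s) lack annotation; retained with empty annotation")
    ann <- rbind(ann, data.frame(feature_id = missing_ann, species_id = "",
                                 species_name = "", family = "",
                                 ko_ids = "", ec_ids = "",
                                 stringsAsFactors = FALSE))
  }
  ann <- ann[match(rownames(vals), ann$feature_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = m, annotation = ann)
}

#' Filter features on replicate presence
#'
#' Keeps a feature (for the whole matrix) if in at least one plant it is
#' nonzero in at least `min_present` of that plant's replicates. With
#' `per_plant = TRUE` the feature is instead masked (zeroed) within every
#' plant where it fails the threshold, and dropped only if it fails
#' everywhere.
#'
#' @param m an [abundance_matrix()].
#' @param min_present minimum number of replicates with nonzero abundance.
#' @param per_plant logical; mask per plant instead of global keep.
#' @return filtered `abundance_matrix`; removed feature ids are attached as
#'   attribute `"removed"`.
#' @export
filter_replicate_presence <- function(m, min_present = 3, per_plant = FALSE) {
  plants <- unique(m$plant)
  pass <- sapply(plants, function(p) {
    cols <- m$plant == p
    rowSums(m$values[, cols, drop = FALSE] > 0) >= min_present
  })
  pass <- matrix(pass, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), plants))
  keep <- rowSums(pass) > 0
  removed <- rownames(m$values)[!keep]
  if (length(removed))
    bgn_log(length(removed), " feature(s) removed by replicate-presence filter")
  out <- am_subset_features(m, keep)
  if (per_plant) {
    for (p in plants) {
      mask <- !pass[keep, p]
      out$values[mask, out$plant == p] <- 0
    }
  }
  attr(out, "removed") <- removed
  out
}

#' Normalize each sample column to a fixed total
#'
#' @param m an [abundance_matrix()].
#' @param total target column sum (default 100, i.e. percent).
#' @return normalized `abundance_matrix`.
#' @export
normalize_relative <- function(m, total = 100) {
  cs <- colSums(m$values)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m$values)[cs <= 0], collapse = ", "))
  m$values <- sweep(m$values, 2, cs / total, "/")
  m
}

## split a semicolon-joined id string into a character vector
split_ids <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Aggregate features to species, family or KO level
#'
#' Sums member feature abundances per key. Features with no key at the
#' requested level are collected under a reserved `"unassigned"` row. At
#' `level = "ko"` a feature annotated with k KO ids contributes, by
#' default, its full abundance to each of the k keys (`multi_ko = "full"`);
#' with `multi_ko = "split"` the abundance is divided evenly among them.
#'
#' @param m an [abundance_matrix()].
#' @param annotation annotation data.frame as returned by
#'   [read_abundance_table()].
#' @param level one of `"species"`, `"family"`, `"ko"`.
#' @param multi_ko `"full"` or `"split"`; only used for `level = "ko"`.
#' @return aggregated `abundance_matrix` (rows keyed by species_id, family
#'   or KO id).
#' @export
aggregate_features <- function(m, annotation, level = c("species", "family", "ko"),
                               multi_ko = c("full", "split")) {
  level <- match.arg(level)
  multi_ko <- match.arg(multi_ko)
  ann <- annotation[match(rownames(m$values), annotation$feature_id), ]
  if (level == "ko") {
    keysets <- split_ids(ann$ko_ids)
    weights <- if (multi_ko == "split")
      lapply(keysets, function(k) rep(1 / max(1, length(k)), length(k)))
    else lapply(keysets, function(k) rep(1, length(k)))
  } else {
    key1 <- if (level == "species") ann$species_id else ann$family
    key1[is.na(key1)] <- ""
    keysets <- as.list(key1)
    keysets <- lapply(keysets, function(k) k[nzchar(k)])
    weights <- lapply(keysets, function(k) rep(1, length(k)))
  }
  empty <- lengths(keysets) == 0
  keysets[empty] <- list("unassigned")
  weights[empty] <- list(1)
  ft <- rep(seq_len(nrow(m$values)), lengths(keysets))
  key <- unlist(keysets)
  w <- unlist(weights)
  agg <- rowsum(m$values[ft, , drop = FALSE] * w, group = key)
  keys <- sort(unique(key))
  keys <- c(setdiff(keys, "unassigned"),
            intersect("unassigned", keys))
  abundance_matrix(agg[keys, , drop = FALSE], m$plant, m$replicate)
}

#' Per-plant mean abundance profiles
#'
#' Averages replicate columns within each plant; optionally renormalizes
#' each plant column to sum 100.
#'
#' @param m an [abundance_matrix()].
#' @param renormalize logical, rescale each plant column to sum 100.
#' @return `abundance_matrix` with one column per plant (replicate index 1).
#' @export
plant_means <- function(m, renormalize = TRUE) {
  plants <- unique(m$plant)
  vals <- sapply(plants, function(p)
    rowMeans(m$values[, m$plant == p, drop = FALSE]))
  vals <- matrix(vals, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), plants))
  out <- abundance_matrix(vals, plants, rep(1L, length(plants)))
  if (renormalize) out <- normalize_relative(out, 100) else out
}
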