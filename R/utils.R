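#' @keywords internal
"_PACKAGE"

#' Derive a deterministic sub-seed from a master seed
#'
#' Stable string hash of the master seed plus any number of labels,
#' reduced below 2^31. Used to give every (pair, method) work unit its
#' own reproducible random stream, independent of evaluation order.
#'
#' @param master_seed integer master seed.
#' @param ... labels (coerced to character) identifying the work unit.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  parts <- paste(c(master_seed, ...), collapse = "|")
  bytes <- utf8ToInt(parts)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

## Evaluate `expr` under a local RNG state so library code never clobbers
## the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

bgn_log <- function(..., verbose = getOption("biogasnet.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[biogasnet] ", ...)
  invisible(NULL)
}

## Canonical unordered pair id "a--b" with lexicographically smaller id first.
pair_id <- function(a, b) {
  lo <- ifelse(a < b, a, b)
  hi <- ifelse(a < b, b, a)
  paste(lo, hi, sep = "--")
}
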