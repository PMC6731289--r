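# Brute-force reference implementations, written directly from the
# textbook formulas and kept independent of the package's code paths.

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_rank <- function(x) {
  # average ranks, from the definition
  sapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2)
}

bf_spearman <- function(x, y) bf_pearson(bf_rank(x), bf_rank(y))

bf_kendall <- function(x, y) {
  # tau-b with tie corrections
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

bf_braycurtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

bf_kl <- function(x, y, eps = 1e-6) {
  p <- (x + eps) / sum(x + eps)
  q <- (y + eps) / sum(y + eps)
  (sum(p * log(p / q)) + sum(q * log(q / p))) / 2
}

bf_assoc <- function(x, y, method) {
  switch(method,
         pearson = bf_pearson(x, y), spearman = bf_spearman(x, y),
         kendall = bf_kendall(x, y), braycurtis = bf_braycurtis(x, y),
         kl = bf_kl(x, y))
}

# z and participation from adjacency + module vector, by counting
bf_connectivity <- function(adj, mod) {
  n <- nrow(adj)
  k <- rowSums(adj)
  kown <- sapply(1:n, function(i) sum(adj[i, mod == mod[i]]))
  z <- numeric(n); P <- numeric(n)
  for (i in 1:n) {
    peers <- which(mod == mod[i])
    mu <- mean(kown[peers])
    s <- if (length(peers) > 1) sd(kown[peers]) else 0
    z[i] <- if (is.na(s) || s == 0) 0 else (kown[i] - mu) / s
    P[i] <- if (k[i] == 0) 0 else
      1 - sum(sapply(unique(mod), function(s2)
        (sum(adj[i, mod == s2]) / k[i])^2))
  }
  list(z = z, P = P)
}

# quick abundance_matrix builder
make_am <- function(vals, plants = NULL, reps = NULL) {
  if (is.null(colnames(vals)))
    colnames(vals) <- paste0("BP01:", seq_len(ncol(vals)))
  if (is.null(rownames(vals)))
    rownames(vals) <- paste0("F", seq_len(nrow(vals)))
  if (is.null(plants)) plants <- sub(":.*", "", colnames(vals))
  if (is.null(reps)) reps <- as.integer(sub(".*:", "", colnames(vals)))
  abundance_matrix(vals, plants, reps)
}

# the planted-structure benchmark: one pooled pathway class of 40
# exchangeable replicates, 30 focal species, 10 + 5 planted pairs
benchmark_sim <- function(seed = 1) {
  simulate_dataset(simulation_config(n_plants = 1, n_replicates = 40,
                                     F_true = 0.1, seed = seed))
}

no_edges <- function() data.frame(a = integer(), b = integer(),
                                  sign = integer(), rho = numeric())
no_links <- function() data.frame(species = integer(),
                                  variable = character(),
                                  direction = integer())
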