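# Independent brute-force oracles and small fixture builders.

# per-position loop implementations, deliberately naive
naive_tanimoto <- function(a, b) {
  inter <- 0L; union <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1L && b[i] == 1L) inter <- inter + 1L
    if (a[i] == 1L || b[i] == 1L) union <- union + 1L
  }
  if (union == 0L) 0 else inter / union
}

naive_city_block <- function(a, b) {
  d <- 0L
  for (i in seq_along(a)) d <- d + abs(a[i] - b[i])
  d
}

naive_pairwise_mean <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) vals <- c(vals, naive_tanimoto(m[i, ], m[j, ]))
  }
  vals
}

# closed-form binary bit entropy, written independently of the package
h2 <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

random_bits <- function(n, L, p = 0.5, seed = 1) {
  withr::with_seed(seed, matrix(as.integer(runif(n * L) < p), n, L))
}

random_bit_matrix <- function(n, L, p = 0.5, seed = 1, label = "test") {
  bit_matrix(random_bits(n, L, p, seed),
             ids = sprintf("t%d", seq_len(n)),
             scheme = dfptools::fp_scheme("GENERIC", length = L),
             source_label = label)
}

# profile with exact rational probabilities
profile_of <- function(p, n = 20L, label = "exact") {
  counts <- as.integer(round(p * n))
  stopifnot(all(abs(counts / n - p) < 1e-12))
  profile_from_counts(counts, n = n, source_label = label)
}
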