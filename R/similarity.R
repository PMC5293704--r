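#' Tanimoto coefficient and city-block distance between bit vectors
#'
#' `tanimoto()` is the standard fingerprint similarity `|a AND b| / |a OR b|`
#' on set bits; by convention it returns 0 when both vectors are all-zero
#' (two featureless fingerprints carry no evidence of similarity).
#' `city_block()` is the Manhattan distance `sum(|a_i - b_i|)`, which on
#' binary vectors equals the Hamming distance.
#'
#' @param a,b Binary 0/1 vectors of equal length (bare vectors, rows of a
#'   [bit_matrix()], or `dfp` objects).
#' @return `tanimoto()`: a number in `[0, 1]`; `city_block()`: a
#'   non-negative integer in `[0, L]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' city_block(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 2
#' @export
tanimoto <- function(a, b) {
  a <- as_bit_vector(a, "a")
  b <- as_bit_vector(b, "b")
  if (length(a) != length(b)) {
    stop(sprintf("bit vectors differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  }
  union <- sum(a | b)
  if (union == 0L) {
    rlang::inform(
      "tanimoto(): both vectors all-zero; returning 0 by convention",
      .frequency = "once", .frequency_id = "dfptools_tanimoto_zero")
    return(0)
  }
  sum(a & b) / union
}

#' @rdname tanimoto
#' @export
city_block <- function(a, b) {
  a <- as_bit_vector(a, "a")
  b <- as_bit_vector(b, "b")
  if (length(a) != length(b)) {
    stop(sprintf("bit vectors differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  }
  sum(abs(a - b))
}

sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)

new_similarity_summary <- function(mean, sd, n, method, sampled,
                                   seed = NA_integer_, label = "") {
  tbl <- tibble::tibble(
    label = label,
    method = method,
    mean = mean,
    sd = sd,
    n_pairs_or_mols = n,
    sampled = sampled,
    seed = as.integer(seed)
  )
  class(tbl) <- c("similarity_summary", class(tbl))
  tbl
}

#' Mean pairwise Tanimoto similarity within a library
#'
#' The classical intra-set diversity summary: the mean (and SD) of the
#' Tanimoto coefficient over molecule pairs. Up to `max_exact_n` molecules
#' all `n(n-1)/2` pairs are evaluated exactly via bit-count linear algebra;
#' larger libraries are summarised over `sample_pairs` distinct pairs drawn
#' uniformly with a seeded RNG (the `sampled` flag records which path ran).
#'
#' @param matrix A [bit_matrix()] with at least two molecules.
#' @param max_exact_n Largest `n` for which the exact all-pairs mean is
#'   computed (default 3000).
#' @param sample_pairs Number of distinct pairs drawn when sampling
#'   (default 200000).
#' @param seed Seed for the pair sample.
#' @return A one-row `similarity_summary` tibble with columns `label`,
#'   `method`, `mean`, `sd`, `n_pairs_or_mols`, `sampled`, `seed`.
#' @examples
#' m <- generate_random_reference(n = 300, seed = 11)
#' intra_set_pairwise(m)
#' @export
intra_set_pairwise <- function(matrix, max_exact_n = 3000L,
                               sample_pairs = 200000L, seed = 1L) {
  stopifnot(inherits(matrix, "bit_matrix"))
  n <- nrow(matrix)
  if (n < 2L) stop("pairwise similarity needs at least 2 molecules",
                   call. = FALSE)
  m <- as_plain_matrix(matrix)
  n_pairs_total <- n * (n - 1) / 2

  if (n <= max_exact_n) {
    inter <- tcrossprod(m)
    pops <- rowSums(m)
    union <- outer(pops, pops, `+`) - inter
    sims <- inter / union
    sims[union == 0] <- 0
    vals <- sims[upper.tri(sims)]
    return(new_similarity_summary(
      mean = mean(vals), sd = sd0(vals), n = n_pairs_total,
      method = "pairwise_tanimoto", sampled = FALSE,
      label = fp_source_label(matrix)))
  }

  sample_pairs <- min(sample_pairs, n_pairs_total)
  ks <- withr::with_seed(seed, sample.int(n_pairs_total, sample_pairs))
  ij <- pair_index_to_ij(ks, n)
  inter <- rowSums(m[ij$i, , drop = FALSE] & m[ij$j, , drop = FALSE])
  union <- rowSums(m[ij$i, , drop = FALSE] | m[ij$j, , drop = FALSE])
  vals <- ifelse(union == 0, 0, inter / union)
  new_similarity_summary(
    mean = mean(vals), sd = sd0(vals), n = sample_pairs,
    method = "pairwise_tanimoto", sampled = TRUE, seed = seed,
    label = fp_source_label(matrix))
}

# Map 1-based pair ranks k in [1, n(n-1)/2] to unordered index pairs (i, j),
# i < j, ordered lexicographically by i. Stays in doubles so ranks beyond
# .Machine$integer.max are fine.
pair_index_to_ij <- function(k, n) {
  k <- as.numeric(k)
  # pairs with first index < i: f(i) = (i-1)(2n-i)/2; invert the quadratic
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  # guard rounding at the boundaries
  f <- function(i) (i - 1) * (2 * n - i) / 2
  too_big <- f(i) >= k
  i[too_big] <- i[too_big] - 1
  too_small <- f(i + 1) < k
  i[too_small] <- i[too_small] + 1
  j <- k - f(i) + i
  list(i = as.integer(i), j = as.integer(j))
}

#' Mean similarity of each molecule to the library's DFP
#'
#' The DFP-based approximation of intra-set similarity: the mean (and SD) of
#' `tanimoto(molecule_i, dfp)` over all molecules. Cost is linear in `n`,
#' versus quadratic for the all-pairs mean it approximates.
#'
#' @param matrix A [bit_matrix()].
#' @param dfp A `dfp` of the same scheme (typically built from `matrix`).
#' @return A one-row `similarity_summary` tibble (`method = "vs_dfp_tanimoto"`).
#' @examples
#' m <- generate_random_reference(n = 300, seed = 11)
#' intra_set_vs_dfp(m, build_dfp_for_database(m, threshold = 0.55))
#' @export
intra_set_vs_dfp <- function(matrix, dfp) {
  stopifnot(inherits(matrix, "bit_matrix"), inherits(dfp, "dfp"))
  if (ncol(matrix) != length(dfp$bits)) {
    stop(sprintf("scheme mismatch: library has %d bits, DFP has %d",
                 ncol(matrix), length(dfp$bits)), call. = FALSE)
  }
  m <- as_plain_matrix(matrix)
  d <- dfp$bits
  inter <- as.vector(m %*% d)
  union <- rowSums(m) + sum(d) - inter
  vals <- ifelse(union == 0, 0, inter / union)
  new_similarity_summary(
    mean = mean(vals), sd = sd0(vals), n = nrow(m),
    method = "vs_dfp_tanimoto", sampled = FALSE,
    label = fp_source_label(matrix))
}

#' Inter-set distance matrix over database fingerprints
#'
#' Pairwise distances between library-level DFPs: city-block (= Hamming;
#' the default) or `1 - Tanimoto`.
#'
#' @param dfps A list of `dfp` objects of equal length. Names (or the DFPs'
#'   source labels) become the matrix labels.
#' @param metric `"city_block"` or `"one_minus_tanimoto"`.
#' @return An object of class `dfp_dist`: a symmetric numeric matrix with
#'   zero diagonal, dimnames from the library labels, and attribute
#'   `metric`.
#' @examples
#' ms <- make_library_ladder(3, seed = 5)
#' ds <- lapply(ms, build_dfp_for_database, threshold = 0.55)
#' inter_set_matrix(ds)
#' @export
inter_set_matrix <- function(dfps, metric = c("city_block",
                                              "one_minus_tanimoto")) {
  metric <- match.arg(metric)
  if (!is.list(dfps) || length(dfps) < 2L) {
    stop("`dfps` must be a list of at least 2 dfp objects", call. = FALSE)
  }
  lens <- vapply(dfps, function(d) length(d$bits), integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("DFPs have mixed bit lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  labels <- names(dfps)
  if (is.null(labels)) {
    labels <- vapply(dfps, function(d) d$source_label, character(1L))
  }
  labels[!nzchar(labels)] <- paste0("dfp", which(!nzchar(labels)))
  labels <- make.unique(labels, sep = "_")
  k <- length(dfps)
  vals <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- switch(metric,
                  city_block = city_block(dfps[[i]], dfps[[j]]),
                  one_minus_tanimoto = 1 - tanimoto(dfps[[i]], dfps[[j]]))
      vals[i, j] <- d
      vals[j, i] <- d
    }
  }
  structure(vals, metric = metric, class = c("dfp_dist", "matrix", "array"))
}

#' @export
print.dfp_dist <- function(x, ...) {
  cat(sprintf("<dfp_dist> %d libraries, metric = %s\n",
              nrow(x), attr(x, "metric")))
  print(unclass(x)[,])
  invisible(x)
}

#' Write a distance matrix as labelled TSV
#'
#' @param dist A `dfp_dist` from [inter_set_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(dist, path) {
  labels <- rownames(dist)
  lines <- c(paste(c("", labels), collapse = "\t"),
             vapply(seq_len(nrow(dist)), function(i) {
               paste(c(labels[i],
                       format(unclass(dist)[i, ], digits = 17,
                              trim = TRUE)),
                     collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
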