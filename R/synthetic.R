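#' Seeded random-reference fingerprint matrices
#'
#' Generates `n` fingerprints with every bit drawn independently as
#' Bernoulli(`p`). With the defaults (1500 molecules, 166 bits, p = 0.5)
#' this is the random reference population used to calibrate thresholds and
#' to anchor the diverse end of the entropy scale. Output is fully
#' determined by `seed` (R's Mersenne-Twister RNG, isolated from the
#' caller's RNG state).
#'
#' @param n Number of fingerprints (default 1500).
#' @param scheme An [fp_scheme()] (default MACCS-166).
#' @param p Per-bit set probability in `[0, 1]` (default 0.5).
#' @param seed Integer seed.
#' @param label Source label for the matrix.
#' @return A [bit_matrix()].
#' @examples
#' m <- generate_random_reference(n = 10, seed = 1)
#' dim(m)
#' @export
generate_random_reference <- function(n = 1500L,
                                      scheme = fp_scheme("MACCS166"),
                                      p = 0.5, seed = 1L,
                                      label = "random") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  stopifnot(is_fp_scheme(scheme))
  L <- scheme$length
  bits <- withr::with_seed(seed, {
    matrix(as.integer(stats::runif(n * L) < p), nrow = n, ncol = L)
  })
  bit_matrix(bits, ids = sprintf("rnd%d", seq_len(n)), scheme = scheme,
             source_label = label)
}

#' Specification of a synthetic fingerprint library
#'
#' Describes a library to be drawn by [generate_library()]: size, scheme,
#' a target per-bit probability profile, and optionally blocks of bits that
#' co-occur within a molecule (emulating the structural correlation real
#' fingerprint bits show, e.g. keys implied by a shared scaffold).
#'
#' @param n Number of molecules.
#' @param profile Length-`L` vector of target per-bit probabilities.
#' @param scheme An [fp_scheme()]; inferred from `length(profile)` if absent.
#' @param blocks Optional list of correlated blocks, each a list with
#'   `bits` (0-based bit indices, disjoint across blocks) and `rho`
#'   (within-block correlation in `[0, 1)`).
#' @param seed Integer seed.
#' @param label Source label.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n, profile, scheme = NULL, blocks = list(),
                         seed = 1L, label = "synthetic") {
  profile <- as.numeric(profile)
  if (any(is.na(profile)) || any(profile < 0) || any(profile > 1)) {
    stop("`profile` entries must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.null(scheme)) scheme <- scheme_from_length(length(profile))
  stopifnot(is_fp_scheme(scheme))
  if (scheme$length != length(profile)) {
    stop("profile length must equal the scheme length", call. = FALSE)
  }
  all_bits <- unlist(lapply(blocks, `[[`, "bits"))
  if (anyDuplicated(all_bits)) {
    stop("correlated blocks must be disjoint bit-index sets", call. = FALSE)
  }
  if (length(all_bits) &&
      (any(all_bits < 0) || any(all_bits >= scheme$length))) {
    stop("block bit indices must lie in [0, L)", call. = FALSE)
  }
  for (b in blocks) {
    if (is.null(b$rho) || b$rho < 0 || b$rho >= 1) {
      stop("each block needs a correlation `rho` in [0, 1)", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), profile = profile, scheme = scheme,
                 blocks = blocks, seed = as.integer(seed),
                 label = as.character(label)),
            class = "library_spec")
}

#' Draw a synthetic fingerprint library
#'
#' Independent bits follow Bernoulli(`profile[i]`). Within a correlated
#' block, each molecule draws one shared latent uniform; each block bit uses
#' the shared uniform with probability `sqrt(rho)` and a private uniform
#' otherwise, then thresholds it at its own target probability. This keeps
#' every marginal exactly at `profile[i]` while giving any two same-`p`
#' block bits Pearson correlation `rho`; empirical frequencies converge to
#' the profile as `n` grows.
#'
#' @param spec A [library_spec()].
#' @return A [bit_matrix()].
#' @examples
#' sp <- library_spec(n = 100, profile = rep(0.8, 20), seed = 4)
#' colMeans(generate_library(sp))[1:5]
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  n <- spec$n
  L <- spec$scheme$length
  bits <- withr::with_seed(spec$seed, {
    u <- matrix(stats::runif(n * L), nrow = n, ncol = L)
    for (b in spec$blocks) {
      cols <- b$bits + 1L
      mix <- sqrt(b$rho)
      shared <- stats::runif(n)
      use_shared <- matrix(stats::runif(n * length(cols)) < mix,
                           nrow = n)
      u[, cols][use_shared] <-
        matrix(shared, nrow = n, ncol = length(cols))[use_shared]
    }
    matrix(as.integer(u < rep(spec$profile, each = n)), nrow = n)
  })
  bit_matrix(bits, ids = sprintf("%s_%d", spec$label, seq_len(n)),
             scheme = spec$scheme, source_label = spec$label)
}

#' A ladder of synthetic libraries of increasing homogeneity
#'
#' Generates `k_levels` libraries whose per-bit probabilities are drawn
#' uniformly from `[0.5 - d, 0.5 + d]` with `d` increasing from 0 to
#' `max_d` across levels. Level 1 (d = 0) matches the random reference
#' distributionally; as `d` grows, probabilities polarise toward 0/1, total
#' Shannon entropy falls and mean pairwise Tanimoto rises — a synthetic
#' analogue of the diversity spread seen across real compound databases.
#'
#' @param k_levels Number of libraries (>= 2).
#' @param scheme An [fp_scheme()] (default MACCS-166).
#' @param n Molecules per library (default 500).
#' @param max_d Half-width of the probability band at the top level
#'   (default 0.4).
#' @param seed Integer seed; level seeds are derived from it.
#' @return A named list of [bit_matrix()] objects
#'   (`level1 ... level<k>`).
#' @examples
#' ladder <- make_library_ladder(3, n = 200, seed = 9)
#' sapply(ladder, function(m) attr(shannon_entropy(bit_probabilities(m)), "total"))
#' @export
make_library_ladder <- function(k_levels, scheme = fp_scheme("MACCS166"),
                                n = 500L, max_d = 0.4, seed = 1L) {
  k_levels <- as.integer(k_levels)
  if (k_levels < 2L) stop("`k_levels` must be at least 2", call. = FALSE)
  d_seq <- max_d * (seq_len(k_levels) - 1L) / (k_levels - 1L)
  out <- vector("list", k_levels)
  for (j in seq_len(k_levels)) {
    prof <- withr::with_seed(seed + 1000L * j, {
      stats::runif(scheme$length, 0.5 - d_seq[j], 0.5 + d_seq[j])
    })
    sp <- library_spec(n = n, profile = prof, scheme = scheme,
                       seed = seed + 1000L * j + 1L,
                       label = sprintf("level%d", j))
    out[[j]] <- generate_library(sp)
  }
  names(out) <- sprintf("level%d", seq_len(k_levels))
  out
}
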