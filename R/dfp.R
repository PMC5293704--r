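#' Build a database fingerprint from a probability profile
#'
#' The database fingerprint (DFP) condenses a whole compound library into one
#' binary vector of the library's fingerprint length: bit `i` of the DFP is 1
#' exactly when the fraction of library molecules setting bit `i` *strictly
#' exceeds* the threshold `t`, and 0 when that probability is equal to or
#' lower than `t`. The strict inequality matters: a bit whose probability sits
#' exactly on the threshold is off.
#'
#' @param profile A probability profile from [bit_probabilities()].
#' @param threshold Probability cutoff, in `[0, 1)`. A threshold of 1 or more
#'   is rejected: it would produce an all-zero, information-free fingerprint.
#' @param strategy How the threshold was chosen (recorded as provenance):
#'   `"fixed"`, `"random_reference_mean"`, or `"mean_plus_sd"`.
#'
#' @return An object of class `dfp`: a list with elements `bits` (integer
#'   0/1 vector of length `L`), `threshold`, `strategy`, `n_source`,
#'   `scheme`, and `source_label`.
#'
#' @seealso [build_dfp_for_database()] for the one-call pipeline from a
#'   [bit_matrix()], [threshold_random_reference()] and
#'   [threshold_mean_plus_sd()] for the two data-driven threshold strategies.
#'
#' @examples
#' m <- generate_random_reference(n = 100, seed = 7)
#' prof <- bit_probabilities(m)
#' d <- build_dfp(prof, threshold = 0.55)
#' sum(d$bits)
#' @export
build_dfp <- function(profile, threshold, strategy = "fixed") {
  stopifnot(inherits(profile, "fp_profile"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stop("`threshold` must be a single number", call. = FALSE)
  }
  if (threshold < 0) {
    stop("`threshold` must be non-negative", call. = FALSE)
  }
  if (threshold >= 1) {
    stop("`threshold` >= 1 would yield an all-zero fingerprint; use t < 1",
         call. = FALSE)
  }
  bits <- as.integer(profile$p > threshold)
  new_dfp(bits = bits,
          threshold = threshold,
          strategy = strategy,
          n_source = attr(profile, "n", exact = TRUE),
          scheme = attr(profile, "scheme", exact = TRUE),
          source_label = attr(profile, "source_label", exact = TRUE))
}

new_dfp <- function(bits, threshold, strategy, n_source, scheme,
                    source_label) {
  structure(list(bits = as.integer(bits),
                 threshold = as.numeric(threshold),
                 strategy = as.character(strategy),
                 n_source = as.integer(n_source),
                 scheme = scheme,
                 source_label = as.character(source_label)),
            class = "dfp")
}

#' @export
print.dfp <- function(x, ...) {
  cat(sprintf(
    "<dfp> %s [%s]: %d / %d bits set\n  threshold %.4g (%s), built from %d molecules\n",
    if (nzchar(x$source_label)) x$source_label else "(unlabelled)",
    format(x$scheme), sum(x$bits), length(x$bits),
    x$threshold, x$strategy, x$n_source))
  invisible(x)
}

#' Random-reference threshold
#'
#' Generates `n_random` random fingerprints of the scheme's length with
#' independent Bernoulli(`p`) bits and returns the mean of the resulting
#' per-bit probabilities. With the defaults (1500 vectors, 166 bits,
#' p = 0.5) this is the mean probability of a random reference population of
#' the kind used to calibrate MACCS-keys DFP thresholds; for unbiased bits it
#' concentrates tightly around `p`.
#'
#' @param scheme An [fp_scheme()] (default MACCS-166).
#' @param n_random Number of random vectors (default 1500).
#' @param p Per-bit set probability (default 0.5).
#' @param seed Integer seed; the draw is fully determined by it.
#' @return A single number in `[0, 1]`.
#' @export
threshold_random_reference <- function(scheme = fp_scheme("MACCS166"),
                                       n_random = 1500L, p = 0.5,
                                       seed = 1L) {
  ref <- generate_random_reference(n = n_random, scheme = scheme, p = p,
                                   seed = seed)
  mean(bit_probabilities(ref)$p)
}

#' Mean-plus-one-SD threshold
#'
#' The second threshold strategy: the mean of a library's own per-bit
#' probabilities plus one sample standard deviation (denominator `L - 1`),
#' clipped into `[0, 1 - eps]` so the resulting DFP is never forced all-zero.
#'
#' @param profile A probability profile from [bit_probabilities()].
#' @return A single number in `[0, 1)`.
#' @export
threshold_mean_plus_sd <- function(profile) {
  stopifnot(inherits(profile, "fp_profile"))
  p <- profile$p
  if (length(p) < 2L) {
    stop("mean-plus-sd threshold needs at least 2 bit positions",
         call. = FALSE)
  }
  t <- mean(p) + stats::sd(p)
  min(max(t, 0), 1 - sqrt(.Machine$double.eps))
}

#' Build a DFP straight from a fingerprint matrix
#'
#' Composes [bit_probabilities()], threshold selection, and [build_dfp()].
#'
#' @param matrix A [bit_matrix()].
#' @param strategy `"fixed"` (supply `threshold`), `"random_reference_mean"`
#'   (threshold from [threshold_random_reference()] with matching scheme), or
#'   `"mean_plus_sd"` (threshold from the library's own profile).
#' @param threshold Cutoff for the `"fixed"` strategy. Default 0.5, the
#'   best-resolving fixed cutoff for the PubChem-fingerprint workflow.
#' @param n_random,p,seed Parameters of the random reference (only used by
#'   `"random_reference_mean"`).
#' @return A `dfp` object.
#' @examples
#' m <- generate_random_reference(n = 200, seed = 3)
#' build_dfp_for_database(m, strategy = "fixed", threshold = 0.5)
#' @export
build_dfp_for_database <- function(matrix,
                                   strategy = c("fixed",
                                                "random_reference_mean",
                                                "mean_plus_sd"),
                                   threshold = 0.5,
                                   n_random = 1500L, p = 0.5, seed = 1L) {
  strategy <- match.arg(strategy)
  prof <- bit_probabilities(matrix)
  t <- switch(strategy,
              fixed = threshold,
              random_reference_mean = threshold_random_reference(
                scheme = fp_scheme_of(matrix), n_random = n_random, p = p,
                seed = seed),
              mean_plus_sd = threshold_mean_plus_sd(prof))
  build_dfp(prof, threshold = t, strategy = strategy)
}
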