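# Shannon entropy of per-bit probability profiles.
#
# Two per-bit variants are supported, both in bits (log base 2):
#   binary    H(p) = -p log2 p - (1-p) log2(1-p)   (entropy of the Bernoulli
#             bit; maximum 1 at p = 0.5)
#   ones_term H(p) = -p log2 p                     (the set-bit term alone;
#             maximum log2(e)/e ~ 0.5307 at p = 1/e)
# 0 * log2(0) is taken as 0 in both.

binary_entropy <- function(p) {
  h <- numeric(length(p))
  i <- p > 0 & p < 1
  h[i] <- -p[i] * log2(p[i]) - (1 - p[i]) * log2(1 - p[i])
  h
}

ones_term_entropy <- function(p) {
  h <- numeric(length(p))
  i <- p > 0
  h[i] <- -p[i] * log2(p[i])
  h
}

#' Shannon entropy of a probability profile
#'
#' Computes per-bit Shannon entropy of a library's bit-probability profile
#' and its total over all bit positions. The total (SE) serves as a library
#' diversity metric: libraries of structurally homogeneous molecules drive
#' per-bit probabilities toward 0 or 1 and thus toward zero entropy, while a
#' diverse library keeps many bits near p = 0.5 and a high SE. A random
#' reference population (independent Bernoulli(0.5) bits) attains the
#' maximum.
#'
#' @param profile An `fp_profile` from [bit_probabilities()].
#' @param mode `"binary"` (default) uses the full Bernoulli bit entropy
#'   `-p log2 p - (1-p) log2(1-p)`; `"ones_term"` uses only the set-bit term
#'   `-p log2 p`, a variant whose totals are roughly half the binary ones.
#'
#' @return A tibble of class `entropy_report` with columns `bit`, `p`, `h`
#'   (bits), and attributes `total` (sum over bits), `mean` (`total / L`),
#'   `mode`, `scheme`, `source_label`, `n`.
#'
#' @examples
#' m <- generate_random_reference(n = 1500, seed = 42)
#' rep <- shannon_entropy(bit_probabilities(m))
#' attr(rep, "total")  # near the 166-bit maximum
#' @export
shannon_entropy <- function(profile, mode = c("binary", "ones_term")) {
  stopifnot(inherits(profile, "fp_profile"))
  mode <- match.arg(mode)
  h <- switch(mode,
              binary = binary_entropy(profile$p),
              ones_term = ones_term_entropy(profile$p))
  out <- tibble::tibble(bit = profile$bit, p = profile$p, h = h)
  structure(out,
            total = sum(h),
            mean = mean(h),
            mode = mode,
            scheme = attr(profile, "scheme", exact = TRUE),
            source_label = attr(profile, "source_label", exact = TRUE),
            n = attr(profile, "n", exact = TRUE),
            class = c("entropy_report", class(tibble::tibble())))
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf(
    "<entropy_report> %s, mode = %s: total SE = %.3f bits (mean %.4f over %d bits)\n",
    if (nzchar(attr(x, "source_label"))) attr(x, "source_label")
    else "(unlabelled)",
    attr(x, "mode"), attr(x, "total"), attr(x, "mean"), nrow(x)))
  NextMethod()
}

#' Differential Shannon entropy between two libraries
#'
#' For each bit position, the binary entropy of the pooled probability minus
#' the average of the two libraries' bit entropies:
#' `DSE_i = H(p_pooled,i) - (H(p_a,i) + H(p_b,i)) / 2`.
#' Bits that are distributed alike in the two libraries score near zero;
#' bits that discriminate between them score high (maximum 1, attained when
#' one library always sets the bit and the other never does). With equal
#' library sizes the pooled probability is the plain average and concavity of
#' the entropy makes every DSE value non-negative.
#'
#' @param a,b `fp_profile` objects of the same scheme.
#' @param weighting `"size_weighted"` (default) pools the raw counts over
#'   `n_a + n_b`; `"equal"` gives both libraries the same weight, which
#'   requires equal sizes -- when they differ the larger profile is first
#'   subsampled to the smaller size by a seeded per-bit hypergeometric draw
#'   (the exact marginal distribution of subsampling molecules).
#' @param seed Seed for the equal-weighting subsample; required when sizes
#'   differ under `weighting = "equal"`.
#'
#' @return A tibble of class `dse_report` with columns `bit`, `p_a`, `p_b`,
#'   `p_pooled`, `dse` (bits), and attributes `weighting` and `labels`.
#'
#' @examples
#' a <- bit_probabilities(generate_random_reference(100, seed = 1))
#' b <- bit_probabilities(generate_random_reference(100, seed = 2))
#' d <- differential_shannon_entropy(a, b, weighting = "equal")
#' all(d$dse >= 0)
#' @export
differential_shannon_entropy <- function(a, b,
                                         weighting = c("size_weighted",
                                                       "equal"),
                                         seed = NULL) {
  stopifnot(inherits(a, "fp_profile"), inherits(b, "fp_profile"))
  weighting <- match.arg(weighting)
  if (nrow(a) != nrow(b)) {
    stop(sprintf("profiles differ in length (%d vs %d bits)",
                 nrow(a), nrow(b)), call. = FALSE)
  }
  n_a <- attr(a, "n", exact = TRUE)
  n_b <- attr(b, "n", exact = TRUE)

  if (weighting == "equal" && n_a != n_b) {
    if (is.null(seed)) {
      stop(paste0("equal weighting with unequal sizes (", n_a, " vs ", n_b,
                  ") needs `seed` for the subsampling draw"), call. = FALSE)
    }
    if (n_a > n_b) a <- subsample_profile(a, n_b, seed = seed)
    else b <- subsample_profile(b, n_a, seed = seed)
    n_a <- attr(a, "n", exact = TRUE)
    n_b <- attr(b, "n", exact = TRUE)
  }

  p_pool <- (a$count + b$count) / (n_a + n_b)
  dse <- binary_entropy(p_pool) -
    (binary_entropy(a$p) + binary_entropy(b$p)) / 2
  out <- tibble::tibble(bit = a$bit, p_a = a$p, p_b = b$p,
                        p_pooled = p_pool, dse = dse)
  structure(out,
            weighting = weighting,
            labels = c(attr(a, "source_label", exact = TRUE),
                       attr(b, "source_label", exact = TRUE)),
            class = c("dse_report", class(tibble::tibble())))
}

# Subsample a profile to m molecules without access to the rows: each bit's
# subsampled count is a hypergeometric draw (the marginal law of drawing m
# molecules without replacement). Adequate for per-bit statistics like DSE.
subsample_profile <- function(profile, m, seed) {
  n <- attr(profile, "n", exact = TRUE)
  stopifnot(m <= n)
  counts <- withr::with_seed(seed,
    stats::rhyper(nrow(profile), profile$count, n - profile$count, m))
  profile_from_counts(counts, n = m,
                      scheme = attr(profile, "scheme", exact = TRUE),
                      source_label = attr(profile, "source_label",
                                          exact = TRUE))
}

#' Export an entropy or DSE report as TSV
#'
#' Writes the per-bit table with full numeric precision; for entropy reports
#' a trailing comment line carries the total.
#'
#' @param report An `entropy_report` or `dse_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_tsv <- function(report, path) {
  df <- as.data.frame(lapply(report, function(col) {
    if (is.double(col)) format(col, digits = 17, trim = TRUE) else col
  }), check.names = FALSE)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(df, sep = "\t")))
  if (inherits(report, "entropy_report")) {
    lines <- c(lines, sprintf("#total\t%s",
                              format(attr(report, "total"), digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_entropy_tsv
#' @details `write_entropy_json()` writes the one-row [glance()] summary
#'   (label, mode, n, total, mean) as a JSON object.
#' @export
write_entropy_json <- function(report, path) {
  stopifnot(inherits(report, "entropy_report"))
  jsonlite::write_json(as.list(glance(report)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
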