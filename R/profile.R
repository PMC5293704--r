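#' Per-bit probability profile of a fingerprint library
#'
#' For each bit position records the count of molecules setting the bit and
#' the plain frequency `p = count / n`. No smoothing or pseudocounts are
#' applied: a bit never set has probability exactly 0, a bit always set
#' exactly 1.
#'
#' @param matrix A [bit_matrix()].
#'
#' @return A tibble of class `fp_profile` with columns `bit` (0-based
#'   index), `count`, and `p`, and attributes `n` (library size), `scheme`,
#'   and `source_label`.
#'
#' @examples
#' m <- bit_matrix(rbind(c(1, 0), c(0, 1)), scheme = fp_scheme("GENERIC", 2))
#' bit_probabilities(m)$p
#' @export
bit_probabilities <- function(matrix) {
  if (!inherits(matrix, "bit_matrix")) {
    stop("`matrix` must be a bit_matrix", call. = FALSE)
  }
  n <- nrow(matrix)
  counts <- as.integer(colSums(as_plain_matrix(matrix)))
  out <- tibble::tibble(
    bit = seq_along(counts) - 1L,
    count = counts,
    p = counts / n
  )
  new_fp_profile(out, n = n, scheme = fp_scheme_of(matrix),
                 source_label = fp_source_label(matrix))
}

new_fp_profile <- function(tbl, n, scheme, source_label) {
  structure(tbl,
            n = as.integer(n),
            scheme = scheme,
            source_label = as.character(source_label),
            class = c("fp_profile", class(tibble::tibble())))
}

#' Construct a probability profile from raw counts
#'
#' Occasionally useful when per-bit counts come from an external tool rather
#' than a matrix held in memory.
#'
#' @param counts Integer vector of per-bit set counts.
#' @param n Library size; every count must lie in `[0, n]`.
#' @param scheme An [fp_scheme()]; inferred from `length(counts)` if absent.
#' @param source_label Library label.
#' @return An `fp_profile` tibble, as from [bit_probabilities()].
#' @export
profile_from_counts <- function(counts, n, scheme = NULL,
                                source_label = "") {
  counts <- as.integer(counts)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be positive", call. = FALSE)
  if (any(counts < 0L) || any(counts > n)) {
    stop("counts must lie in [0, n]", call. = FALSE)
  }
  if (is.null(scheme)) scheme <- scheme_from_length(length(counts))
  if (scheme$length != length(counts)) {
    stop("length(counts) must equal the scheme length", call. = FALSE)
  }
  out <- tibble::tibble(bit = seq_along(counts) - 1L, count = counts,
                        p = counts / n)
  new_fp_profile(out, n = n, scheme = scheme, source_label = source_label)
}

#' @export
print.fp_profile <- function(x, ...) {
  cat(sprintf("<fp_profile> %s [%s], n = %d molecules\n",
              if (nzchar(attr(x, "source_label"))) attr(x, "source_label")
              else "(unlabelled)",
              format(attr(x, "scheme")), attr(x, "n")))
  NextMethod()
}
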