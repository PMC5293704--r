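#' Fingerprint schemes
#'
#' A fingerprint scheme names the bit dictionary a fingerprint was computed
#' with and fixes its length `L`. Two dictionary schemes are built in --
#' MACCS structural keys (166 bits) and the PubChem substructure fingerprint
#' (881 bits) -- and `"GENERIC"` covers any other fixed-length binary scheme.
#'
#' @param name One of `"MACCS166"`, `"PUBCHEM881"`, `"GENERIC"`.
#' @param length Number of bits. Implied (and checked) for the two dictionary
#'   schemes; required for `"GENERIC"`.
#'
#' @return An object of class `fp_scheme`: a list with elements `name` and
#'   `length`.
#'
#' @examples
#' fp_scheme("MACCS166")
#' fp_scheme("GENERIC", length = 1024)
#' @export
fp_scheme <- function(name = c("MACCS166", "PUBCHEM881", "GENERIC"),
                      length = NULL) {
  name <- match.arg(name)
  fixed <- c(MACCS166 = 166L, PUBCHEM881 = 881L)
  if (name %in% names(fixed)) {
    if (!is.null(length) && as.integer(length) != fixed[[name]]) {
      stop(sprintf("scheme %s has %d bits, not %s", name, fixed[[name]],
                   format(length)), call. = FALSE)
    }
    length <- fixed[[name]]
  } else {
    if (is.null(length)) {
      stop("a GENERIC scheme needs an explicit bit length", call. = FALSE)
    }
    length <- as.integer(length)
    if (is.na(length) || length < 1L) {
      stop("scheme length must be a positive integer", call. = FALSE)
    }
  }
  structure(list(name = name, length = as.integer(length)),
            class = "fp_scheme")
}

#' @export
print.fp_scheme <- function(x, ...) {
  cat(sprintf("<fp_scheme> %s (%d bits)\n", x$name, x$length))
  invisible(x)
}

#' @export
format.fp_scheme <- function(x, ...) sprintf("%s/%d", x$name, x$length)

# Infer a scheme from a bit count: the two dictionary lengths are recognised,
# anything else is GENERIC.
scheme_from_length <- function(n_bits) {
  n_bits <- as.integer(n_bits)
  if (n_bits == 166L) return(fp_scheme("MACCS166"))
  if (n_bits == 881L) return(fp_scheme("PUBCHEM881"))
  fp_scheme("GENERIC", length = n_bits)
}

is_fp_scheme <- function(x) inherits(x, "fp_scheme")

same_scheme <- function(a, b) identical(a$length, b$length)
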