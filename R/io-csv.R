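#' Read and write CSV/TSV bit-matrix files
#'
#' Two dialects are supported, auto-detected from the header line: *narrow*
#' (an id column plus one column holding the whole fingerprint as a 0/1
#' string) and *wide* (an id column plus `L` separate 0/1 columns). The field
#' separator (comma or tab) is likewise detected from the header.
#'
#' @param path File path.
#' @param scheme An [fp_scheme()] fixing the expected bit length `L`.
#' @param source_label Library label; defaults to the file name.
#'
#' @return `read_bit_csv()` returns a [bit_matrix()]; `write_bit_csv()`
#'   returns `path` invisibly.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,bits", "m1,101", "m2,011"), f)
#' read_bit_csv(f, fp_scheme("GENERIC", 3))
#' @export
read_bit_csv <- function(path, scheme, source_label = NULL) {
  stopifnot(is_fp_scheme(scheme))
  L <- scheme$length
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("bit CSV needs a header line and at least one record: ", path,
         call. = FALSE)
  }
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  wide <- length(header) > 2L
  if (wide && length(header) != L + 1L) {
    stop(sprintf(
      "bit CSV header has %d columns; expected 2 (narrow) or %d (wide) for L=%d",
      length(header), L + 1L, L), call. = FALSE)
  }

  rows <- strsplit(lines[-1L], sep, fixed = TRUE)
  ids <- character(length(rows))
  bits <- matrix(0L, nrow = length(rows), ncol = L)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    ids[i] <- r[[1L]]
    digits <- if (wide) r[-1L] else
      strsplit(r[[2L]], "", fixed = TRUE)[[1L]]
    if (length(digits) != L) {
      stop(sprintf(
        "bit CSV validation error at row %d (id '%s'): %d bits, expected %d",
        i, ids[i], length(digits), L), call. = FALSE)
    }
    if (any(!(digits %in% c("0", "1")))) {
      stop(sprintf(
        "bit CSV validation error at row %d (id '%s'): characters outside {0,1}",
        i, ids[i]), call. = FALSE)
    }
    bits[i, ] <- as.integer(digits)
  }
  bit_matrix(bits, ids = ids, scheme = scheme,
             source_label = source_label %||% basename(path))
}

#' @rdname read_bit_csv
#' @param matrix A [bit_matrix()].
#' @param dialect `"narrow"` (id + bitstring) or `"wide"` (id + L columns).
#' @param sep Field separator, `","` or `"\t"`.
#' @export
write_bit_csv <- function(matrix, path, dialect = c("narrow", "wide"),
                          sep = ",") {
  stopifnot(inherits(matrix, "bit_matrix"))
  dialect <- match.arg(dialect)
  m <- as_plain_matrix(matrix)
  if (dialect == "narrow") {
    body <- paste(fp_ids(matrix),
                  apply(m, 1L, paste, collapse = ""), sep = sep)
    header <- paste("id", "bits", sep = sep)
  } else {
    body <- paste(fp_ids(matrix),
                  apply(m, 1L, paste, collapse = sep), sep = sep)
    header <- paste(c("id", paste0("bit", seq_len(ncol(m)) - 1L)),
                    collapse = sep)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
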