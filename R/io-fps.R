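#' Read and write FPS v1 fingerprint files
#'
#' FPS is the de-facto plain-text interchange format for hex-encoded binary
#' fingerprints: header lines starting with `#` (one of which must declare
#' `num_bits`), then one `hex TAB identifier` record per molecule. Bit `k`
#' (0-based) lives in byte `k %/% 8` with mask `2^(k %% 8)`; pad bits beyond
#' `num_bits` in the last byte are written as zero.
#'
#' @param path File path.
#' @param source_label Library label to attach; defaults to the file's
#'   `#source=` header, else the file name.
#' @param dedupe_ids Duplicate identifiers are an error by default; set
#'   `TRUE` to disambiguate them with [make.unique()] instead (used by the
#'   structure adapter, where repeated titles are legitimate).
#'
#' @return `read_fps()` returns a [bit_matrix()]; `write_fps()` returns
#'   `path` invisibly.
#'
#' @examples
#' m <- generate_random_reference(n = 5, seed = 1)
#' f <- tempfile(fileext = ".fps")
#' write_fps(m, f)
#' identical(unclass(read_fps(f)), unclass(m))
#' @export
read_fps <- function(path, source_label = NULL, dedupe_ids = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_header <- startsWith(lines, "#")
  headers <- lines[is_header]
  records <- lines[!is_header]
  rec_lineno <- which(!is_header)

  nb_lines <- headers[startsWith(headers, "#num_bits=")]
  nb_vals <- unique(sub("^#num_bits=", "", nb_lines))
  if (length(nb_vals) == 0L) {
    stop("FPS format error: no #num_bits= header in ", path, call. = FALSE)
  }
  if (length(nb_vals) > 1L) {
    stop("FPS format error: contradictory #num_bits= headers (",
         paste(nb_vals, collapse = ", "), ")", call. = FALSE)
  }
  num_bits <- suppressWarnings(as.integer(nb_vals))
  if (is.na(num_bits) || num_bits < 1L) {
    stop("FPS format error: invalid num_bits value '", nb_vals, "'",
         call. = FALSE)
  }
  if (length(records) == 0L) {
    stop("FPS file contains no fingerprint records: ", path, call. = FALSE)
  }

  n_bytes <- ceiling(num_bits / 8L)
  parts <- strsplit(records, "\t", fixed = TRUE)
  hex <- vapply(parts, `[[`, character(1L), 1L)
  ids <- vapply(parts, function(p) {
    if (length(p) >= 2L) p[[2L]] else ""
  }, character(1L))
  if (any(!nzchar(ids))) {
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
  }

  bad_len <- nchar(hex) != 2L * n_bytes
  if (any(bad_len)) {
    i <- which(bad_len)[1L]
    stop(sprintf(
      "FPS record error at line %d: hex field has %d characters, expected %d for num_bits=%d",
      rec_lineno[i], nchar(hex[i]), 2L * n_bytes, num_bits), call. = FALSE)
  }

  bits <- matrix(0L, nrow = length(hex), ncol = num_bits)
  for (i in seq_along(hex)) {
    bytes <- hex_to_bytes(hex[i])
    if (is.null(bytes)) {
      stop(sprintf("FPS record error at line %d: invalid hex characters",
                   rec_lineno[i]), call. = FALSE)
    }
    row <- as.vector(t(byte_bits_table[bytes + 1L, , drop = FALSE]))
    bits[i, ] <- row[seq_len(num_bits)]
  }

  if (is.null(source_label)) {
    src <- headers[startsWith(headers, "#source=")]
    source_label <- if (length(src)) sub("^#source=", "", src[1L]) else
      basename(path)
  }
  if (anyDuplicated(ids)) {
    if (dedupe_ids) {
      ids <- make.unique(ids, sep = "_dup")
    } else {
      dup <- unique(ids[duplicated(ids)])
      stop(sprintf("FPS validation error: duplicate identifier(s): %s",
                   paste(utils::head(dup, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bit_matrix(bits, ids = ids, scheme = scheme_from_length(num_bits),
             source_label = source_label)
}

#' @rdname read_fps
#' @param matrix A [bit_matrix()].
#' @export
write_fps <- function(matrix, path) {
  stopifnot(inherits(matrix, "bit_matrix"))
  sch <- fp_scheme_of(matrix)
  hex <- apply(as_plain_matrix(matrix), 1L,
               function(row) bytes_to_hex(bits_to_bytes(row)))
  lbl <- fp_source_label(matrix)
  header <- c("#FPS1",
              sprintf("#num_bits=%d", sch$length),
              sprintf("#type=%s", sch$name),
              "#software=dfptools",
              if (nzchar(lbl)) sprintf("#source=%s", lbl))
  writeLines(c(header, paste(hex, fp_ids(matrix), sep = "\t")), path)
  invisible(path)
}
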