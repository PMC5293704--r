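#' Binary fingerprint matrices
#'
#' A `bit_matrix` is the raw representation of a compound library: an
#' `n x L` matrix over \{0, 1\} with one row per molecule, row names holding
#' the molecule identifiers, plus the [fp_scheme()] and a free-text source
#' label (typically the database name).
#'
#' @param bits A numeric/integer/logical matrix containing only 0 and 1,
#'   one molecule per row.
#' @param ids Character vector of unique molecule identifiers, one per row.
#'   Defaults to existing row names, or `mol1 ... moln`.
#' @param scheme An [fp_scheme()]; inferred from the column count when absent.
#' @param source_label Free-text name of the library.
#'
#' @return An object of class `bit_matrix`: an integer matrix with attributes
#'   `scheme` and `source_label`.
#'
#' @examples
#' m <- bit_matrix(rbind(c(1, 0, 1), c(0, 1, 1)), ids = c("a", "b"),
#'                 scheme = fp_scheme("GENERIC", 3))
#' fp_ids(m)
#' @export
bit_matrix <- function(bits, ids = NULL, scheme = NULL, source_label = "") {
  if (!is.matrix(bits)) bits <- matrix(bits, nrow = 1L)
  storage.mode(bits) <- "integer"
  if (nrow(bits) < 1L) stop("a bit_matrix needs at least one molecule",
                            call. = FALSE)
  bad <- !(bits %in% c(0L, 1L))
  if (any(bad)) {
    stop(sprintf("bit matrix contains %d entries outside {0, 1}", sum(bad)),
         call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- rownames(bits)
    if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(bits)))
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(bits)) {
    stop("length(ids) must equal the number of rows", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate molecule identifier(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(scheme)) scheme <- scheme_from_length(ncol(bits))
  stopifnot(is_fp_scheme(scheme))
  if (ncol(bits) != scheme$length) {
    stop(sprintf("matrix has %d columns but scheme %s expects %d bits",
                 ncol(bits), scheme$name, scheme$length), call. = FALSE)
  }
  rownames(bits) <- ids
  colnames(bits) <- NULL
  structure(bits,
            scheme = scheme,
            source_label = as.character(source_label)[1L],
            class = c("bit_matrix", "matrix", "array"))
}

#' @rdname bit_matrix
#' @param x A `bit_matrix`.
#' @export
fp_ids <- function(x) rownames(x)

#' @rdname bit_matrix
#' @export
fp_scheme_of <- function(x) attr(x, "scheme", exact = TRUE)

#' @rdname bit_matrix
#' @export
fp_source_label <- function(x) attr(x, "source_label", exact = TRUE)

#' @export
print.bit_matrix <- function(x, ...) {
  sch <- fp_scheme_of(x)
  lbl <- fp_source_label(x)
  cat(sprintf("<bit_matrix> %d molecules x %d bits [%s]%s\n",
              nrow(x), ncol(x), format(sch),
              if (nzchar(lbl)) paste0(" \"", lbl, "\"") else ""))
  dens <- mean(x)
  cat(sprintf("  bit density %.3f; first ids: %s\n", dens,
              paste(utils::head(rownames(x), 3L), collapse = ", ")))
  invisible(x)
}

#' Stack two fingerprint matrices of the same scheme
#'
#' Row-binds two libraries; identifiers of the second block are suffixed when
#' they collide with the first. Mostly useful for pooled analyses and for
#' duplication-invariance checks.
#'
#' @param a,b `bit_matrix` objects with the same scheme.
#' @param source_label Label for the combined matrix.
#' @return A `bit_matrix`.
#' @export
bind_bit_matrices <- function(a, b, source_label = "") {
  if (ncol(a) != ncol(b)) stop("schemes differ in length", call. = FALSE)
  ids <- c(rownames(a), rownames(b))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_dup")
  }
  bit_matrix(rbind(unclass(a), unclass(b)), ids = ids,
             scheme = fp_scheme_of(a), source_label = source_label)
}

# strip class/attrs down to a plain integer matrix
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "scheme") <- NULL
  attr(y, "source_label") <- NULL
  y
}

# validate a 0/1 vector argument (similarity ops accept bare vectors,
# bit_matrix rows, or dfp objects)
as_bit_vector <- function(x, arg = "x") {
  if (inherits(x, "dfp")) x <- x$bits
  x <- as.integer(x)
  if (any(is.na(x)) || any(!(x %in% c(0L, 1L)))) {
    stop(sprintf("`%s` must be a binary 0/1 vector", arg), call. = FALSE)
  }
  x
}
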