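#' Read and write DFP record files
#'
#' The package-native, plain-text serialization of a database fingerprint:
#' a `#DFPv1` version line, `#key=value` provenance headers (scheme, bit
#' count, threshold at full precision, strategy, source size and label), and
#' a single line of `L` characters over \{0,1\}. Round-trips are bit-exact
#' and metadata-exact.
#'
#' @param dfp A `dfp` object from [build_dfp()].
#' @param path File path.
#' @return `write_dfp_record()` returns `path` invisibly;
#'   `read_dfp_record()` returns a `dfp`.
#' @examples
#' m <- generate_random_reference(n = 50, seed = 2)
#' d <- build_dfp_for_database(m, threshold = 0.55)
#' f <- tempfile(fileext = ".dfp")
#' write_dfp_record(d, f)
#' identical(read_dfp_record(f), d)
#' @export
write_dfp_record <- function(dfp, path) {
  stopifnot(inherits(dfp, "dfp"))
  lines <- c(
    "#DFPv1",
    sprintf("#scheme=%s", dfp$scheme$name),
    sprintf("#num_bits=%d", dfp$scheme$length),
    sprintf("#threshold=%s", format(dfp$threshold, digits = 17)),
    sprintf("#strategy=%s", dfp$strategy),
    sprintf("#n_source=%d", dfp$n_source),
    sprintf("#source_label=%s", dfp$source_label),
    paste(dfp$bits, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dfp_record
#' @export
read_dfp_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L || lines[1L] != "#DFPv1") {
    stop("DFP record format error: expected #DFPv1 version line in ", path,
         call. = FALSE)
  }
  headers <- lines[startsWith(lines, "#")][-1L]
  body <- lines[!startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", headers), "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, function(x) {
    paste(x[-1L], collapse = "=")
  }, character(1L))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("DFP record format error: missing #", k, " header",
                       call. = FALSE)
    vals[i]
  }
  num_bits <- as.integer(get("num_bits"))
  if (length(body) != 1L) {
    stop("DFP record format error: expected exactly one bitstring line",
         call. = FALSE)
  }
  digits <- strsplit(body, "", fixed = TRUE)[[1L]]
  if (length(digits) != num_bits || any(!(digits %in% c("0", "1")))) {
    stop(sprintf(
      "DFP record format error: bitstring must be %d characters over {0,1}",
      num_bits), call. = FALSE)
  }
  scheme_name <- get("scheme")
  scheme <- if (scheme_name %in% c("MACCS166", "PUBCHEM881")) {
    fp_scheme(scheme_name)
  } else {
    fp_scheme("GENERIC", length = num_bits)
  }
  if (scheme$length != num_bits) {
    stop("DFP record format error: num_bits contradicts scheme",
         call. = FALSE)
  }
  new_dfp(bits = as.integer(digits),
          threshold = as.numeric(get("threshold")),
          strategy = get("strategy"),
          n_source = as.integer(get("n_source")),
          scheme = scheme,
          source_label = get("source_label"))
}
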