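#' Compute MACCS-166 fingerprints from structure files
#'
#' Adapter from chemical structures to a [bit_matrix()], backed by the
#' OpenBabel command-line tool (`obabel`), which emits MACCS keys in FPS
#' format that the package then ingests with [read_fps()]. OpenBabel's MACCS
#' implementation reports the 166 dictionary keys (key `k`, 1-based, maps to
#' column `k - 1`). Molecules that fail structure parsing are skipped with a
#' warning naming how many were lost; identifiers come from the SMILES title
#' field / SDF title line, with `mol<i>` filled in where missing.
#'
#' @param path A SMILES file (`.smi`/`.ism`/`.can`, one molecule per line,
#'   optional whitespace-separated id) or an SDF (`.sdf`/`.mol`).
#' @param source_label Library label; defaults to the file name.
#' @param obabel Path to the `obabel` executable (found on `PATH` by
#'   default).
#' @return A [bit_matrix()] with scheme `MACCS166`.
#' @export
structures_to_maccs <- function(path, source_label = NULL,
                                obabel = Sys.which("obabel")) {
  if (!nzchar(obabel)) {
    stop(paste0(
      "no fingerprint backend: the `obabel` executable was not found on ",
      "PATH.\nInstall OpenBabel, or supply precomputed fingerprints via ",
      "read_fps()/read_bit_csv()."), call. = FALSE)
  }
  if (!file.exists(path)) stop("structure file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext,
                smi = , ism = , can = "smi",
                sdf = , mol = , mdl = "sdf",
                stop("unrecognised structure format '.", ext,
                     "' (expected .smi or .sdf)", call. = FALSE))
  n_in <- count_structures(path, fmt)

  out <- tempfile(fileext = ".fps")
  on.exit(unlink(out), add = TRUE)
  log <- suppressWarnings(system2(
    obabel, c(paste0("-i", fmt), shQuote(path), "-ofps", "-xfMACCS",
              "-e", "-O", shQuote(out)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status") %||% 0L
  if (!file.exists(out) || file.size(out) == 0L) {
    stop("fingerprint backend produced no output (zero parseable ",
         "molecules?):\n", paste(log, collapse = "\n"), call. = FALSE)
  }
  m <- read_fps(out, source_label = source_label %||% basename(path),
                dedupe_ids = TRUE)
  if (nrow(m) == 0L) {
    stop("zero parseable molecules in ", path, call. = FALSE)
  }
  if (!is.na(n_in) && nrow(m) < n_in) {
    warning(sprintf(
      "%d of %d structures in %s failed to parse and were skipped",
      n_in - nrow(m), n_in, basename(path)), call. = FALSE)
  }
  if (status != 0L) {
    warning("fingerprint backend reported: ",
            paste(log, collapse = "; "), call. = FALSE)
  }
  m
}

count_structures <- function(path, fmt) {
  lines <- readLines(path, warn = FALSE)
  if (fmt == "smi") {
    sum(nzchar(trimws(lines)))
  } else {
    sum(lines == "$$$$") + as.integer(length(lines) > 0L &&
                                        lines[length(lines)] != "$$$$")
  }
}
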