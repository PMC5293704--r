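#' Select informationally significant bit positions across libraries
#'
#' Reduces the fingerprint to the bit positions that carry discriminating
#' information across a collection of libraries. Three explicit rules are
#' offered:
#'
#' * `"union_of_dfps"` (default): a bit is kept iff it is set in at least
#'   one library's DFP at `dfp_threshold` — i.e. some library sets it in
#'   more than a `dfp_threshold` fraction of its molecules. Raising the
#'   threshold can only shrink the selection.
#' * `"pooled_entropy_cutoff"`: a bit is kept iff the binary entropy of the
#'   size-weighted pooled probability is at least `cutoff` bits.
#' * `"dse_cutoff"`: a bit is kept iff its maximum pairwise differential
#'   Shannon entropy over all library pairs is at least `cutoff` bits.
#'
#' The entropy- and DSE-based rules can additionally be intersected with the
#' DFP-support union via `within_dfp_support = TRUE`.
#'
#' @param profiles A list of at least two `fp_profile` objects (same scheme).
#' @param dfp_threshold DFP probability threshold (default 0.5).
#' @param rule Selection rule, see above.
#' @param cutoff Entropy/DSE cutoff in bits (used by the two cutoff rules).
#' @param within_dfp_support If `TRUE`, restrict cutoff-rule selections to
#'   bits surviving the DFP threshold in at least one library.
#' @return An object of class `bit_selection`: a list with `selected`
#'   (sorted 0-based indices), `rule`, `threshold_used`, `cutoff`, and
#'   `n_selected`.
#' @examples
#' ms <- make_library_ladder(3, n = 200, seed = 2)
#' profs <- lapply(ms, bit_probabilities)
#' select_significant_bits(profs, dfp_threshold = 0.5)
#' @export
select_significant_bits <- function(profiles, dfp_threshold = 0.5,
                                    rule = c("union_of_dfps",
                                             "pooled_entropy_cutoff",
                                             "dse_cutoff"),
                                    cutoff = 0.1,
                                    within_dfp_support = FALSE) {
  rule <- match.arg(rule)
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("`profiles` must be a list of at least 2 probability profiles",
         call. = FALSE)
  }
  if (!all(vapply(profiles, inherits, logical(1L), "fp_profile"))) {
    stop("every element of `profiles` must be an fp_profile", call. = FALSE)
  }
  lens <- vapply(profiles, nrow, integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("profiles have mixed bit lengths", call. = FALSE)
  }
  L <- lens[1L]

  p_mat <- vapply(profiles, `[[`, numeric(L), "p")       # L x k
  union_support <- rowSums(p_mat > dfp_threshold) > 0

  keep <- switch(rule,
    union_of_dfps = union_support,
    pooled_entropy_cutoff = {
      counts <- Reduce(`+`, lapply(profiles, `[[`, "count"))
      n_tot <- sum(vapply(profiles, attr, integer(1L), "n"))
      binary_entropy(counts / n_tot) >= cutoff
    },
    dse_cutoff = {
      k <- length(profiles)
      max_dse <- rep(0, L)
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          d <- differential_shannon_entropy(profiles[[i]], profiles[[j]],
                                            weighting = "size_weighted")
          max_dse <- pmax(max_dse, d$dse)
        }
      }
      max_dse >= cutoff
    })
  if (within_dfp_support && rule != "union_of_dfps") {
    keep <- keep & union_support
  }

  selected <- which(keep) - 1L
  structure(list(selected = selected,
                 rule = rule,
                 threshold_used = dfp_threshold,
                 cutoff = if (rule == "union_of_dfps") NA_real_ else cutoff,
                 n_selected = length(selected)),
            class = "bit_selection")
}

#' @export
print.bit_selection <- function(x, ...) {
  cat(sprintf("<bit_selection> %d bits selected (rule %s, DFP threshold %.3g%s)\n",
              x$n_selected, x$rule, x$threshold_used,
              if (!is.na(x$cutoff)) sprintf(", cutoff %.3g", x$cutoff)
              else ""))
  if (x$n_selected) {
    cat("  ", paste(utils::head(x$selected, 15L), collapse = " "),
        if (x$n_selected > 15L) "..." else "", "\n")
  }
  invisible(x)
}

# subset a bit_matrix to selected (0-based) bit columns
restrict_bits <- function(matrix, selection) {
  cols <- selection$selected + 1L
  if (length(cols) < 1L) {
    stop("bit selection is empty; nothing to analyse", call. = FALSE)
  }
  bit_matrix(as_plain_matrix(matrix)[, cols, drop = FALSE],
             ids = fp_ids(matrix),
             scheme = fp_scheme("GENERIC", length = length(cols)),
             source_label = fp_source_label(matrix))
}

#' Per-library entropy and DFP-similarity summary
#'
#' The two coordinates used to place libraries in diversity space: the mean
#' per-bit binary Shannon entropy (`se_mean`, in `[0, 1]`) and the mean
#' Tanimoto similarity of each molecule to the library's own DFP
#' (`dfp_similarity_mean`). Analysis can be restricted to a
#' [select_significant_bits()] selection, which changes the bit positions
#' analysed but never the molecule count.
#'
#' @param matrices A (preferably named) list of [bit_matrix()] objects
#'   sharing a scheme.
#' @param dfp_threshold Threshold for each library's own DFP (default 0.5).
#' @param bit_selection Optional `bit_selection` restricting the analysis.
#' @return A tibble of class `library_summary` with columns `label`, `n`,
#'   `se_mean`, `dfp_similarity_mean`.
#' @examples
#' ms <- make_library_ladder(3, n = 200, seed = 2)
#' summarize_libraries(ms)
#' @export
summarize_libraries <- function(matrices, dfp_threshold = 0.5,
                                bit_selection = NULL) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    stop("`matrices` must be a non-empty list of bit_matrix objects",
         call. = FALSE)
  }
  lens <- vapply(matrices, ncol, integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("libraries have mixed bit lengths", call. = FALSE)
  }
  rows <- purrr::map(matrices, function(m) {
    if (!is.null(bit_selection)) m <- restrict_bits(m, bit_selection)
    prof <- bit_probabilities(m)
    se <- shannon_entropy(prof, mode = "binary")
    d <- build_dfp(prof, threshold = dfp_threshold)
    sim <- intra_set_vs_dfp(m, d)
    tibble::tibble(label = fp_source_label(m), n = nrow(m),
                   se_mean = attr(se, "mean", exact = TRUE),
                   dfp_similarity_mean = sim$mean)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(names(matrices))) {
    blank <- !nzchar(out$label)
    out$label[blank] <- names(matrices)[blank]
  }
  class(out) <- c("library_summary", class(out))
  out
}

#' Group libraries by k-means in entropy-similarity space
#'
#' Clusters libraries on the `(se_mean, dfp_similarity_mean)` plane with
#' seeded multi-restart k-means (Lloyd's algorithm, Euclidean distance). The
#' two axes are z-score standardized by default so neither dominates by
#' scale; the best of `n_restarts` random initialisations is kept.
#'
#' @param rows A `library_summary` tibble from [summarize_libraries()].
#' @param k Number of clusters (default 5).
#' @param seed Integer seed; same seed and data give identical clusters.
#' @param n_restarts Random restarts (default 10).
#' @param standardize Z-score the two axes first (default `TRUE`).
#' @return A tibble of class `library_clusters`: the input rows plus a
#'   `cluster` column, with attributes `centroids` (k x 2, original scale),
#'   `inertia` (total within-cluster sum of squares in the clustering
#'   space), `k`, `seed`, `n_restarts`, `standardized`.
#' @examples
#' ms <- make_library_ladder(6, n = 150, seed = 3)
#' kmeans_libraries(summarize_libraries(ms), k = 2, seed = 7)
#' @export
kmeans_libraries <- function(rows, k = 5L, seed = 1L, n_restarts = 10L,
                             standardize = TRUE) {
  stopifnot(is.data.frame(rows))
  if (!all(c("se_mean", "dfp_similarity_mean") %in% names(rows))) {
    stop("`rows` must carry se_mean and dfp_similarity_mean columns",
         call. = FALSE)
  }
  k <- as.integer(k)
  n <- nrow(rows)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k > n) {
    stop(sprintf("`k` (%d) cannot exceed the number of libraries (%d)",
                 k, n), call. = FALSE)
  }
  x <- cbind(se = rows$se_mean, sim = rows$dfp_similarity_mean)
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    xs <- scale(x, center = mu, scale = sdv)
  } else {
    mu <- c(0, 0); sdv <- c(1, 1)
    xs <- x
  }
  fit <- withr::with_seed(seed,
    stats::kmeans(xs, centers = k, nstart = n_restarts,
                  algorithm = "Lloyd", iter.max = 300L))
  centroids <- sweep(sweep(fit$centers, 2L, sdv, `*`), 2L, mu, `+`)
  out <- tibble::as_tibble(rows)
  out$cluster <- as.integer(fit$cluster)
  structure(out,
            centroids = centroids,
            inertia = fit$tot.withinss,
            k = k, seed = as.integer(seed),
            n_restarts = as.integer(n_restarts),
            standardized = standardize,
            class = c("library_clusters", class(tibble::tibble())))
}
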