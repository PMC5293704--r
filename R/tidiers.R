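#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a database fingerprint
#'
#' @param x A `dfp` object.
#' @param ... Unused.
#' @return A tibble with columns `bit` (0-based) and `value` (0/1).
#' @method tidy dfp
#' @export
tidy.dfp <- function(x, ...) {
  tibble::tibble(bit = seq_along(x$bits) - 1L, value = x$bits)
}

#' One-row summary of a database fingerprint
#'
#' @param x A `dfp` object.
#' @param ... Unused.
#' @return A one-row tibble: `source_label`, `scheme`, `n_bits`,
#'   `n_source`, `threshold`, `strategy`, `popcount`, `density`.
#' @method glance dfp
#' @export
glance.dfp <- function(x, ...) {
  tibble::tibble(
    source_label = x$source_label,
    scheme = x$scheme$name,
    n_bits = length(x$bits),
    n_source = x$n_source,
    threshold = x$threshold,
    strategy = x$strategy,
    popcount = sum(x$bits),
    density = mean(x$bits)
  )
}

#' One-row summary of an entropy report
#'
#' @param x An `entropy_report` from [shannon_entropy()].
#' @param ... Unused.
#' @return A one-row tibble: `source_label`, `mode`, `n`, `n_bits`,
#'   `total` (total SE, bits), `mean`.
#' @method glance entropy_report
#' @export
glance.entropy_report <- function(x, ...) {
  tibble::tibble(
    source_label = attr(x, "source_label", exact = TRUE),
    mode = attr(x, "mode", exact = TRUE),
    n = attr(x, "n", exact = TRUE),
    n_bits = nrow(x),
    total = attr(x, "total", exact = TRUE),
    mean = attr(x, "mean", exact = TRUE)
  )
}

#' Tidy an inter-set distance matrix
#'
#' @param x A `dfp_dist` from [inter_set_matrix()].
#' @param ... Unused.
#' @return A long tibble with columns `from`, `to`, `distance` (one row per
#'   unordered pair, plus the zero diagonal omitted).
#' @method tidy dfp_dist
#' @export
tidy.dfp_dist <- function(x, ...) {
  labels <- rownames(x)
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(from = labels[idx[, 1L]],
                 to = labels[idx[, 2L]],
                 distance = m[idx])
}

#' One-row summary of a library clustering
#'
#' @param x A `library_clusters` from [kmeans_libraries()].
#' @param ... Unused.
#' @return A one-row tibble: `k`, `inertia`, `n_restarts`, `seed`,
#'   `standardized`, `n_libraries`.
#' @method glance library_clusters
#' @export
glance.library_clusters <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k", exact = TRUE),
    inertia = attr(x, "inertia", exact = TRUE),
    n_restarts = attr(x, "n_restarts", exact = TRUE),
    seed = attr(x, "seed", exact = TRUE),
    standardized = attr(x, "standardized", exact = TRUE),
    n_libraries = nrow(x)
  )
}
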