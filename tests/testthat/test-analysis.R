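make_profiles <- function(n_libs = 3, n = 200, seed = 1) {
  lapply(seq_len(n_libs), function(i) {
    bit_probabilities(random_bit_matrix(n, 60, p = 0.3 + 0.15 * i,
                                        seed = seed + i,
                                        label = paste0("lib", i)))
  })
}

test_that("union-of-DFPs selection equals the DFP support for clones", {
  m <- random_bit_matrix(100, 60, p = 0.5, seed = 3)
  prof <- bit_probabilities(m)
  sel <- select_significant_bits(list(prof, prof), dfp_threshold = 0.5)
  d <- build_dfp(prof, 0.5)
  expect_equal(sel$selected, which(d$bits == 1L) - 1L)
  expect_equal(sel$n_selected, sum(d$bits))
})

test_that("selection count is non-increasing in the DFP threshold", {
  profs <- make_profiles()
  ns <- vapply(c(0.5, 0.6, 0.7), function(t) {
    sel <- select_significant_bits(profs, dfp_threshold = t)
    # subset relation, not just counts
    expect_true(all(sel$selected %in%
                      select_significant_bits(profs,
                                              dfp_threshold = 0.5)$selected))
    sel$n_selected
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("DSE rule isolates the discriminating bit", {
  a <- profile_from_counts(c(5L, 5L, 10L), n = 10,
                           scheme = fp_scheme("GENERIC", 3))
  b <- profile_from_counts(c(5L, 5L, 0L), n = 10,
                           scheme = fp_scheme("GENERIC", 3))
  sel <- select_significant_bits(list(a, b), rule = "dse_cutoff",
                                 cutoff = 1e-12)
  expect_equal(sel$selected, 2L)  # only the p=1 vs p=0 bit has nonzero DSE
})

test_that("pooled-entropy rule keeps bits the pooled profile leaves uncertain", {
  a <- profile_from_counts(c(10L, 0L, 5L), n = 10,
                           scheme = fp_scheme("GENERIC", 3))
  b <- profile_from_counts(c(10L, 0L, 5L), n = 10,
                           scheme = fp_scheme("GENERIC", 3))
  sel <- select_significant_bits(list(a, b), rule = "pooled_entropy_cutoff",
                                 cutoff = 0.9)
  expect_equal(sel$selected, 2L)  # pooled p: 1, 0, 0.5 -> entropies 0, 0, 1
})

test_that("selection inputs are validated", {
  profs <- make_profiles()
  expect_error(select_significant_bits(profs[1]), "at least 2")
  short <- bit_probabilities(random_bit_matrix(10, 30, seed = 1))
  expect_error(select_significant_bits(c(profs[1], list(short))), "mixed")
})

test_that("library summaries land in the expected corners", {
  clone_row <- unclass(random_bit_matrix(1, 166, p = 0.5, seed = 2))[1, ]
  clones <- bit_matrix(matrix(rep(clone_row, each = 50), nrow = 50),
                       scheme = fp_scheme("MACCS166"),
                       source_label = "clones")
  rnd <- generate_random_reference(n = 500, seed = 8)
  summary <- summarize_libraries(list(clones = clones, random = rnd),
                                 dfp_threshold = 0.5)
  expect_equal(summary$se_mean[1], 0)
  expect_equal(summary$dfp_similarity_mean[1], 1.0)
  expect_gt(summary$se_mean[2], 0.95)          # near the binary maximum
  expect_lt(summary$dfp_similarity_mean[2], 0.6)
  expect_equal(summary$n, c(50L, 500L))
})

test_that("restricting to a bit selection changes columns, never n", {
  ms <- make_library_ladder(3, n = 150, seed = 12)
  profs <- lapply(ms, bit_probabilities)
  sel <- select_significant_bits(profs, dfp_threshold = 0.6)
  full <- summarize_libraries(ms, dfp_threshold = 0.5)
  restricted <- summarize_libraries(ms, dfp_threshold = 0.5,
                                    bit_selection = sel)
  expect_equal(restricted$n, full$n)
  expect_false(isTRUE(all.equal(restricted$se_mean, full$se_mean)))
})

test_that("k-means is deterministic, permutation-stable, and recovers clouds", {
  withr::with_seed(19, {
    rows <- tibble::tibble(
      label = sprintf("lib%d", 1:12),
      n = 100L,
      se_mean = c(rnorm(6, 0.9, 0.01), rnorm(6, 0.3, 0.01)),
      dfp_similarity_mean = c(rnorm(6, 0.35, 0.01), rnorm(6, 0.8, 0.01))
    )
  })
  f1 <- kmeans_libraries(rows, k = 2, seed = 4)
  f2 <- kmeans_libraries(rows, k = 2, seed = 4)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(attr(f1, "inertia"), attr(f2, "inertia"))

  # generating labels recovered up to relabeling
  expect_equal(length(unique(f1$cluster[1:6])), 1)
  expect_equal(length(unique(f1$cluster[7:12])), 1)
  expect_false(f1$cluster[1] == f1$cluster[7])

  # permuting rows permutes assignments consistently
  perm <- withr::with_seed(2, sample(12))
  f3 <- kmeans_libraries(rows[perm, ], k = 2, seed = 4)
  same <- outer(f1$cluster[perm], f1$cluster[perm], `==`)
  same3 <- outer(f3$cluster, f3$cluster, `==`)
  expect_identical(same, same3)

  # k = n gives a zero-inertia singleton partition
  fn <- kmeans_libraries(rows, k = 12, seed = 4)
  expect_equal(attr(fn, "inertia"), 0)
  expect_equal(sort(unique(fn$cluster)), 1:12)

  expect_error(kmeans_libraries(rows, k = 13), "exceed")
  expect_error(kmeans_libraries(rows, k = 0), "at least 1")
})

test_that("multi-restart inertia is never worse than a single restart", {
  withr::with_seed(29, {
    rows <- tibble::tibble(label = sprintf("l%d", 1:15), n = 10L,
                           se_mean = runif(15),
                           dfp_similarity_mean = runif(15))
  })
  multi <- kmeans_libraries(rows, k = 4, seed = 11, n_restarts = 10)
  single <- kmeans_libraries(rows, k = 4, seed = 11, n_restarts = 1)
  expect_lte(attr(multi, "inertia"), attr(single, "inertia") + 1e-12)
  # inertia recomputes from assignments and centroids (standardized space)
  x <- scale(cbind(rows$se_mean, rows$dfp_similarity_mean))
  cent <- attr(multi, "centroids")
  mu <- colMeans(cbind(rows$se_mean, rows$dfp_similarity_mean))
  sdv <- apply(cbind(rows$se_mean, rows$dfp_similarity_mean), 2, sd)
  cent_std <- sweep(sweep(cent, 2, mu, `-`), 2, sdv, `/`)
  recomputed <- sum(vapply(seq_len(nrow(x)), function(i) {
    sum((x[i, ] - cent_std[multi$cluster[i], ])^2)
  }, numeric(1)))
  expect_equal(recomputed, attr(multi, "inertia"), tolerance = 1e-8)
})

test_that("tidiers expose fitted objects as tibbles", {
  m <- random_bit_matrix(50, 64, seed = 40, label = "libX")
  d <- build_dfp_for_database(m, threshold = 0.5)
  td <- tidy(d)
  expect_equal(nrow(td), 64)
  expect_equal(td$value, d$bits)
  g <- glance(d)
  expect_equal(g$popcount, sum(d$bits))
  expect_equal(g$source_label, "libX")

  rep <- shannon_entropy(bit_probabilities(m))
  expect_equal(glance(rep)$total, attr(rep, "total"))

  dfps <- lapply(1:3, function(s) build_dfp_for_database(
    random_bit_matrix(30, 64, seed = s, label = paste0("L", s)),
    threshold = 0.5))
  long <- tidy(inter_set_matrix(dfps))
  expect_equal(nrow(long), 3)
  expect_true(all(c("from", "to", "distance") %in% names(long)))
})
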