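test_that("tanimoto handles identity, disjoint and mixed cases", {
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(suppressMessages(tanimoto(c(0, 0), c(0, 0))), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("city block equals the Hamming distance on binary vectors", {
  expect_equal(city_block(c(1, 0, 1), c(1, 0, 1)), 0)
  ones <- rep(1L, 166)
  expect_equal(city_block(ones, 1L - ones), 166)
  withr::with_seed(5, {
    a <- sample(0:1, 64, TRUE); b <- sample(0:1, 64, TRUE)
  })
  expect_equal(city_block(a, b), naive_city_block(a, b))
})

test_that("similarity kernels match naive per-bit loops on random pairs", {
  withr::with_seed(17, {
    for (i in 1:50) {
      a <- sample(0:1, 166, TRUE, prob = c(0.6, 0.4))
      b <- sample(0:1, 166, TRUE, prob = c(0.6, 0.4))
      expect_identical(tanimoto(a, b), naive_tanimoto(a, b))
      expect_identical(city_block(a, b), naive_city_block(a, b))
    }
  })
})

test_that("tanimoto and city block satisfy metric-style axioms", {
  withr::with_seed(23, {
    trip <- replicate(40, sample(0:1, 40, TRUE), simplify = FALSE)
  })
  for (i in seq(1, 38, by = 3)) {
    a <- trip[[i]]; b <- trip[[i + 1]]; c <- trip[[i + 2]]
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
    expect_equal(city_block(a, b), city_block(b, a))
    expect_lte(city_block(a, c), city_block(a, b) + city_block(b, c))
    expect_equal(city_block(a, a), 0)
  }
  # tanimoto is 1 iff equal and nonzero
  nz <- c(1, 0, 1, 1)
  expect_equal(tanimoto(nz, nz), 1)
  expect_lt(tanimoto(nz, c(1, 0, 1, 0)), 1)
})

test_that("exact pairwise mean matches the brute-force oracle", {
  m <- random_bit_matrix(25, 48, p = 0.4, seed = 77)
  s <- intra_set_pairwise(m)
  vals <- naive_pairwise_mean(unclass(m)[, ])
  expect_false(s$sampled)
  expect_equal(s$n_pairs_or_mols, 25 * 24 / 2)
  expect_equal(s$mean, mean(vals))
  expect_equal(s$sd, sd(vals))
})

test_that("two identical molecules have mean pairwise similarity 1", {
  m <- bit_matrix(rbind(c(1L, 0L, 1L), c(1L, 0L, 1L)),
                  ids = c("a", "b"), scheme = fp_scheme("GENERIC", 3))
  s <- intra_set_pairwise(m)
  expect_equal(s$mean, 1.0)
  expect_equal(s$sd, 0.0)
})

test_that("sampled pairwise means agree with exact within sampling error", {
  m <- random_bit_matrix(500, 166, seed = 55)
  exact <- intra_set_pairwise(m)
  sampled <- intra_set_pairwise(m, max_exact_n = 100,
                                sample_pairs = 30000, seed = 2)
  expect_true(sampled$sampled)
  expect_equal(sampled$n_pairs_or_mols, 30000)
  tol <- 3 * exact$sd / sqrt(30000)
  expect_lt(abs(sampled$mean - exact$mean), tol)
  # same seed, same answer
  expect_identical(sampled$mean,
                   intra_set_pairwise(m, max_exact_n = 100,
                                      sample_pairs = 30000, seed = 2)$mean)
})

test_that("pair-rank decoding enumerates each unordered pair exactly once", {
  n <- 9
  got <- dfptools:::pair_index_to_ij(seq_len(n * (n - 1) / 2), n)
  pairs <- paste(got$i, got$j)
  expect_true(all(got$i < got$j))
  expect_true(all(got$i >= 1) && all(got$j <= n))
  expect_equal(length(unique(pairs)), n * (n - 1) / 2)
})

test_that("molecule-vs-DFP similarity matches a direct loop", {
  withr::with_seed(31, {
    p_star <- sample(c(0.05, 0.95), 60, TRUE)
  })
  m <- generate_library(library_spec(n = 80, profile = p_star, seed = 41))
  d <- build_dfp_for_database(m, threshold = 0.5)
  s <- intra_set_vs_dfp(m, d)
  direct <- vapply(seq_len(nrow(m)),
                   function(i) naive_tanimoto(unclass(m)[i, ], d$bits),
                   numeric(1))
  expect_equal(s$mean, mean(direct))
  expect_equal(s$sd, sd(direct))
  expect_equal(s$n_pairs_or_mols, 80)

  # a single-molecule library is perfectly similar to its own DFP
  one <- random_bit_matrix(1, 60, p = 0.5, seed = 3)
  s1 <- intra_set_vs_dfp(one, build_dfp_for_database(one, threshold = 0.5))
  expect_equal(s1$mean, 1.0)

  # all-zero DFP: empty-intersection convention gives 0
  zero <- build_dfp(profile_from_counts(rep(0L, 60), n = 10), threshold = 0.5)
  expect_equal(intra_set_vs_dfp(m, zero)$mean, 0)

  expect_error(intra_set_vs_dfp(random_bit_matrix(5, 10, seed = 1), d),
               "mismatch")
})

test_that("inter-set matrices are symmetric with zero diagonal", {
  d1 <- build_dfp_for_database(random_bit_matrix(30, 64, seed = 1),
                               threshold = 0.4)
  mat <- inter_set_matrix(list(a = d1, b = d1))
  expect_equal(unclass(mat)[, ], matrix(0, 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b"))))

  dfps <- lapply(1:5, function(s) {
    build_dfp_for_database(random_bit_matrix(30, 64, seed = s),
                           threshold = 0.4)
  })
  m_cb <- inter_set_matrix(dfps, metric = "city_block")
  expect_equal(unclass(m_cb), t(unclass(m_cb)))
  expect_equal(diag(unclass(m_cb)), rep(0, 5), ignore_attr = TRUE)
  v <- unclass(m_cb)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(v[i, k], v[i, j] + v[j, k])
  }
  expect_true(all(v == round(v)) && all(v >= 0) && all(v <= 64))

  m_t <- inter_set_matrix(dfps, metric = "one_minus_tanimoto")
  expect_true(all(unclass(m_t) >= 0 & unclass(m_t) <= 1))

  short <- build_dfp_for_database(random_bit_matrix(10, 32, seed = 9),
                                  threshold = 0.4)
  expect_error(inter_set_matrix(list(d1, short)), "mixed")
})

test_that("a random DFP is the most distant from correlated libraries", {
  withr::with_seed(61, {
    base <- sample(c(0.1, 0.9), 166, TRUE)
  })
  libs <- lapply(1:3, function(i) {
    prof <- pmin(pmax(base + withr::with_seed(70 + i,
                                              runif(166, -0.05, 0.05)),
                      0), 1)
    generate_library(library_spec(n = 300, profile = prof, seed = 80 + i,
                                  label = paste0("lib", i)))
  })
  rnd <- generate_random_reference(n = 300, seed = 99)
  dfps <- c(lapply(libs, build_dfp_for_database, threshold = 0.5),
            list(build_dfp_for_database(rnd, threshold = 0.5)))
  v <- unclass(inter_set_matrix(dfps, metric = "city_block"))
  rnd_dists <- v[4, 1:3]
  lib_dists <- v[1:3, 1:3][upper.tri(v[1:3, 1:3])]
  expect_gt(min(rnd_dists), max(lib_dists))
})

test_that("mean pairwise and vs-DFP similarity rise together on the ladder", {
  ladder <- make_library_ladder(4, n = 250, seed = 13)
  pairwise <- vapply(ladder, function(m) intra_set_pairwise(m)$mean,
                     numeric(1))
  vs_dfp <- vapply(ladder, function(m) {
    intra_set_vs_dfp(m, build_dfp_for_database(m, threshold = 0.5))$mean
  }, numeric(1))
  expect_true(all(diff(pairwise) > 0))
  expect_true(all(diff(vs_dfp) > 0))
  expect_equal(cor(pairwise, vs_dfp, method = "spearman"), 1)
})
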