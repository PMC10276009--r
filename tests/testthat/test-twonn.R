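test_that("neighbour distances match an exhaustive all-pairs scan", {
  pts <- matrix(c(0, 1, 3), ncol = 1)
  d <- nn_distances(pts, 2)
  expect_equal(d[1, ], c(r1 = 1, r2 = 3))
  expect_equal(unname(nn_ratios(d)), c(3, 2, 1.5))

  x <- withr::with_seed(10, matrix(rnorm(300), 100, 3))
  expect_equal(unname(nn_distances(x, 5)), brute_nn(x, 5)$distances,
               tolerance = 1e-12)

  expect_error(nn_distances(rbind(x, x[7, ])), "duplicate")
})

test_that("ratios validate their domain and flag ties", {
  expect_equal(nn_ratios(matrix(c(1, 3), 1)), 3)
  expect_warning(r <- nn_ratios(matrix(c(2, 2), 1)), "mu = 1")
  expect_equal(r, 1)
  expect_error(nn_ratios(matrix(c(0, 1), 1)), "zero first")
  expect_error(nn_ratios(matrix(1, 1, 1)), "at least 2")
})

test_that("the closed-form MLE behaves on hand cases and simulations", {
  expect_equal(twonn_mle(c(exp(1), exp(1)))$d_hat, 1)
  expect_equal(twonn_mle(c(exp(0.5), exp(0.5)))$d_hat, 2)
  expect_error(twonn_mle(c(1, 1)), "infinite")
  expect_error(twonn_mle(0.9), ">= 1")

  s <- sample_manifold_mixture(manifold_spec(list(c(2, 2000)), 6, seed = 11))
  est <- twonn(s$matrix)
  expect_lt(abs(est$d_hat - 2), 2 * est$se)
  expect_equal(est$se, est$d_hat / sqrt(2000))
})

test_that("log-ratio mean approaches 1/d for uniform cube samples", {
  for (d in c(3L, 6L)) {
    s <- sample_manifold_mixture(manifold_spec(list(c(d, 1500)), 8,
                                               seed = 20 + d))
    mu <- nn_ratios(nn_distances(s$matrix))
    # Pareto(1, d): E[log mu] = 1/d, sd[log mu] = 1/d
    expect_lt(abs(mean(log(mu)) - 1 / d), 4 / (d * sqrt(1500)))
  }
})

test_that("ratio sample passes a Pareto goodness-of-fit check", {
  s <- sample_manifold_mixture(manifold_spec(list(c(2, 1000)), 5, seed = 12))
  mu <- nn_ratios(nn_distances(s$matrix))
  d_hat <- twonn_mle(mu)$d_hat
  ks <- suppressWarnings(
    stats::ks.test(mu, function(x) 1 - x^(-d_hat)))
  expect_gt(ks$p.value, 0.01)
})

test_that("neighbourhood matrix follows its definition", {
  x <- withr::with_seed(13, matrix(rnorm(10), 5, 2))
  N <- neighbourhood_matrix(x, 2)
  expect_true(all(rowSums(N) == 2))
  expect_true(all(diag(N) == 0))
  bf <- brute_nn(x, 2)$neighbours
  for (i in 1:5) expect_setequal(which(N[i, ] == 1L), bf[i, ])
  expect_error(neighbourhood_matrix(x, 5), "n > q")
})

test_that("distances and neighbourhoods are rotation invariant", {
  x <- withr::with_seed(14, matrix(rnorm(240), 60, 4))
  Q <- withr::with_seed(15, qr.Q(qr(matrix(rnorm(16), 4, 4))))
  xr <- x %*% Q
  expect_equal(nn_distances(x, 3), nn_distances(xr, 3), tolerance = 1e-8)
  expect_identical(neighbourhood_matrix(x, 3) == 1L,
                   neighbourhood_matrix(xr, 3) == 1L)
})

test_that("duplicate jitter separates rows without moving the geometry", {
  x <- matrix(c(0, 0, 1, 1, 0, 0, 5, 5), 4, 2, byrow = TRUE)
  expect_error(nn_distances(x), "duplicate")
  xj <- jitter_duplicates(x, seed = 16)
  expect_identical(jitter_duplicates(x, seed = 16), xj)   # seeded
  expect_lt(max(abs(xj - x)), 1e-8)                       # micro-scale
  expect_silent(d <- nn_distances(xj))
  expect_lt(d[1, 1], 1e-8)                                # former twins
  # non-duplicated rows are bit-identical
  expect_identical(xj[2, ], x[2, ])
  expect_identical(xj[4, ], x[4, ])
})

test_that("ratio and neighbourhood audit exports round-trip", {
  x <- withr::with_seed(17, matrix(rnorm(30), 10, 3))
  mu <- nn_ratios(nn_distances(x))
  N <- neighbourhood_matrix(x, 2)
  dir <- withr::local_tempdir()
  write_twonn_csv(mu, N, dir)
  expect_equal(read.csv(file.path(dir, "mu.csv"))$mu, mu)
  trip <- read.csv(file.path(dir, "nq_triplets.csv"))
  expect_equal(nrow(trip), 20L)  # n x q ones
  N2 <- matrix(0L, 10, 10)
  N2[cbind(trip$i, trip$j)] <- 1L
  expect_equal(N2, unname(unclass(N))[1:10, 1:10], ignore_attr = TRUE)
})
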