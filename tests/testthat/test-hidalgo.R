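# shared small fixture: ratios and neighbourhoods from 3-D Gaussian points
fixture_state <- function(n = 60L, q = 3L, seed = 30L) {
  x <- withr::with_seed(seed, matrix(rnorm(n * 3), n, 3))
  list(x = x,
       mu = nn_ratios(nn_distances(x, 2)),
       N = neighbourhood_matrix(x, q))
}

test_that("mixture density evaluates and normalizes", {
  expect_equal(mixture_density(exp(1), 1, 1), exp(-2), tolerance = 1e-12)
  mu <- c(1.1, 2.5, 7)
  expect_equal(mixture_density(mu, c(1, 1), c(0.5, 0.5)),
               mixture_density(mu, 1, 1))
  expect_error(mixture_density(0.5, 2, 1), ">= 1")
  expect_error(mixture_density(2, c(1, 2), c(0.7, 0.7)), "sum to 1")
  withr::with_seed(31, {
    for (rep in 1:3) {
      d <- runif(3, 0.5, 12)
      pi <- as.vector(rgamma(3, 1)); pi <- pi / sum(pi)
      I <- stats::integrate(function(m) mixture_density(m, d, pi), 1, Inf)
      expect_equal(I$value, 1, tolerance = 1e-6)
    }
  })
})

test_that("augmented log-likelihood matches a hand-expanded evaluation", {
  # 6-point toy, two clusters, hand-built neighbourhood structure (q = 2)
  N <- rbind(c(0, 1, 1, 0, 0, 0),
             c(1, 0, 1, 0, 0, 0),
             c(1, 1, 0, 0, 0, 0),
             c(0, 0, 0, 0, 1, 1),
             c(0, 0, 1, 0, 0, 1),
             c(0, 0, 0, 1, 1, 0))
  mu <- c(1.2, 1.5, 2.0, 1.1, 3.0, 1.8)
  labs <- c(1L, 1L, 1L, 2L, 2L, 2L)
  d <- c(2, 5); zeta <- 0.75; n <- 6L; q <- 2L
  # term-by-term oracle with explicit loops and the binomial-sum normalizer
  ll <- 0
  for (i in 1:n) {
    ll <- ll + log(d[labs[i]]) - (d[labs[i]] + 1) * log(mu[i])
    for (j in 1:n) {
      if (N[i, j] == 1) {
        ll <- ll + if (labs[i] == labs[j]) log(zeta) else log(1 - zeta)
      }
    }
    m <- sum(labs == labs[i])
    z <- 0
    for (a in 0:q) {
      if (a > m - 1 || q - a > n - m) next
      z <- z + choose(m - 1, a) * choose(n - m, q - a) *
        zeta^a * (1 - zeta)^(q - a)
    }
    ll <- ll - log(z)
  }
  expect_equal(augmented_loglik(mu, N, labs, d, zeta), ll, tolerance = 1e-12)

  # all points in one cluster: every neighbour agrees, exponent (q, 0)
  one <- rep(1L, 6)
  ll_one <- augmented_loglik(mu, N, one, d, zeta)
  pareto <- sum(log(d[1]) - (d[1] + 1) * log(mu))
  z_all <- sum(sapply(0:q, function(a) choose(5, a) * choose(0, q - a) *
                                       zeta^a * (1 - zeta)^(q - a)))
  expect_equal(ll_one, pareto + 6 * q * log(zeta) - 6 * log(z_all),
               tolerance = 1e-12)
})

test_that("zeta = 0.5 removes the neighbourhood term from the likelihood", {
  st <- fixture_state()
  d <- c(2, 6)
  l1 <- withr::with_seed(32, sample(1:2, 60, TRUE))
  l2 <- withr::with_seed(33, sample(1:2, 60, TRUE))
  diff_aug <- augmented_loglik(st$mu, st$N, l1, d, 0.5) -
    augmented_loglik(st$mu, st$N, l2, d, 0.5)
  pareto <- function(l) sum(log(d[l]) - (d[l] + 1) * log(st$mu))
  expect_equal(diff_aug, pareto(l1) - pareto(l2), tolerance = 1e-9)
})

test_that("label conditionals agree with the joint likelihood and collapse at zeta = 0.5", {
  st <- fixture_state()
  d <- c(1.5, 4, 9)
  pi <- c(0.2, 0.5, 0.3)
  labs <- withr::with_seed(34, sample(1:3, 60, TRUE))
  for (i in c(1L, 17L, 60L)) {
    # dual route: exponentiated joint likelihood over the three candidate labels
    lj <- vapply(1:3, function(l) {
      ll <- labs; ll[i] <- l
      augmented_loglik(st$mu, st$N, ll, d, 0.66) + log(pi[l])
    }, numeric(1))
    expect_equal(label_conditional(i, labs, st$mu, st$N, d, pi, 0.66),
                 as.vector(exp(lj - max(lj)) / sum(exp(lj - max(lj)))),
                 tolerance = 1e-9)
    # zeta = 0.5: plain mixture responsibilities
    plain <- pi * d * st$mu[i]^(-(d + 1))
    expect_equal(label_conditional(i, labs, st$mu, st$N, d, pi, 0.5),
                 plain / sum(plain), tolerance = 1e-9)
  }
})

test_that("configuration is validated", {
  expect_error(hidalgo_config(zeta = 0.4), "zeta")
  expect_error(hidalgo_config(burn_in = 100, n_iter = 100), "burn_in")
  expect_error(hidalgo_config(alpha = c(0.1, 0.1)), "length 1 or L")
  expect_true(hidalgo_config(alpha = 0.05)$sparse)
  expect_false(hidalgo_config(alpha = 1)$sparse)
})

test_that("with one component the sampler reproduces the conjugate posterior", {
  st <- fixture_state(n = 100L)
  mu <- rep(exp(0.5), 100)  # sum(log mu) = 50 exactly
  cfg <- hidalgo_config(L = 1, n_iter = 3000, burn_in = 500, seed = 35)
  fit <- hidalgo_fit(mu, st$N, cfg)
  # d | data ~ Gamma(1 + 100, 1 + 50); kept draws are iid
  target <- 101 / 51
  mc_se <- sd(fit$dims) / sqrt(length(fit$dims))
  expect_lt(abs(mean(fit$dims) - target), 3 * mc_se)
  expect_equal(dim(fit$dims), c(2500L, 1L))
})

test_that("chains are reproducible and weights stay on the simplex", {
  st <- fixture_state()
  cfg <- hidalgo_config(L = 4, n_iter = 400, burn_in = 50, seed = 36)
  f1 <- hidalgo_fit(st$mu, st$N, cfg)
  f2 <- hidalgo_fit(st$mu, st$N, cfg)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$dims, f2$dims)
  expect_true(all(abs(rowSums(f1$weights) - 1) < 1e-9))
  expect_true(all(f1$dims > 0))
  expect_true(all(f1$labels >= 1L & f1$labels <= 4L))
  expect_equal(nrow(f1$labels), 350L)
})

test_that("the sparse prior empties surplus components", {
  s <- sample_manifold_mixture(
    manifold_spec(list(c(1, 150), c(6, 150)), 10, seed = 37))
  # long enough for the label posterior to coalesce; short chains can
  # transiently hold a same-ID manifold split across two components
  fit <- hidalgo(s$matrix, hidalgo_config(n_iter = 6000, burn_in = 1000,
                                          seed = 38))
  # most of the 6 components stay (near-)empty under alpha = 0.05 ...
  populated <- apply(fit$labels, 1, function(r) {
    sum(tabulate(r, nbins = 6) >= 0.05 * length(r))
  })
  expect_lte(mean(populated), 3)
  expect_true(all(populated <= 6))
  # ... and the estimated number of clusters lands on the two latent
  # manifolds (two components may share a manifold in any one sweep —
  # they carry near-identical IDs and the co-clustering matrix merges them)
  expect_equal(vi_partition(coclustering(fit), fit)$L_star, 2L)
})

test_that("an empty dataset returns draws from the prior", {
  cfg <- hidalgo_config(L = 3, a_d = 2, b_d = 3, n_iter = 3000, burn_in = 0,
                        seed = 39)
  fit <- hidalgo_fit(numeric(0), NULL, cfg)
  draws <- as.vector(fit$dims)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 2 / 3), 3 * mc_se)
  expect_lt(abs(var(draws) - 2 / 9), 0.03)
})

test_that("sampling zeta keeps it in range and favours homogeneity", {
  s <- sample_manifold_mixture(
    manifold_spec(list(c(1, 80), c(5, 80)), 8, seed = 40))
  fit <- hidalgo(s$matrix,
                 hidalgo_config(n_iter = 800, burn_in = 200,
                                sample_zeta = TRUE, seed = 41))
  expect_true(all(fit$zeta > 0 & fit$zeta < 1))
  expect_gt(mean(fit$zeta), 0.5)
})
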