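#' Configuration for the heterogeneous-ID mixture sampler
#'
#' @param L Upper bound on the number of mixture components (default 6).
#'   Under a sparse Dirichlet prior the populated number L* <= L is
#'   estimated from the data.
#' @param a_d,b_d Shape and rate of the Gamma prior on each component's
#'   intrinsic dimension (default 1, 1: weakly informative, prior mean 1).
#' @param alpha Dirichlet concentration for the mixing weights; a scalar
#'   is recycled to length `L`.  Values at or below 0.05 give the sparse
#'   mixture behaviour that empties unneeded components (default 0.05).
#' @param q Neighbourhood size for the local-homogeneity term (default 3).
#' @param zeta Probability that a point's q-neighbour shares its cluster,
#'   in (0.5, 1); default 0.75.  Set `sample_zeta = TRUE` to give it a
#'   Beta(`zeta_a`, `zeta_b`) prior and sample it by a Metropolis step.
#' @param sample_zeta Logical; sample `zeta` instead of fixing it.
#' @param zeta_a,zeta_b Beta prior parameters used when sampling `zeta`
#'   (default 10, 1, favouring strong local homogeneity).
#' @param n_iter Total MCMC iterations (default 25000).
#' @param burn_in Discarded initial iterations (default 1000).
#' @param seed Integer seed; every random draw in the fit flows from it.
#'
#' @return A list of class `hidalgo_config`.
#' @export
hidalgo_config <- function(L = 6L, a_d = 1, b_d = 1, alpha = 0.05, q = 3L,
                           zeta = 0.75, sample_zeta = FALSE,
                           zeta_a = 10, zeta_b = 1,
                           n_iter = 25000L, burn_in = 1000L, seed = NULL) {
  L <- as.integer(L); q <- as.integer(q)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  stopifnot(L >= 1L, q >= 1L, a_d > 0, b_d > 0, n_iter >= 1L, burn_in >= 0L)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, L)
  if (length(alpha) != L) stop("alpha must have length 1 or L", call. = FALSE)
  stopifnot(all(alpha > 0))
  if (zeta <= 0.5 || zeta >= 1) stop("zeta must lie in (0.5, 1)", call. = FALSE)
  structure(list(L = L, a_d = a_d, b_d = b_d, alpha = alpha, q = q,
                 zeta = zeta, sample_zeta = isTRUE(sample_zeta),
                 zeta_a = zeta_a, zeta_b = zeta_b,
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 sparse = all(alpha <= 0.05)),
            class = "hidalgo_config")
}

#' Pareto mixture density of a neighbour-distance ratio
#'
#' f(mu | d, pi) = sum_l pi_l d_l mu^-(d_l + 1), the marginal density of
#' a ratio generated by an L-component mixture of Pareto(1, d_l) laws.
#'
#' @param mu Ratio value(s), each >= 1.
#' @param d Positive vector of component intrinsic dimensions.
#' @param pi Mixing weights summing to 1, same length as `d`.
#' @return Density value(s).
#' @export
mixture_density <- function(mu, d, pi) {
  if (any(mu < 1)) stop("ratios must be >= 1", call. = FALSE)
  stopifnot(length(d) == length(pi), all(d > 0), all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  vapply(mu, function(m) sum(pi * d * m^(-(d + 1))), numeric(1))
}

#' Neighbourhood-augmented mixture log-likelihood
#'
#' The joint log-likelihood of the ratios and the binary q-neighbourhood
#' matrix given labels: for each point, the Pareto term of its assigned
#' component times zeta^(same-cluster neighbours) (1-zeta)^(other
#' neighbours), normalized by Z_i, the total probability of its
#' q-neighbour set given the current cluster sizes.
#'
#' @param mu Ratio vector.
#' @param N Binary neighbourhood matrix from [neighbourhood_matrix()].
#' @param labels Integer labels in 1..length(d).
#' @param d Component intrinsic dimensions.
#' @param zeta Local-homogeneity probability in (0, 1).
#' @return Scalar log-likelihood.
#' @export
augmented_loglik <- function(mu, N, labels, d, zeta) {
  n <- length(mu)
  stopifnot(nrow(N) == n, length(labels) == n, all(labels >= 1),
            all(labels <= length(d)), zeta > 0, zeta < 1)
  q <- sum(N[1L, ])
  same <- vapply(seq_len(n), function(i) sum(N[i, ] * (labels == labels[i])),
                 numeric(1))
  counts <- tabulate(labels, nbins = length(d))
  logz <- logz_table_cpp(n, q, zeta)
  sum(log(d[labels]) - (d[labels] + 1) * log(mu)) +
    sum(same) * log(zeta) + (n * q - sum(same)) * log(1 - zeta) -
    sum(logz[counts[labels]])
}

#' Full-conditional label probabilities for one observation
#'
#' The exact categorical distribution the Gibbs sampler draws `c_i`
#' from, given the rest of the state: Pareto term x mixing weight x
#' every neighbourhood factor involving i (row i and column i of N, and
#' the cluster-size-dependent normalizers).  Exposed for diagnostics;
#' at `zeta = 0.5` it reduces to the plain mixture responsibilities.
#'
#' @param i Observation index.
#' @param labels Current label vector (1-based).
#' @param mu Ratio vector.
#' @param N Neighbourhood matrix.
#' @param d,pi Current component parameters.
#' @param zeta Local-homogeneity probability.
#' @return Probability vector of length `length(d)`.
#' @export
label_conditional <- function(i, labels, mu, N, d, pi, zeta) {
  outn <- neighbour_index(N)
  lp <- label_logprob_cpp(as.integer(i), as.integer(labels), log(mu), outn,
                          as.numeric(d), as.numeric(pi), zeta)
  p <- exp(lp - max(lp))
  p / sum(p)
}

# n x q matrix of 1-based neighbour indices from a binary N matrix
neighbour_index <- function(N) {
  q <- sum(N[1L, ])
  idx <- t(apply(N, 1L, function(r) which(r == 1L)))
  storage.mode(idx) <- "integer"
  if (ncol(idx) != q) stop("neighbourhood matrix rows must all sum to q", call. = FALSE)
  idx
}

#' Fit the heterogeneous-ID Pareto mixture by Gibbs sampling
#'
#' Runs the blocked Gibbs sampler: labels are updated one observation at
#' a time in a freshly randomized order each sweep from their exact full
#' conditionals; the component dimensions use Pareto-Gamma conjugacy,
#' d_l | . ~ Gamma(a_d + n_l, b_d + sum log mu over members); the weights
#' use Dirichlet conjugacy.  All densities are handled in log space and
#' categorical draws use Gumbel-max.
#'
#' @param mu Ratio vector from [nn_ratios()]; may be empty to sample the
#'   prior.
#' @param N Neighbourhood matrix from [neighbourhood_matrix()] on the
#'   same data (ignored when `mu` is empty).
#' @param config A [hidalgo_config()].
#' @return An object of class `hidalgo_chains`: list with `labels`
#'   (n_kept x n), `weights` (n_kept x L), `dims` (n_kept x L), the
#'   `config`, and `zeta` (chain) when it was sampled.
#' @export
hidalgo_fit <- function(mu, N = NULL, config = hidalgo_config()) {
  stopifnot(inherits(config, "hidalgo_config"))
  n <- length(mu)
  if (n > 0L) {
    if (any(mu < 1)) stop("ratios must be >= 1", call. = FALSE)
    if (is.null(N)) stop("a neighbourhood matrix is required when mu is non-empty",
                         call. = FALSE)
    if (nrow(N) != n) stop("mu and N disagree on n", call. = FALSE)
    outn <- neighbour_index(N)
    if (ncol(outn) != config$q) {
      stop("neighbourhood matrix was built with q = ", ncol(outn),
           " but config has q = ", config$q, call. = FALSE)
    }
  } else {
    outn <- matrix(integer(0), 0L, config$q)
  }
  run <- function() {
    hidalgo_gibbs_cpp(log(mu), outn, config$L, config$a_d, config$b_d,
                      config$alpha, config$zeta, config$sample_zeta,
                      config$zeta_a, config$zeta_b, 0.5,
                      config$n_iter, config$burn_in)
  }
  res <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  res$config <- config
  res$n <- n
  if (n > 0L && !is.null(rownames(N))) res$units <- rownames(N)
  class(res) <- "hidalgo_chains"
  res
}

#' Fit Hidalgo straight from a data matrix
#'
#' Computes TWO-NN ratios and the q-neighbourhood matrix, then calls
#' [hidalgo_fit()].
#'
#' @param x Numeric matrix with unique rows (n x D).
#' @param config A [hidalgo_config()].
#' @return As [hidalgo_fit()].
#' @export
hidalgo <- function(x, config = hidalgo_config()) {
  mu <- nn_ratios(nn_distances(x, 2L))
  N <- neighbourhood_matrix(x, config$q)
  hidalgo_fit(mu, N, config)
}

#' @export
print.hidalgo_chains <- function(x, ...) {
  cat("<hidalgo_chains> ", nrow(x$dims), " kept iterations, n = ", x$n,
      ", L = ", x$config$L, "\n", sep = "")
  if (x$n > 0L) {
    occ <- mean(apply(x$labels, 1L, function(r) length(unique(r))))
    cat("  mean populated components per iteration: ", round(occ, 2), "\n", sep = "")
  }
  invisible(x)
}
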