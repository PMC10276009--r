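#' Exact Euclidean q-nearest-neighbour distances
#'
#' Distances from each row of `x` to its `q` nearest other rows, self
#' excluded, by exhaustive search (n here is small).  Ties are broken by
#' ascending row index so results replay exactly.
#'
#' @param x Numeric matrix with unique rows.
#' @param q Number of neighbours (default 2, the TWO-NN case).
#' @return An n x q matrix; entry (i, j) is the distance from point i to
#'   its j-th nearest neighbour.
#' @export
nn_distances <- function(x, q = 2L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < q + 1L) stop("need at least q + 1 points", call. = FALSE)
  dm <- as.matrix(dist(x))
  diag(dm) <- Inf
  out <- matrix(0, n, q)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])[seq_len(q)]  # order() breaks ties by index
    out[i, ] <- dm[i, ord]
  }
  if (any(out[, 1L] == 0)) {
    stop("duplicate rows detected (zero first-neighbour distance); ",
         "unique observations are required", call. = FALSE)
  }
  rownames(out) <- rownames(x)
  colnames(out) <- paste0("r", seq_len(q))
  out
}

#' Second-to-first nearest-neighbour distance ratios
#'
#' For locally homogeneous samples on a d-dimensional manifold the
#' ratio mu_i = r_(i,2) / r_(i,1) follows a Pareto(1, d) law, which is
#' what every estimator downstream exploits.
#'
#' @param distances An n x q (q >= 2) matrix as from [nn_distances()].
#' @return Numeric vector of ratios, each >= 1.  Ties (`mu == 1`) are
#'   kept but flagged with a warning since they sit on the boundary of
#'   the Pareto support.
#' @export
nn_ratios <- function(distances) {
  distances <- as.matrix(distances)
  if (ncol(distances) < 2L) stop("need at least 2 neighbour distances", call. = FALSE)
  if (any(distances[, 1L] <= 0)) stop("zero first-neighbour distance", call. = FALSE)
  mu <- distances[, 2L] / distances[, 1L]
  if (any(mu == 1)) {
    warning("tied first and second neighbour distances (mu = 1) at ",
            sum(mu == 1), " point(s)", call. = FALSE)
  }
  unname(mu)
}

#' TWO-NN maximum-likelihood intrinsic dimension estimate
#'
#' Under mu_i ~ Pareto(1, d) iid, the MLE is d = n / sum(log mu) with
#' standard error d / sqrt(n) (from the Gamma posterior / Fisher
#' information).
#'
#' @param mu Ratio vector from [nn_ratios()].
#' @return List with `d_hat`, `se` and `n`.
#' @export
twonn_mle <- function(mu) {
  if (any(mu < 1)) stop("ratios must be >= 1", call. = FALSE)
  s <- sum(log(mu))
  if (s == 0) stop("all ratios equal 1; estimate is infinite", call. = FALSE)
  n <- length(mu)
  d_hat <- n / s
  list(d_hat = d_hat, se = d_hat / sqrt(n), n = n)
}

#' TWO-NN estimate straight from a data matrix
#'
#' @param x Numeric matrix with unique rows.
#' @return As [twonn_mle()].
#' @export
twonn <- function(x) {
  twonn_mle(nn_ratios(nn_distances(x, 2L)))
}

#' Break exact duplicate rows with seeded micro-jitter
#'
#' Duplicate observations make the first-neighbour distance zero and the
#' Pareto ratio undefined, so the estimators reject them.  When
#' duplicates are genuine (e.g. discretized series), this adds uniform
#' noise at a scale far below any meaningful distance so the rows become
#' distinct while the geometry is unchanged.
#'
#' @param x Numeric matrix.
#' @param amount Half-width of the uniform jitter (default `1e-9`).
#' @param seed Optional integer seed.
#' @return `x` with jitter added to every entry of the duplicated rows.
#' @export
jitter_duplicates <- function(x, amount = 1e-9, seed = NULL) {
  x <- as.matrix(x)
  dup <- duplicated(x) | duplicated(x, fromLast = TRUE)
  if (!any(dup)) return(x)
  jit <- function() {
    x[dup, ] <- x[dup, , drop = FALSE] +
      matrix(runif(sum(dup) * ncol(x), -amount, amount), sum(dup))
    x
  }
  if (is.null(seed)) jit() else withr::with_seed(seed, jit())
}

#' Write ratio and neighbourhood audit files
#'
#' Exports the TWO-NN ratios as `mu.csv` (unit, mu), the binary
#' neighbourhood matrix as `nq.csv`, and its sparse triplet form as
#' `nq_triplets.csv` (i, j, value).
#'
#' @param mu Ratio vector.
#' @param N Neighbourhood matrix from [neighbourhood_matrix()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_twonn_csv <- function(mu, N, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  units <- rownames(N)
  if (is.null(units)) units <- seq_along(mu)
  write.csv(data.frame(unit = units, mu = mu),
            file.path(dir, "mu.csv"), row.names = FALSE)
  write.csv(N, file.path(dir, "nq.csv"), row.names = FALSE)
  idx <- which(N == 1L, arr.ind = TRUE)
  write.csv(data.frame(i = idx[, 1L], j = idx[, 2L], value = 1L),
            file.path(dir, "nq_triplets.csv"), row.names = FALSE)
  invisible(dir)
}

#' Binary q-neighbourhood matrix
#'
#' Entry (i, j) is 1 iff j is among the first q nearest neighbours of i.
#' Rows sum to exactly q; the diagonal is zero; the matrix need not be
#' symmetric.  This is the local-homogeneity evidence fed to the
#' neighbourhood-augmented mixture likelihood.
#'
#' @param x Numeric matrix with unique rows.
#' @param q Neighbourhood size; must satisfy `n > q`.
#' @return An n x n integer 0/1 matrix.
#' @export
neighbourhood_matrix <- function(x, q = 3L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= q) stop("need n > q", call. = FALSE)
  dm <- as.matrix(dist(x))
  if (any(dm[upper.tri(dm)] == 0)) {
    stop("duplicate rows detected; unique observations are required", call. = FALSE)
  }
  diag(dm) <- Inf
  N <- matrix(0L, n, n)
  for (i in seq_len(n)) N[i, order(dm[i, ])[seq_len(q)]] <- 1L
  dimnames(N) <- list(rownames(x), rownames(x))
  attr(N, "q") <- as.integer(q)
  N
}
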