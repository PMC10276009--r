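#' Binary contiguity weights from an edge list
#'
#' Builds the symmetric 0/1 adjacency matrix used by Moran's I.  The
#' diagonal is zero, self-loops are rejected, and every unit must have
#' at least one neighbour.
#'
#' @param edges Two-column matrix/data frame of undirected edges (unit
#'   indices in 1..n, or unit names when `n` is a character vector of
#'   unit names).
#' @param n Number of spatial units, or a character vector of unit
#'   names.
#' @return An object of class `spatial_weights`: list with the `w`
#'   matrix, total weight `W = sum(w)` and `N = n`.
#' @export
build_weights <- function(edges, n) {
  units <- NULL
  if (is.character(n)) { units <- n; n <- length(units) }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  if (!is.null(units) && !is.numeric(edges)) {
    edges <- cbind(match(edges[, 1L], units), match(edges[, 2L], units))
    if (anyNA(edges)) stop("edge list names unknown units", call. = FALSE)
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) == 0L) stop("empty edge list", call. = FALSE)
  if (any(edges < 1L) || any(edges > n)) stop("edge index out of range", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed", call. = FALSE)
  w <- matrix(0, n, n)
  w[edges] <- 1
  w[edges[, 2:1, drop = FALSE]] <- 1
  if (!is.null(units)) dimnames(w) <- list(units, units)
  isolated <- which(rowSums(w) == 0)
  if (length(isolated)) {
    nm <- if (is.null(units)) isolated else units[isolated]
    stop("isolated unit(s) with no neighbour: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  structure(list(w = w, W = sum(w), N = n, units = units),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> N = ", x$N, ", total weight W = ", x$W, "\n", sep = "")
  invisible(x)
}

#' Moran's I global spatial autocorrelation
#'
#' I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2 with binary, non-row-standardized weights.  Values near +1
#' indicate that neighbouring units carry similar values; the null
#' (permutation) expectation is -1/(N-1).
#'
#' @param x Numeric vector (e.g. per-unit median posterior IDs),
#'   length `weights$N`, non-constant.
#' @param weights A [build_weights()] object.
#' @return The Moran's I value.
#' @export
morans_i <- function(x, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (length(x) != weights$N) stop("x length must equal N", call. = FALSE)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("Moran's I is undefined for constant x", call. = FALSE)
  (weights$N / weights$W) * as.numeric(crossprod(z, weights$w %*% z)) / denom
}

#' Permutation test for Moran's I
#'
#' Recomputes I under random relabelling of the units; the p-value is
#' (1 + number of permuted statistics at least as extreme) / (1 +
#' n_perm).  One-sided "greater" by default, matching the hypothesis of
#' positive spatial autocorrelation.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return List with `I`, `expected_I` (= -1/(N-1)), `p_value`,
#'   `n_perm`, `alternative` and `seed`.
#' @export
moran_test <- function(x, weights, n_perm = 999L, seed = NULL,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  I_obs <- morans_i(x, weights)
  run <- function() {
    vapply(seq_len(n_perm), function(i) morans_i(sample(x), weights), numeric(1))
  }
  perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  e0 <- -1 / (weights$N - 1)
  extreme <- if (alternative == "greater") {
    sum(perm >= I_obs)
  } else {
    sum(abs(perm - e0) >= abs(I_obs - e0))
  }
  list(I = I_obs, expected_I = e0,
       p_value = (1 + extreme) / (1 + n_perm),
       n_perm = as.integer(n_perm), alternative = alternative, seed = seed)
}
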