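#' Posterior co-clustering matrix
#'
#' Entry (i, j) is the fraction of kept MCMC iterations in which
#' observations i and j carried the same component label.  Because only
#' co-membership is counted, the matrix is invariant to label switching.
#'
#' @param labels An n_kept x n label matrix, or a `hidalgo_chains`
#'   object.
#' @return An n x n symmetric matrix with unit diagonal.
#' @export
coclustering <- function(labels) {
  if (inherits(labels, "hidalgo_chains")) labels <- labels$labels
  labels <- as.matrix(labels)
  if (nrow(labels) == 0L) stop("empty label chain", call. = FALSE)
  n <- ncol(labels)
  p <- matrix(0, n, n)
  for (l in sort(unique(as.vector(labels)))) {
    a <- labels == l
    p <- p + crossprod(a)
  }
  p <- p / nrow(labels)
  dimnames(p) <- list(colnames(labels), colnames(labels))
  p
}

# Lower bound on the posterior expected Variation of Information of a
# candidate partition, computable from the co-clustering matrix alone
# (Jensen's inequality swap of log and expectation).  Exact when the
# posterior is concentrated; the quantity minimized by vi_partition().
expected_vi_lb <- function(pcm, labels) {
  n <- length(labels)
  same <- outer(labels, labels, "==")
  sizes <- rowSums(same)
  mean(log2(sizes) + log2(rowSums(pcm)) - 2 * log2(rowSums(pcm * same)))
}

# all set partitions of n items as restricted-growth label vectors,
# preallocated via the Bell-number recurrence
all_set_partitions <- function(n) {
  bell <- 1
  row <- 1
  for (k in seq_len(n)[-1]) {
    nr <- numeric(k)
    nr[1] <- row[length(row)]
    for (j in 2:k) nr[j] <- nr[j - 1] + row[j - 1]
    row <- nr
    bell <- row[1]
  }
  out <- vector("list", if (n == 1L) 1L else row[length(row)])
  pos <- 0L
  labels <- integer(n)
  rec <- function(i, k) {
    if (i > n) {
      pos <<- pos + 1L
      out[[pos]] <<- labels[seq_len(n)]
      return(invisible())
    }
    for (l in seq_len(k + 1L)) {
      labels[i] <<- l
      rec(i + 1L, max(k, l))
    }
  }
  rec(1L, 0L)
  out[seq_len(pos)]
}

# relabel to 1..L* in order of first appearance
canonical_labels <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

#' Variation-of-Information point-estimate partition
#'
#' Picks, among a set of candidate partitions, the one minimizing the
#' posterior expected Variation of Information (via its co-clustering
#' lower bound).  Candidates are the average-linkage dendrogram cuts of
#' `1 - pcm` at every number of clusters, plus every distinct partition
#' visited by the chain when `labels_chain` is supplied; for n <= 10 all
#' set partitions are searched exhaustively instead.
#'
#' @param pcm Co-clustering matrix from [coclustering()].
#' @param labels_chain Optional n_kept x n label matrix (or
#'   `hidalgo_chains`) whose sampled partitions join the candidate set.
#' @return A list of class `vi_partition`: `labels` (1..L*, relabelled
#'   in order of first appearance), `L_star`, and `evi` (the attained
#'   bound).
#' @export
vi_partition <- function(pcm, labels_chain = NULL) {
  pcm <- as.matrix(pcm)
  n <- nrow(pcm)
  stopifnot(ncol(pcm) == n, all(pcm >= 0), all(pcm <= 1))
  if (inherits(labels_chain, "hidalgo_chains")) labels_chain <- labels_chain$labels

  if (n <= 10L) {
    cands <- all_set_partitions(n)
  } else {
    hc <- hclust(as.dist(1 - pcm), method = "average")
    cands <- lapply(seq_len(n), function(k) unname(cutree(hc, k = k)))
    if (!is.null(labels_chain)) {
      sampled <- unique(lapply(seq_len(nrow(labels_chain)),
                               function(t) canonical_labels(labels_chain[t, ])))
      cands <- c(cands, sampled)
    }
  }
  ev <- vapply(cands, function(l) expected_vi_lb(pcm, l), numeric(1))
  best <- canonical_labels(cands[[which.min(ev)]])
  structure(list(labels = best, L_star = max(best), evi = min(ev)),
            class = "vi_partition")
}

#' @export
print.vi_partition <- function(x, ...) {
  cat("<vi_partition> L* = ", x$L_star, ", sizes: ",
      paste(tabulate(x$labels), collapse = ", "),
      " (expected VI bound ", signif(x$evi, 4), ")\n", sep = "")
  invisible(x)
}

#' Map component chains to observation-specific ID chains
#'
#' Entry (t, i) is the ID draw of the component that observation i
#' belonged to at iteration t: d_(c_i).  Tracking IDs through the
#' labels makes the per-observation chains immune to label switching.
#'
#' @param labels n_kept x n label matrix or `hidalgo_chains`.
#' @param dims n_kept x L matrix of component ID draws (taken from the
#'   chains object when one is supplied).
#' @return An n_kept x n matrix of per-observation ID draws.
#' @export
observation_chains <- function(labels, dims = NULL) {
  if (inherits(labels, "hidalgo_chains")) {
    dims <- labels$dims
    labels <- labels$labels
  }
  labels <- as.matrix(labels); dims <- as.matrix(dims)
  stopifnot(nrow(labels) == nrow(dims))
  if (any(labels < 1L) || any(labels > ncol(dims))) {
    stop("labels outside 1..L", call. = FALSE)
  }
  n_kept <- nrow(labels); n <- ncol(labels)
  out <- matrix(dims[cbind(rep(seq_len(n_kept), times = n), as.vector(labels))],
                n_kept, n)
  colnames(out) <- colnames(labels)
  out
}

#' Posterior ID summaries per observation and per cluster
#'
#' Per observation: posterior median and central 90% interval of its ID
#' chain.  Per cluster of the supplied partition: posterior mean ID
#' pooled over the member observations' draws (the label-switching-safe
#' summary), plus the pooled draws for density plots.
#'
#' @param obs_chains Matrix from [observation_chains()].
#' @param partition A [vi_partition()] result (or a bare label vector).
#' @return A list with tibbles `observation` (unit, median_id, q05, q95,
#'   cluster) and `cluster` (cluster, n_units, mean_id, median_id), and
#'   `draws` (named list of pooled per-cluster draw vectors).
#' @export
summarize_id <- function(obs_chains, partition) {
  labels <- if (inherits(partition, "vi_partition")) partition$labels else partition
  obs_chains <- as.matrix(obs_chains)
  n <- ncol(obs_chains)
  stopifnot(length(labels) == n)
  units <- colnames(obs_chains)
  if (is.null(units)) units <- paste0("obs_", seq_len(n))
  observation <- tibble::tibble(
    unit = units,
    median_id = unname(apply(obs_chains, 2L, median)),
    q05 = unname(apply(obs_chains, 2L, quantile, probs = 0.05, names = FALSE)),
    q95 = unname(apply(obs_chains, 2L, quantile, probs = 0.95, names = FALSE)),
    cluster = as.integer(labels))
  draws <- lapply(sort(unique(labels)), function(l) {
    as.vector(obs_chains[, labels == l, drop = FALSE])
  })
  names(draws) <- paste0("cluster_", sort(unique(labels)))
  cluster <- tibble::tibble(
    cluster = sort(unique(labels)),
    n_units = as.integer(tabulate(labels)[sort(unique(labels))]),
    mean_id = unname(vapply(draws, mean, numeric(1))),
    median_id = unname(vapply(draws, median, numeric(1))))
  list(observation = observation, cluster = cluster, draws = draws)
}
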