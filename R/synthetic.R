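#' Specification of a multi-manifold point cloud
#'
#' Describes a mixture of uniform hypercube samples of distinct
#' intrinsic dimension, embedded in a common nominal dimension.  Each
#' component is a unit-side d-dimensional hypercube, zero-padded to
#' `nominal_dim`, rotated by a seeded random orthogonal matrix and
#' offset along the first axis by multiples of `separation` so that
#' component supports are well separated (the local-homogeneity premise
#' of the neighbourhood term).
#'
#' @param components List of `c(intrinsic_dim, n_points)` pairs (or a
#'   two-column matrix/data frame).  Every component needs at least 3
#'   points (the TWO-NN ratio needs two neighbours).
#' @param nominal_dim Ambient dimension D, at least the largest
#'   intrinsic dimension.
#' @param separation Offset between component supports in side lengths
#'   (default 10, far enough that small q-neighbourhoods are pure).
#' @param noise_sd Isotropic Gaussian noise added after embedding
#'   (default 0).
#' @param seed Integer seed; all randomness in the sample flows from it.
#' @return A list of class `manifold_spec`.
#' @export
manifold_spec <- function(components, nominal_dim, separation = 10,
                          noise_sd = 0, seed = NULL) {
  if (is.matrix(components) || is.data.frame(components)) {
    components <- lapply(seq_len(nrow(components)),
                         function(i) as.numeric(components[i, 1:2]))
  }
  comp <- lapply(components, function(cc) {
    cc <- as.integer(cc)
    if (length(cc) != 2L || cc[1L] < 1L) stop("component needs (intrinsic_dim, n_points)",
                                              call. = FALSE)
    if (cc[2L] < 3L) stop("every component needs at least 3 points", call. = FALSE)
    list(intrinsic_dim = cc[1L], n_points = cc[2L])
  })
  nominal_dim <- as.integer(nominal_dim)
  dmax <- max(vapply(comp, `[[`, integer(1), "intrinsic_dim"))
  if (nominal_dim < dmax) stop("nominal_dim must be >= every intrinsic_dim",
                               call. = FALSE)
  stopifnot(separation >= 0, noise_sd >= 0)
  structure(list(components = comp, nominal_dim = nominal_dim,
                 separation = separation, noise_sd = noise_sd, seed = seed),
            class = "manifold_spec")
}

# random orthogonal matrix via QR of a Gaussian matrix
random_rotation <- function(D) {
  qr_d <- qr(matrix(rnorm(D * D), D, D))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), D)
}

#' Sample a multi-manifold mixture point cloud
#'
#' @param spec A [manifold_spec()].
#' @return List with `matrix` (n x D, rows unique), `true_labels`
#'   (component index per row) and `true_dims` (intrinsic dimension per
#'   row).
#' @export
sample_manifold_mixture <- function(spec) {
  stopifnot(inherits(spec, "manifold_spec"))
  gen <- function() {
    D <- spec$nominal_dim
    parts <- lapply(seq_along(spec$components), function(l) {
      cc <- spec$components[[l]]
      u <- matrix(runif(cc$n_points * cc$intrinsic_dim), cc$n_points)
      x <- cbind(u, matrix(0, cc$n_points, D - cc$intrinsic_dim))
      x <- x %*% random_rotation(D)
      x[, 1L] <- x[, 1L] + (l - 1L) * spec$separation
      if (spec$noise_sd > 0) x <- x + matrix(rnorm(length(x), sd = spec$noise_sd),
                                             nrow(x))
      x
    })
    m <- do.call(rbind, parts)
    rownames(m) <- sprintf("u%04d", seq_len(nrow(m)))
    labs <- rep(seq_along(spec$components),
                vapply(spec$components, `[[`, integer(1), "n_points"))
    dims <- vapply(spec$components, `[[`, integer(1), "intrinsic_dim")[labs]
    if (anyDuplicated(m)) stop("degenerate sample with duplicate rows", call. = FALSE)
    list(matrix = m, true_labels = labs, true_dims = dims)
  }
  if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
}

#' Specification of a synthetic country panel
#'
#' Describes a panel of `n_units` units observed daily over `n_days` on
#' `n_variables` series.  Each unit's concatenated series is a linear
#' combination of `latent_dim` shared latent factor series with
#' unit-specific loadings, so the noiseless concatenated matrix has rank
#' at most `latent_dim`.  With `spatial_field = TRUE`, units take their
#' factor regime from the community structure of `graph`, making the
#' implied ID map spatially autocorrelated by construction.
#'
#' @param n_units,n_days Panel size.
#' @param n_variables Number of daily series per unit (default 3).
#' @param latent_dim Number of shared latent factors; at most
#'   `n_days * n_variables`.  May be a vector: with `spatial_field` on,
#'   community k of the graph uses `latent_dim[(k - 1) %% length + 1]`,
#'   so different regions can lie on manifolds of different intrinsic
#'   dimension.
#' @param missing_rate Fraction of values deleted completely at random,
#'   in `[0, 1)` (default 0).
#' @param noise_sd Observation noise (default 0).
#' @param graph Two-column edge list over units (required when
#'   `spatial_field` is on; must leave no unit isolated).
#' @param spatial_field Logical; tie factor regimes to graph
#'   communities.
#' @param start_date First calendar day (default `"2020-03-01"`).
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_units, n_days, n_variables = 3L, latent_dim = 3L,
                       missing_rate = 0, noise_sd = 0, graph = NULL,
                       spatial_field = FALSE, start_date = "2020-03-01",
                       seed = NULL) {
  n_units <- as.integer(n_units); n_days <- as.integer(n_days)
  n_variables <- as.integer(n_variables); latent_dim <- as.integer(latent_dim)
  stopifnot(n_units >= 1L, n_days >= 1L, n_variables >= 1L,
            length(latent_dim) >= 1L, all(latent_dim >= 1L),
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0)
  if (max(latent_dim) > n_days * n_variables) {
    stop("latent_dim must be <= n_days * n_variables", call. = FALSE)
  }
  if (isTRUE(spatial_field)) {
    if (is.null(graph)) stop("spatial_field needs a graph", call. = FALSE)
    deg <- tabulate(as.vector(as.matrix(graph)[, 1:2]), nbins = n_units)
    if (any(deg == 0)) {
      stop("graph leaves isolated unit(s): ",
           paste(which(deg == 0), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_units = n_units, n_days = n_days, n_variables = n_variables,
                 latent_dim = latent_dim, missing_rate = missing_rate,
                 noise_sd = noise_sd, graph = graph,
                 spatial_field = isTRUE(spatial_field),
                 start_date = as.Date(start_date), seed = seed),
            class = "panel_spec")
}

#' Generate a synthetic country panel
#'
#' @param spec A [panel_spec()].
#' @return List with `panel` (a [country_panel()] with lognormal
#'   population metadata) and `true_membership` (factor-regime index per
#'   unit; all 1 when `spatial_field` is off).
#' @export
synth_country_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  gen <- function() {
    n <- spec$n_units
    D <- spec$n_days * spec$n_variables
    if (spec$spatial_field) {
      g <- igraph::graph_from_edgelist(as.matrix(spec$graph)[, 1:2, drop = FALSE],
                                       directed = FALSE)
      g <- igraph::simplify(igraph::add_vertices(g, max(0L, n - igraph::vcount(g))))
      membership <- as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
    } else {
      membership <- rep(1L, n)
    }
    K <- max(membership)
    ld <- spec$latent_dim[(seq_len(K) - 1L) %% length(spec$latent_dim) + 1L]
    factors <- lapply(seq_len(K), function(k) matrix(rnorm(ld[k] * D), ld[k], D))
    values <- t(vapply(seq_len(n), function(u) {
      k <- membership[u]
      as.vector(rnorm(ld[k]) %*% factors[[k]])
    }, numeric(D)))
    if (spec$noise_sd > 0) {
      values <- values + matrix(rnorm(length(values), sd = spec$noise_sd), n)
    }
    units <- sprintf("U%03d", seq_len(n))
    dates <- spec$start_date + seq_len(spec$n_days) - 1L
    vars <- if (spec$n_variables == 3L) c("cases_pmp", "deaths_pmp", "stringency")
            else sprintf("var%d", seq_len(spec$n_variables))
    # column layout of `values` is variable-major to mirror concatenate()
    long <- tibble::tibble(
      unit = rep(units, each = D),
      variable = rep(rep(vars, each = spec$n_days), times = n),
      date = rep(rep(dates, times = spec$n_variables), times = n),
      value = as.vector(t(values)))
    if (spec$missing_rate > 0) {
      drop <- runif(nrow(long)) < spec$missing_rate
      long$value[drop] <- NA_real_
    }
    population <- tibble::tibble(
      unit = units,
      population = round(stats::rlnorm(n, meanlog = log(5e6), sdlog = 1.2)))
    list(panel = country_panel(long[, c("unit", "date", "variable", "value")],
                               population = population),
         true_membership = membership)
  }
  if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
}

#' Generate a synthetic spatial adjacency structure
#'
#' `"grid"` lays the units on a near-square lattice with rook
#' contiguity; `"random_geometric"` scatters them uniformly in the unit
#' square and connects pairs closer than `1.5 / sqrt(n)`, then wires any
#' isolated unit to its nearest unit so that every unit ends up with at
#' least one neighbour.
#'
#' @param n_units Number of units (>= 2).
#' @param model `"grid"` or `"random_geometric"`.
#' @param seed Integer seed (used by the geometric model).
#' @return A [build_weights()] object.
#' @export
synth_adjacency <- function(n_units, model = c("grid", "random_geometric"),
                            seed = NULL) {
  model <- match.arg(model)
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 2L)
  gen <- function() {
    if (model == "grid") {
      nr <- floor(sqrt(n_units))
      nc <- ceiling(n_units / nr)
      idx <- function(r, ch) (r - 1L) * nc + ch
      edges <- NULL
      for (r in seq_len(nr)) for (ch in seq_len(nc)) {
        i <- idx(r, ch)
        if (i > n_units) next
        if (ch < nc && idx(r, ch + 1L) <= n_units) edges <- rbind(edges, c(i, idx(r, ch + 1L)))
        if (r < nr && idx(r + 1L, ch) <= n_units) edges <- rbind(edges, c(i, idx(r + 1L, ch)))
      }
      # a trailing short row can leave its last cell tied only rightwards
      deg <- tabulate(as.vector(edges), nbins = n_units)
      if (any(deg == 0)) {
        for (i in which(deg == 0)) edges <- rbind(edges, c(i, i - 1L))
      }
    } else {
      pts <- cbind(runif(n_units), runif(n_units))
      dm <- as.matrix(dist(pts))
      r <- 1.5 / sqrt(n_units)
      edges <- which(dm <= r & upper.tri(dm), arr.ind = TRUE)
      deg <- tabulate(as.vector(edges), nbins = n_units)
      for (i in which(deg == 0)) {
        nb <- order(dm[i, ])[2L]  # nearest other unit
        edges <- rbind(edges, c(min(i, nb), max(i, nb)))
        deg <- tabulate(as.vector(edges), nbins = n_units)
      }
      edges <- unique(edges)
      dimnames(edges) <- NULL
    }
    build_weights(edges, n_units)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
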