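#' Read and write pipeline artifacts
#'
#' Panels travel as long-format CSV (`unit,date,variable,value`) with an
#' optional unit-metadata CSV (`unit,population`); adjacency as a
#' two-column edge-list TSV; analysis matrices as CSV with a leading
#' `unit` column.
#'
#' @param panel A [country_panel()].
#' @param path Output/input file path.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "country_panel"))
  write.csv(tibble::as_tibble(panel)[, c("unit", "date", "variable", "value")],
            path, row.names = FALSE)
  pop <- panel_population(panel)
  if (!is.null(pop)) {
    write.csv(pop, sub("\\.csv$", "_population.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname panel_io
#' @param population_path Optional path of the unit-metadata CSV.
#' @export
read_panel_csv <- function(path, population_path = NULL) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  pop <- if (!is.null(population_path)) read.csv(population_path, stringsAsFactors = FALSE)
  country_panel(data, population = pop)
}

#' @rdname panel_io
#' @param m Numeric matrix with unit row names.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(unit = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname panel_io
#' @param weights A [build_weights()] object.
#' @export
write_edges_tsv <- function(weights, path) {
  stopifnot(inherits(weights, "spatial_weights"))
  idx <- which(weights$w == 1 & upper.tri(weights$w), arr.ind = TRUE)
  ed <- data.frame(from = idx[, 1L], to = idx[, 2L])
  if (!is.null(weights$units)) {
    ed$from <- weights$units[idx[, 1L]]
    ed$to <- weights$units[idx[, 2L]]
  }
  write.table(ed, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @param n As in [build_weights()]: unit count or unit names.
#' @export
read_edges_tsv <- function(path, n) {
  ed <- read.delim(path, stringsAsFactors = FALSE)
  build_weights(ed, n)
}

#' Write MCMC chains as the three canonical CSV matrices
#'
#' Membership labels (n_kept x n), mixing weights (n_kept x L) and
#' intrinsic dimensions (n_kept x L) as `labels.csv`, `weights.csv`,
#' `dims.csv`, plus a `config.json` sidecar echoing the configuration,
#' seed and package version.
#'
#' @param chains A `hidalgo_chains` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_chains <- function(chains, dir) {
  stopifnot(inherits(chains, "hidalgo_chains"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- chains$labels
  if (!is.null(chains$units)) colnames(lab) <- chains$units
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(chains$weights, file.path(dir, "weights.csv"), row.names = FALSE)
  write.csv(chains$dims, file.path(dir, "dims.csv"), row.names = FALSE)
  cfg <- chains$config
  cfg$package_version <- as.character(utils::packageVersion("hidalgoid"))
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
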