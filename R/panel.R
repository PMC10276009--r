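#' Country panel container
#'
#' A `country_panel` holds per-unit, per-day values for one or more
#' variables on a common daily date grid, plus optional per-unit
#' population metadata.  It is the input container for the preprocessing
#' pipeline that ends in the n x D analysis matrix.
#'
#' @param data A data frame with columns `unit`, `date` (class `Date`),
#'   `variable` and `value`.  Every unit must carry every variable on the
#'   full date grid; `value` may be `NA`.
#' @param population Optional data frame with columns `unit` and
#'   `population` (positive), one row per unit.
#'
#' @return An object of class `country_panel`: a tibble as above with
#'   attributes `units`, `dates`, `variables` and (optionally)
#'   `population`.
#' @export
country_panel <- function(data, population = NULL) {
  data <- tibble::as_tibble(data)
  req <- c("unit", "date", "variable", "value")
  if (!all(req %in% names(data))) {
    stop("panel data needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!inherits(data$date, "Date")) data$date <- as.Date(data$date)
  units <- sort(unique(as.character(data$unit)))
  dates <- sort(unique(data$date))
  vars  <- sort(unique(as.character(data$variable)))

  if (length(dates) > 1L) {
    gaps <- diff(as.integer(dates))
    if (any(gaps != 1L)) {
      stop("panel dates must be contiguous at daily resolution", call. = FALSE)
    }
  }
  expected <- length(units) * length(dates) * length(vars)
  key <- paste(data$unit, data$date, data$variable)
  if (anyDuplicated(key)) stop("duplicated (unit, date, variable) rows", call. = FALSE)
  if (nrow(data) != expected) {
    stop("panel is not a complete unit x date x variable grid (",
         nrow(data), " rows, expected ", expected, ")", call. = FALSE)
  }

  if (!is.null(population)) {
    population <- tibble::as_tibble(population)
    if (!all(c("unit", "population") %in% names(population))) {
      stop("population metadata needs columns `unit` and `population`", call. = FALSE)
    }
    population$unit <- as.character(population$unit)
    population <- population[population$unit %in% units, , drop = FALSE]
  }

  data <- dplyr::arrange(data, .data$unit, .data$variable, .data$date)
  structure(data,
            units = units, dates = dates, variables = vars,
            population = population,
            class = c("country_panel", class(tibble::tibble())))
}

#' @export
print.country_panel <- function(x, ...) {
  cat("<country_panel> ", length(attr(x, "units")), " units x ",
      length(attr(x, "dates")), " days x ",
      length(attr(x, "variables")), " variables\n", sep = "")
  cat("  dates: ", format(min(attr(x, "dates"))), " .. ",
      format(max(attr(x, "dates"))), "\n", sep = "")
  if (!is.null(attr(x, "population"))) cat("  population metadata: yes\n")
  invisible(x)
}

#' @rdname country_panel
#' @param x A `country_panel`.
#' @export
panel_units <- function(x) attr(x, "units")

#' @rdname country_panel
#' @export
panel_dates <- function(x) attr(x, "dates")

#' @rdname country_panel
#' @export
panel_variables <- function(x) attr(x, "variables")

#' @rdname country_panel
#' @export
panel_population <- function(x) attr(x, "population")

# rebuild a country_panel after row subsetting, keeping metadata in sync
rebuild_panel <- function(data, population = NULL, extra_attrs = NULL) {
  p <- country_panel(tibble::as_tibble(data), population = population)
  for (nm in names(extra_attrs)) attr(p, nm) <- extra_attrs[[nm]]
  p
}
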