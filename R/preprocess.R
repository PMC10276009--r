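#' Drop units with too much missing data
#'
#' A unit is retained only if, for every variable, its fraction of
#' missing daily values does not exceed `max_missing_frac` (strictly more
#' than the threshold excludes).  The default 0.2 reproduces the usual
#' "more than 20% missing in any series" rule for country panels.
#'
#' @param panel A [country_panel()].
#' @param max_missing_frac Maximum tolerated missing fraction per
#'   variable, in `[0, 1)`.  Default `0.2`.
#'
#' @return The filtered `country_panel`.  The attribute `"exclusions"`
#'   holds a tibble (unit, variable, missing_frac) for the dropped units.
#' @export
filter_missing <- function(panel, max_missing_frac = 0.2) {
  stopifnot(inherits(panel, "country_panel"))
  fr <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(panel), .data$unit, .data$variable),
    missing_frac = mean(is.na(.data$value)), .groups = "drop")
  bad <- fr[fr$missing_frac > max_missing_frac, , drop = FALSE]
  keep <- setdiff(panel_units(panel), unique(bad$unit))
  if (length(keep) == 0L) {
    stop("no units survive the missing-data filter", call. = FALSE)
  }
  out <- dplyr::filter(tibble::as_tibble(panel), .data$unit %in% keep)
  pop <- panel_population(panel)
  if (!is.null(pop)) pop <- pop[pop$unit %in% keep, , drop = FALSE]
  rebuild_panel(out, pop, list(exclusions = bad))
}

#' Impute missing values in a daily series by a linear fit on time
#'
#' Missing entries are replaced by the ordinary-least-squares regression
#' line of the observed values on the time index (`method = "ols"`, the
#' default), or by linear interpolation between observed neighbours with
#' flat extrapolation at the ends (`method = "interp"`).  Observed
#' entries are never altered.
#'
#' @param x Numeric vector, possibly with `NA`s.
#' @param time_index Numeric/integer time index, same length as `x`.
#' @param method `"ols"` (global least-squares line) or `"interp"`.
#'
#' @return `x` with missing entries filled.
#' @export
impute_linear <- function(x, time_index = seq_along(x),
                          method = c("ols", "interp")) {
  method <- match.arg(method)
  if (length(x) != length(time_index)) {
    stop("`x` and `time_index` lengths differ", call. = FALSE)
  }
  obs <- !is.na(x)
  if (sum(obs) < 2L) stop("need at least 2 observed points to impute", call. = FALSE)
  if (!any(is.na(x))) return(x)
  t <- as.numeric(time_index)
  if (sd(t[obs]) == 0) stop("time index is constant on observed points", call. = FALSE)
  if (method == "ols") {
    fit <- lm(y ~ t, data = data.frame(y = x[obs], t = t[obs]))
    x[!obs] <- predict(fit, newdata = data.frame(t = t[!obs]))
  } else {
    x[!obs] <- approx(t[obs], x[obs], xout = t[!obs], rule = 2)$y
  }
  x
}

#' Impute every unit/variable series of a panel
#'
#' @param panel A [country_panel()].
#' @inheritParams impute_linear
#' @return A complete `country_panel` with no missing values.
#' @export
impute_panel <- function(panel, method = c("ols", "interp")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "country_panel"))
  data <- tibble::as_tibble(panel)
  data <- dplyr::mutate(
    dplyr::group_by(data, .data$unit, .data$variable),
    value = if (anyNA(.data$value)) {
      impute_linear(.data$value, as.numeric(.data$date), method = method)
    } else .data$value)
  data <- dplyr::ungroup(data)
  rebuild_panel(data, panel_population(panel))
}

#' Drop small-population units
#'
#' Units with population strictly below `min_pop` are removed (a unit at
#' exactly the threshold is retained).  Small populations make per-capita
#' daily rates volatile, which distorts nearest-neighbour geometry.
#'
#' @param panel A [country_panel()] with population metadata.
#' @param min_pop Minimum population, default one million.
#' @return The filtered `country_panel`.
#' @export
filter_population <- function(panel, min_pop = 1e6) {
  stopifnot(inherits(panel, "country_panel"))
  pop <- panel_population(panel)
  if (is.null(pop)) stop("panel has no population metadata", call. = FALSE)
  missing_pop <- setdiff(panel_units(panel), pop$unit[!is.na(pop$population)])
  if (length(missing_pop)) {
    stop("missing population for unit(s): ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  keep <- pop$unit[pop$population >= min_pop]
  if (length(keep) == 0L) stop("no units survive the population filter", call. = FALSE)
  out <- dplyr::filter(tibble::as_tibble(panel), .data$unit %in% keep)
  rebuild_panel(out, pop[pop$unit %in% keep, , drop = FALSE])
}

#' Pooled z-score standardization per variable
#'
#' Each variable is standardized as z = (x - mean) / sd where the mean
#' and (sample, n-1 denominator) standard deviation are pooled over all
#' units and all days of that variable — variables are standardized
#' independently, units are not.
#'
#' @param panel A complete (no `NA`) [country_panel()].
#' @return A `standardized_panel` (also a `country_panel`); the attribute
#'   `"scaling"` records the per-variable mean and sd used.
#' @export
standardize <- function(panel) {
  stopifnot(inherits(panel, "country_panel"))
  data <- tibble::as_tibble(panel)
  if (anyNA(data$value)) stop("standardize() needs a complete panel; impute first", call. = FALSE)
  scaling <- dplyr::summarise(dplyr::group_by(data, .data$variable),
                              mean = mean(.data$value),
                              sd = sd(.data$value), .groups = "drop")
  if (any(scaling$sd == 0)) {
    stop("degenerate variable(s) with zero pooled sd: ",
         paste(scaling$variable[scaling$sd == 0], collapse = ", "), call. = FALSE)
  }
  data <- dplyr::left_join(data, scaling, by = "variable")
  data$value <- (data$value - data$mean) / data$sd
  data$mean <- NULL; data$sd <- NULL
  out <- rebuild_panel(data, panel_population(panel), list(scaling = scaling))
  class(out) <- c("standardized_panel", class(out))
  out
}

#' Concatenate a panel into the n x D analysis matrix
#'
#' One row per unit; columns are variable 1's days, then variable 2's
#' days, and so on, so D = n_variables x n_days.  Row names are unit
#' IDs, column names `"var:day_t"`.  Duplicate rows are a hard error
#' because the downstream Pareto-ratio model needs unique observations
#' (a zero first-neighbour distance is undefined).
#'
#' @param panel A complete (typically standardized) [country_panel()].
#' @return A numeric matrix.
#' @export
concatenate <- function(panel) {
  stopifnot(inherits(panel, "country_panel"))
  data <- tibble::as_tibble(panel)
  if (anyNA(data$value)) stop("concatenate() needs a complete panel", call. = FALSE)
  units <- panel_units(panel); dates <- panel_dates(panel)
  vars <- panel_variables(panel)
  data <- data[order(match(data$unit, units), match(data$variable, vars),
                     data$date), , drop = FALSE]
  D <- length(vars) * length(dates)
  m <- matrix(data$value, nrow = length(units), ncol = D, byrow = TRUE)
  rownames(m) <- units
  colnames(m) <- paste0(rep(vars, each = length(dates)), ":day_",
                        rep(seq_along(dates), times = length(vars)))
  dup <- duplicated(m) | duplicated(m, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate rows for units: ", paste(units[dup], collapse = ", "),
         "; unique observations are required", call. = FALSE)
  }
  m
}

#' Temporal stage windows
#'
#' `stage_window()` builds one labelled inclusive date window;
#' `stage_windows()` returns the four pandemic stages used for the
#' reference analysis (1 Mar 2020 – 23 Jun 2020, 24 Jun – 15 Oct 2020,
#' 16 Oct 2020 – 6 Feb 2021, 7 Feb – 29 May 2021).
#'
#' @param label Window label.
#' @param start,end Inclusive window bounds (`Date` or coercible).
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
stage_window <- function(label, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("window end precedes start", call. = FALSE)
  tibble::tibble(label = label, start = start, end = end)
}

#' @rdname stage_window
#' @export
stage_windows <- function() {
  dplyr::bind_rows(
    stage_window(1L, "2020-03-01", "2020-06-23"),
    stage_window(2L, "2020-06-24", "2020-10-15"),
    stage_window(3L, "2020-10-16", "2021-02-06"),
    stage_window(4L, "2021-02-07", "2021-05-29"))
}

#' Split a panel into temporal stages
#'
#' The windows must partition the panel's date range: no gaps, no
#' overlaps, full coverage (windows may extend past the panel's first or
#' last date, but every panel date must fall in exactly one window).
#'
#' @param panel A [country_panel()].
#' @param windows A tibble of windows as from [stage_windows()].
#' @return A named list of sub-panels, one per window.
#' @export
stratify <- function(panel, windows = stage_windows()) {
  stopifnot(inherits(panel, "country_panel"))
  windows <- windows[order(windows$start), , drop = FALSE]
  if (nrow(windows) > 1L) {
    gap <- as.integer(windows$start[-1L]) - as.integer(windows$end[-nrow(windows)])
    if (any(gap > 1L)) stop("gap between consecutive windows", call. = FALSE)
    if (any(gap < 1L)) stop("overlapping windows", call. = FALSE)
  }
  dates <- panel_dates(panel)
  covered <- dates >= min(windows$start) & dates <= max(windows$end)
  if (!all(covered)) stop("windows do not cover the panel's date range", call. = FALSE)
  pop <- panel_population(panel)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    d <- dplyr::filter(tibble::as_tibble(panel),
                       .data$date >= windows$start[i], .data$date <= windows$end[i])
    if (nrow(d) == 0L) stop("window ", windows$label[i], " contains no panel dates",
                            call. = FALSE)
    rebuild_panel(d, pop)
  })
  names(out) <- paste0("stage_", windows$label)
  out
}

#' Preprocess a raw panel into the analysis matrix
#'
#' Convenience wrapper running the canonical order: missing-data filter,
#' imputation of remaining gaps, population filter, pooled z-scoring,
#' concatenation.
#'
#' @param panel A [country_panel()].
#' @param max_missing_frac Passed to [filter_missing()].
#' @param min_pop Passed to [filter_population()]; `NULL` skips the
#'   population filter (e.g. when no metadata is available).
#' @param impute_method Passed to [impute_panel()].
#' @return A list with `matrix` (the n x D [concatenate()] output),
#'   `panel` (the standardized panel) and `exclusions`.
#' @export
preprocess_panel <- function(panel, max_missing_frac = 0.2, min_pop = 1e6,
                             impute_method = c("ols", "interp")) {
  impute_method <- match.arg(impute_method)
  p <- filter_missing(panel, max_missing_frac)
  exclusions <- attr(p, "exclusions")
  p <- impute_panel(p, method = impute_method)
  if (!is.null(min_pop) && !is.null(panel_population(p))) {
    p <- filter_population(p, min_pop)
  }
  p <- standardize(p)
  list(matrix = concatenate(p), panel = p, exclusions = exclusions)
}
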