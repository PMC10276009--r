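# small hand-built panel: `miss` marks which (unit, variable) series get
# missing values and how many of the n_days days
make_panel <- function(units = c("A", "B", "C"), n_days = 20L,
                       vars = c("x", "y"), miss = NULL, population = NULL,
                       seed = 1L) {
  withr::with_seed(seed, {
    grid <- expand.grid(unit = units, variable = vars,
                        date = as.Date("2020-03-01") + seq_len(n_days) - 1L,
                        stringsAsFactors = FALSE)
    grid$value <- rnorm(nrow(grid)) + as.numeric(factor(grid$unit))
    if (!is.null(miss)) {
      for (k in seq_len(nrow(miss))) {
        idx <- which(grid$unit == miss$unit[k] & grid$variable == miss$variable[k])
        grid$value[idx[seq_len(miss$n[k])]] <- NA_real_
      }
    }
    country_panel(grid, population = population)
  })
}

test_that("missing-data filter excludes strictly above the threshold", {
  # C has 25% missing in one variable -> dropped; B at exactly 20% -> kept
  p <- make_panel(miss = data.frame(unit = c("B", "C"), variable = "x",
                                    n = c(4L, 5L)))
  out <- filter_missing(p, 0.2)
  expect_setequal(panel_units(out), c("A", "B"))
  expect_equal(attr(out, "exclusions")$unit, "C")

  full <- make_panel()
  expect_identical(panel_units(filter_missing(full)), panel_units(full))

  # at a zero threshold only the fully observed unit survives
  expect_identical(panel_units(filter_missing(p, max_missing_frac = 0)), "A")
  all_gappy <- make_panel(miss = data.frame(unit = c("A", "B", "C"),
                                            variable = "x", n = 5L))
  expect_error(filter_missing(all_gappy, max_missing_frac = 0.1),
               "no units survive")
})

test_that("linear imputation fits the observed points and fills the gaps", {
  expect_equal(impute_linear(c(1, NA, 3), 0:2), c(1, 2, 3))
  x <- c(0.5, 1.2, 0.8)
  expect_identical(impute_linear(x, 0:2), x)
  # OLS on observed pairs (0,0), (1,1): line v = t, predicted at t = 2, 3
  expect_equal(impute_linear(c(0, 1, NA, NA), 0:3), c(0, 1, 2, 3))
  # interpolation carries the last observed value forward at the edges
  expect_equal(impute_linear(c(0, 2, NA, NA), 0:3, method = "interp"),
               c(0, 2, 2, 2))
  expect_error(impute_linear(c(1, NA, NA), 0:2), "at least 2 observed")
  expect_error(impute_linear(c(1, NA, 2), c(3, 1, 3)), "constant")
})

test_that("panel-level imputation touches only the missing cells", {
  p <- make_panel(miss = data.frame(unit = "A", variable = "y", n = 3L))
  out <- impute_panel(p)
  expect_false(anyNA(tibble::as_tibble(out)$value))
  a <- tibble::as_tibble(p); b <- tibble::as_tibble(out)
  obs <- !is.na(a$value)
  expect_equal(b$value[obs], a$value[obs])
})

test_that("population filter uses a strict lower bound", {
  pop <- data.frame(unit = c("A", "B", "C"),
                    population = c(5e5, 1e6, 2e6))
  p <- make_panel(population = pop)
  out <- filter_population(p)
  expect_setequal(panel_units(out), c("B", "C"))  # exactly 1e6 is kept

  all_big <- make_panel(population = data.frame(unit = c("A", "B", "C"),
                                                population = rep(2e6, 3)))
  expect_identical(panel_units(filter_population(all_big)),
                   panel_units(all_big))
  expect_error(filter_population(make_panel()), "no population")
  pop$population[2] <- NA
  expect_error(filter_population(make_panel(population = pop)), "B")
})

test_that("standardization pools across units and days, per variable", {
  p <- make_panel()
  z <- standardize(p)
  v <- tibble::as_tibble(z)
  for (k in panel_variables(z)) {
    expect_lt(abs(mean(v$value[v$variable == k])), 1e-9)
    expect_lt(abs(sd(v$value[v$variable == k]) - 1), 1e-9)
  }
  # z of z is z
  zz <- standardize(z)
  expect_equal(tibble::as_tibble(zz)$value, tibble::as_tibble(z)$value,
               tolerance = 1e-9)
  # symmetric three-point pool maps to (-1, 0, 1) under the sample sd
  tiny <- country_panel(data.frame(
    unit = rep(c("A", "B", "C"), 1), date = as.Date("2020-03-01"),
    variable = "x", value = c(1, 2, 3)))
  expect_equal(sort(tibble::as_tibble(standardize(tiny))$value), c(-1, 0, 1))
  # constant variable is degenerate
  const <- country_panel(data.frame(
    unit = rep(c("A", "B"), each = 2),
    date = rep(as.Date("2020-03-01") + 0:1, 2),
    variable = "x", value = 5))
  expect_error(standardize(const), "zero pooled sd")
})

test_that("concatenation is variable-major with intact unit correspondence", {
  p <- make_panel(units = sprintf("U%02d", 1:10), vars = c("a", "b", "c"))
  m <- concatenate(p)
  expect_equal(dim(m), c(10L, 60L))
  expect_identical(rownames(m), panel_units(p))
  # spot-check the layout: row U03, variable b, day 7
  v <- tibble::as_tibble(p)
  expect_equal(m["U03", "b:day_7"],
               v$value[v$unit == "U03" & v$variable == "b" &
                       v$date == as.Date("2020-03-01") + 6])
  # round-trips through CSV with the unit column preserved
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, f)
  m2 <- read_matrix_csv(f)
  expect_equal(m2, m)

  dup <- tibble::as_tibble(p)
  dup$value[dup$unit == "U02"] <- dup$value[dup$unit == "U01"]
  expect_error(concatenate(country_panel(dup)), "U01, U02")
})

test_that("stratification reproduces the four-stage calendar", {
  # 454 daily observations starting 1 Mar 2020
  p <- make_panel(units = c("A", "B"), n_days = 454L, vars = "x")
  stages <- stratify(p, stage_windows())
  expect_length(stages, 4L)
  expect_length(panel_dates(stages$stage_1), 115L)  # 1 Mar - 23 Jun inclusive
  all_dates <- unname(do.call(c, lapply(stages, panel_dates)))
  expect_equal(sort(all_dates), panel_dates(p))     # partition: no gap/overlap
  expect_equal(anyDuplicated(all_dates), 0L)

  w <- stage_windows()
  w$start[2] <- w$start[2] + 5
  expect_error(stratify(p, w), "gap")
  w <- stage_windows()
  w$end[1] <- w$end[1] + 3
  expect_error(stratify(p, w), "overlap")
})

test_that("the filter stages are idempotent", {
  pop <- data.frame(unit = c("A", "B", "C"), population = c(5e5, 2e6, 3e6))
  p <- make_panel(miss = data.frame(unit = "C", variable = "x", n = 5L),
                  population = pop)
  f1 <- filter_missing(p)
  expect_identical(panel_units(filter_missing(f1)), panel_units(f1))
  f2 <- filter_population(impute_panel(f1))
  expect_identical(panel_units(filter_population(f2)), panel_units(f2))
})
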