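write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

fixture_rows <- function(dish_id, cum, times = seq_along(cum) * 12,
                         stage = "germination", value = 20, sown = 50,
                         viable = NULL, dead = 2) {
  if (is.null(viable)) viable <- sown - max(cum) - dead
  data.frame(dish_id = dish_id, species = "Test sp.", accession = "A1",
             region = "reg", replicate = 1, stage = stage,
             treatment_kind = "temperature", treatment_value = value,
             time_h = times, cum_count = cum, n_sown = sown,
             n_viable_ungerminated = viable, n_dead = dead)
}

test_that("a well-formed table parses into one validated object per dish", {
  df <- rbind(fixture_rows("d1", c(5, 20, 40)),
              fixture_rows("d2", c(0, 10, 30)),
              fixture_rows("d3", c(2, 25, 43)))
  dishes <- read_scoring_table(write_fixture_csv(df))
  expect_length(dishes, 3)
  expect_s3_class(dishes[[1]], "dish_time_course")
  d1 <- dishes[[which(vapply(dishes, `[[`, "", "dish_id") == "d1")]]
  expect_equal(d1$cum_counts, c(5, 20, 40))
  expect_equal(d1$times, c(12, 24, 36))
})

test_that("interval counts are cumulated on read", {
  df <- fixture_rows("d1", c(5, 15, 20), viable = 8)  # interval increments
  dishes <- read_scoring_table(write_fixture_csv(df), counts = "interval")
  expect_equal(dishes[[1]]$cum_counts, c(5, 20, 40))
})

test_that("schema and validation errors name the problem", {
  df <- fixture_rows("d1", c(5, 20, 40))
  expect_error(read_scoring_table(write_fixture_csv(df[-which(names(df) == "stage")])),
               class = "st_schema_error")
  bad <- fixture_rows("d9", c(40, 38, 41))
  expect_error(read_scoring_table(write_fixture_csv(bad)), "d9",
               class = "st_validation_error")
  # accounting identity violation
  off <- fixture_rows("d7", c(5, 20, 40), viable = 3, dead = 3)
  expect_error(read_scoring_table(write_fixture_csv(off)), "d7",
               class = "st_validation_error")
  # 40 germinated + 5 viable + 5 dead of 50 sown is accepted
  ok <- fixture_rows("d8", c(5, 20, 40), viable = 5, dead = 5)
  expect_length(read_scoring_table(write_fixture_csv(ok)), 1)
})

test_that("dish construction enforces ordering and non-negativity", {
  expect_error(make_dish(c(12, 12, 36), c(1, 2, 3)),
               class = "st_validation_error")
  expect_error(make_dish(c(12, 24), c(3, -1), viable_ung = 51),
               class = "st_validation_error")
})

test_that("viable basis follows the germinated-plus-living rule", {
  d <- make_dish(c(24, 48, 72), c(10, 30, 40), viable_ung = 5, dead = 5)
  vb <- viable_basis(d, seedling_final = 30)
  expect_equal(vb$n_viable, 45)
  expect_equal(vb$pct_germination, 100 * 40 / 45, tolerance = 1e-12)
  expect_equal(vb$pct_seedlings_of_germinated, 75)
  # all-germinated-or-dead dish: 100% of viable
  d2 <- make_dish(c(24, 48), c(20, 40), viable_ung = 0, dead = 10)
  expect_equal(viable_basis(d2)$pct_germination, 100)
})

test_that("viable basis is scale-free in the counts", {
  d1 <- make_dish(c(24, 48, 72), c(5, 15, 20), sown = 25, viable_ung = 3,
                  dead = 2)
  d2 <- make_dish(c(24, 48, 72), c(10, 30, 40), sown = 50, viable_ung = 6,
                  dead = 4)
  expect_equal(viable_basis(d1)$pct_germination,
               viable_basis(d2)$pct_germination)
})

test_that("viable-basis inconsistencies are errors", {
  dead_dish <- make_dish(c(24, 48), c(0, 0), sown = 10, viable_ung = 0,
                         dead = 10)
  expect_error(viable_basis(dead_dish), class = "st_no_viable_seed")
  none <- make_dish(c(24, 48), c(0, 0), sown = 10, viable_ung = 8, dead = 2)
  expect_error(viable_basis(none, seedling_final = 3),
               class = "st_inconsistency")
})

test_that("parameter tables round-trip losslessly through CSV", {
  params <- data.frame(
    accession = rep(sprintf("A%02d", 1:10), each = 4),
    species = "Test sp.",
    stage = rep(c("germination", "seedling"), each = 2, times = 10),
    model = "thermal",
    param = rep(c("base", "time_constant"), times = 20),
    value = c(rbind(rnorm(20, 3, 1), rnorm(20, 900, 100)))[1:40],
    stderr = runif(40), n_points = 18L, r_squared = runif(40),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_params_table(params, path)
  back <- read_params_table(path)
  expect_equal(nrow(back), 40)
  expect_equal(back$value, params$value, tolerance = 1e-12)
  expect_equal(back$r_squared, params$r_squared, tolerance = 1e-12)
  expect_identical(back$accession, params$accession)
  expect_error(write_params_table(params[0, ], tempfile()),
               class = "st_validation_error")
})

test_that("scoring tables round-trip through write and read", {
  dishes <- simulate_thermal(thermal_scenario(seed = 11))
  path <- tempfile(fileext = ".csv")
  write_scoring_table(dishes, path)
  back <- read_scoring_table(path)
  expect_length(back, length(dishes))
  ids <- vapply(back, `[[`, "", "dish_id")
  orig <- vapply(dishes, `[[`, "", "dish_id")
  for (k in seq_along(dishes))
    expect_equal(back[[which(ids == orig[k])]]$cum_counts,
                 dishes[[k]]$cum_counts)
})
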