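#' Construct a dish scoring time course
#'
#' One Petri dish's cumulative scoring series for one developmental stage
#' (radicle protrusion for `"germination"`, cotyledon opening for
#' `"seedling"`), together with the end-of-test viability accounting from the
#' cut test. Construction validates the dish: times strictly increasing,
#' cumulative counts non-decreasing and non-negative, and the accounting
#' identity `max(counts) + n_viable_ungerminated + n_dead == n_sown`.
#'
#' @param dish_id dish identifier (shared by the paired germination and
#'   seedling series of the same dish).
#' @param species,accession,region labels carried through to outputs.
#' @param stage `"germination"` or `"seedling"`.
#' @param treatment_kind `"temperature"` or `"osmoticum"`.
#' @param treatment_value treatment level: degrees Celsius or MPa.
#' @param times scoring times in hours, strictly increasing.
#' @param cum_counts cumulative counts of seeds past the stage at each time.
#' @param n_sown seeds sown in the dish.
#' @param n_viable_ungerminated seeds neither germinated nor dead at the end
#'   of the test (cut-test viable).
#' @param n_dead cut-test dead seeds.
#' @param replicate replicate-experiment index (one dish per treatment per
#'   replicate experiment).
#' @return An object of class `dish_time_course`.
#' @export
dish_time_course <- function(dish_id, species, accession, region,
                             stage = c("germination", "seedling"),
                             treatment_kind = c("temperature", "osmoticum"),
                             treatment_value, times, cum_counts,
                             n_sown, n_viable_ungerminated, n_dead,
                             replicate = 1L) {
  stage <- match.arg(stage)
  treatment_kind <- match.arg(treatment_kind)
  d <- structure(list(
    dish_id = as.character(dish_id), species = as.character(species),
    accession = as.character(accession), region = as.character(region),
    stage = stage, treatment_kind = treatment_kind,
    treatment_value = as.numeric(treatment_value),
    times = as.numeric(times), cum_counts = as.numeric(cum_counts),
    n_sown = as.integer(n_sown),
    n_viable_ungerminated = as.integer(n_viable_ungerminated),
    n_dead = as.integer(n_dead), replicate = as.integer(replicate)
  ), class = "dish_time_course")
  validate_dish(d)
}

validate_dish <- function(d) {
  id <- d$dish_id
  if (length(d$times) != length(d$cum_counts))
    st_stop("st_validation_error",
            sprintf("dish %s: times and counts differ in length", id))
  if (length(d$times) == 0)
    st_stop("st_validation_error", sprintf("dish %s: empty time course", id))
  if (any(diff(d$times) <= 0))
    st_stop("st_validation_error",
            sprintf("dish %s: scoring times must be strictly increasing", id))
  if (any(d$cum_counts < 0))
    st_stop("st_validation_error",
            sprintf("dish %s: negative cumulative count", id))
  if (any(diff(d$cum_counts) < 0))
    st_stop("st_validation_error",
            sprintf("dish %s: cumulative counts decrease", id))
  if (!is_count(d$n_sown) || !is_count(d$n_viable_ungerminated) ||
      !is_count(d$n_dead))
    st_stop("st_validation_error",
            sprintf("dish %s: seed totals must be non-negative integers", id))
  if (d$stage == "germination" &&
      max(d$cum_counts) + d$n_viable_ungerminated + d$n_dead != d$n_sown)
    st_stop("st_validation_error", sprintf(
      "dish %s: accounting identity violated (%d germinated + %d viable + %d dead != %d sown)",
      id, max(d$cum_counts), d$n_viable_ungerminated, d$n_dead, d$n_sown))
  d
}

#' @export
print.dish_time_course <- function(x, ...) {
  cat(sprintf("<dish_time_course> %s  %s/%s  stage=%s  %s=%g\n",
              x$dish_id, x$species, x$accession, x$stage,
              if (x$treatment_kind == "temperature") "T (C)" else "psi (MPa)",
              x$treatment_value))
  cat(sprintf("  %d scorings over %g-%g h; final %d of %d sown (%d viable ungerminated, %d dead)\n",
              length(x$times), min(x$times), max(x$times),
              max(x$cum_counts), x$n_sown, x$n_viable_ungerminated, x$n_dead))
  invisible(x)
}

scoring_columns <- c("dish_id", "species", "accession", "region", "replicate",
                     "stage", "treatment_kind", "treatment_value", "time_h",
                     "cum_count", "n_sown", "n_viable_ungerminated", "n_dead")

#' Read a dish scoring table
#'
#' Reads a tidy CSV with one row per dish per observation time and returns a
#' validated list of [dish_time_course()] objects, one per (dish, stage). The
#' expected columns are documented in the schema file shipped at
#' `system.file("extdata", "scoring_schema.csv", package = "seedthresholds")`.
#'
#' @param path path to the CSV file.
#' @param counts `"cumulative"` (the canonical on-disk representation) or
#'   `"interval"`, in which case per-interval counts are cumulated on read.
#' @param time_unit unit of the `time_h` column; `"days"` values are
#'   converted to hours.
#' @return A list of `dish_time_course` objects.
#' @export
read_scoring_table <- function(path, counts = c("cumulative", "interval"),
                               time_unit = c("hours", "days")) {
  counts <- match.arg(counts)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path))
    st_stop("st_io_error", sprintf("scoring table not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(scoring_columns, "replicate"), names(df))
  if (length(missing))
    st_stop("st_schema_error",
            sprintf("scoring table %s lacks required columns: %s",
                    path, paste(missing, collapse = ", ")))
  if (is.null(df$replicate)) df$replicate <- 1L
  if (time_unit == "days") df$time_h <- df$time_h * 24
  key <- interaction(df$dish_id, df$stage, drop = TRUE)
  dishes <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    cc <- if (counts == "interval") cumsum(g$cum_count) else g$cum_count
    for (col in c("species", "accession", "region", "stage", "treatment_kind",
                  "treatment_value", "n_sown", "n_viable_ungerminated",
                  "n_dead", "replicate"))
      if (length(unique(g[[col]])) != 1L)
        st_stop("st_validation_error", sprintf(
          "dish %s (%s): column %s varies within one dish series",
          g$dish_id[1], g$stage[1], col))
    dish_time_course(g$dish_id[1], g$species[1], g$accession[1], g$region[1],
                     g$stage[1], g$treatment_kind[1], g$treatment_value[1],
                     g$time_h, cc, g$n_sown[1], g$n_viable_ungerminated[1],
                     g$n_dead[1], g$replicate[1])
  })
  names(dishes) <- NULL
  dishes
}

#' Write dishes back to the scoring CSV schema
#'
#' @param dishes list of [dish_time_course()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scoring_table <- function(dishes, path) {
  if (length(dishes) == 0)
    st_stop("st_validation_error", "no dishes to write")
  rows <- lapply(dishes, function(d) data.frame(
    dish_id = d$dish_id, species = d$species, accession = d$accession,
    region = d$region, replicate = d$replicate, stage = d$stage,
    treatment_kind = d$treatment_kind, treatment_value = d$treatment_value,
    time_h = d$times, cum_count = d$cum_counts, n_sown = d$n_sown,
    n_viable_ungerminated = d$n_viable_ungerminated, n_dead = d$n_dead,
    stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  ok <- try(write.csv(df, path, row.names = FALSE, quote = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    st_stop("st_io_error", sprintf("cannot write scoring table to %s", path))
  invisible(path)
}

#' Viable-seed percentage basis for one dish
#'
#' Percentages are computed over viable seeds only: germinated seeds plus
#' ungerminated seeds found alive at the cut test. Dead seeds are excluded
#' from the denominator. The seedling conversion is expressed as a
#' percentage of all germinated seeds.
#'
#' @param dish a germination-stage [dish_time_course()].
#' @param seedling_final final count of normal seedlings from the paired
#'   seedling series (optional).
#' @return A list of class `viable_basis`: `n_viable`, `pct_germination`
#'   (percent of viable seeds), and `pct_seedlings_of_germinated` (percent of
#'   germinated seeds; `NA` when `seedling_final` is not given).
#' @examples
#' d <- dish_time_course("d1", "sp", "a1", "r", "germination", "temperature",
#'                       20, times = c(24, 48, 72), cum_counts = c(10, 30, 40),
#'                       n_sown = 50, n_viable_ungerminated = 5, n_dead = 5)
#' viable_basis(d, seedling_final = 30)  # 88.9% germination, 75% conversion
#' @export
viable_basis <- function(dish, seedling_final = NULL) {
  stopifnot(inherits(dish, "dish_time_course"))
  final_germ <- max(dish$cum_counts)
  n_viable <- final_germ + dish$n_viable_ungerminated
  if (n_viable == 0)
    st_stop("st_no_viable_seed",
            sprintf("dish %s: no viable seed (all dead)", dish$dish_id))
  pct_seedlings <- NA_real_
  if (!is.null(seedling_final)) {
    if (final_germ == 0 && seedling_final > 0)
      st_stop("st_inconsistency", sprintf(
        "dish %s: %d seedlings recorded but no germinated seed",
        dish$dish_id, seedling_final))
    if (seedling_final > final_germ)
      st_stop("st_inconsistency", sprintf(
        "dish %s: more seedlings (%d) than germinated seeds (%d)",
        dish$dish_id, seedling_final, final_germ))
    pct_seedlings <- if (final_germ > 0) 100 * seedling_final / final_germ
                     else NA_real_
  }
  structure(list(n_viable = n_viable,
                 pct_germination = 100 * final_germ / n_viable,
                 pct_seedlings_of_germinated = pct_seedlings),
            class = "viable_basis")
}

#' @export
print.viable_basis <- function(x, ...) {
  cat(sprintf("<viable_basis> %d viable seeds; germination %.1f%%",
              x$n_viable, x$pct_germination))
  if (!is.na(x$pct_seedlings_of_germinated))
    cat(sprintf("; seedling conversion %.1f%% of germinated",
                x$pct_seedlings_of_germinated))
  cat("\n")
  invisible(x)
}

params_columns <- c("accession", "species", "stage", "model", "param",
                    "value", "stderr", "n_points", "r_squared")

#' Write threshold parameters to a long-format CSV
#'
#' One row per accession x stage x model x parameter, with columns
#' `accession, species, stage, model, param, value, stderr, n_points,
#' r_squared`. Values are written at full double precision so that
#' [read_params_table()] round-trips losslessly.
#'
#' @param params a data frame in the long schema above (as produced by
#'   [threshold_params_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_params_table <- function(params, path) {
  if (!is.data.frame(params) || nrow(params) == 0)
    st_stop("st_validation_error", "empty parameter collection")
  missing <- setdiff(params_columns, names(params))
  if (length(missing))
    st_stop("st_schema_error", sprintf("parameter table lacks columns: %s",
                                       paste(missing, collapse = ", ")))
  out <- params[params_columns]
  for (col in c("value", "stderr", "r_squared"))
    out[[col]] <- vapply(out[[col]], function(v)
      if (is.na(v)) "NA" else sprintf("%.17g", v), "")
  ok <- try(write.csv(out, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    st_stop("st_io_error", sprintf("cannot write parameter table to %s", path))
  invisible(path)
}

#' Read a threshold parameter table written by [write_params_table()]
#'
#' @param path CSV path.
#' @return A data frame in the long parameter schema.
#' @export
read_params_table <- function(path) {
  if (!file.exists(path))
    st_stop("st_io_error", sprintf("parameter table not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(params_columns, names(df))
  if (length(missing))
    st_stop("st_schema_error", sprintf("parameter table lacks columns: %s",
                                       paste(missing, collapse = ", ")))
  for (col in c("value", "stderr", "r_squared"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
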