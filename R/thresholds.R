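new_threshold_fit <- function(model, x, y, used, lmfit, stage = NA_character_,
                              accession = NA_character_,
                              species = NA_character_) {
  co <- coef(lmfit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  if (!is.finite(slope) || slope <= 0)
    st_stop("st_non_positive_slope", sprintf(
      "%s rate regression slope is not positive (%.3g): no threshold can be extrapolated",
      model, slope))
  sm <- suppressWarnings(summary(lmfit))
  structure(list(
    model = model, base = -intercept / slope, time_constant = 1 / slope,
    slope = slope, intercept = intercept,
    base_se = threshold_base_se(lmfit),
    r_squared = sm$r.squared, n_points = length(x),
    treatments_used = sort(unique(used)),
    stage = stage, accession = accession, species = species,
    lm = lmfit, x = x, y = y
  ), class = "threshold_fit")
}

# delta-method standard error of -intercept/slope
threshold_base_se <- function(lmfit) {
  co <- coef(lmfit); V <- suppressWarnings(stats::vcov(lmfit))
  if (nrow(V) < 2 || any(!is.finite(V))) return(NA_real_)
  b <- co[1]; a <- co[2]
  g <- c(-1 / a, b / a^2)
  sqrt(drop(t(g) %*% V %*% g))
}

#' Base temperature and thermal time from rate-temperature pairs
#'
#' Ordinary least squares of germination (or seedling) rate on temperature
#' over the sub-optimal range: `rate = a T + b`. The base temperature is the
#' temperature at which the regression extrapolates to zero rate,
#' `Tb = -b/a`, and the thermal time is the reciprocal slope,
#' `theta_T = 1/a` (degree-hours).
#'
#' The sub-optimal range defaults to all temperatures up to and including
#' the temperature of maximum mean rate, accommodating both species with a
#' rate peak inside the tested range and species whose rate still rises at
#' the warmest tested temperature; `suboptimal_max` overrides it.
#'
#' @param temperature temperatures, degrees Celsius.
#' @param rate rates in reciprocal hours (non-negative; `NA` dropped).
#' @param suboptimal_max optional upper temperature bound of the regression.
#' @param stage,accession,species optional labels carried into outputs.
#' @return An object of class `threshold_fit` with `base` (Tb, C),
#'   `time_constant` (theta_T, C h), `slope`, `intercept`, `r_squared`,
#'   `n_points`, `treatments_used`. Methods: `print`, `coef`, `summary`,
#'   `predict`.
#' @examples
#' fit_thermal(c(10, 15, 20), c(0.08, 0.13, 0.18))  # Tb = 2 C, theta = 100 C h
#' @export
fit_thermal <- function(temperature, rate, suboptimal_max = NULL,
                        stage = NA_character_, accession = NA_character_,
                        species = NA_character_) {
  ok <- is.finite(temperature) & is.finite(rate)
  temperature <- temperature[ok]; rate <- rate[ok]
  if (any(rate < 0))
    st_stop("st_validation_error", "rates must be non-negative")
  if (is.null(suboptimal_max)) {
    mean_rate <- tapply(rate, temperature, mean)
    # warmest temperature attaining the maximum mean rate (ties included)
    peak <- mean_rate >= max(mean_rate) - 1e-12
    suboptimal_max <- max(as.numeric(names(mean_rate)[peak]))
  }
  sel <- temperature <= suboptimal_max + 1e-9
  x <- temperature[sel]; y <- rate[sel]
  if (length(unique(x)) < 3)
    st_stop("st_insufficient_data",
            "need rates at >= 3 distinct sub-optimal temperatures")
  new_threshold_fit("thermal", x, y, x, lm(y ~ x), stage, accession, species)
}

#' Base water potential and hydrotime from rate-potential pairs
#'
#' Ordinary least squares of rate on water potential, `rate = a psi + b`,
#' over osmoticum treatments with germination. The base water potential is
#' `psi_b = -b/a` (MPa) and the hydrotime the reciprocal slope,
#' `theta_H = 1/a` (MPa hours). Zero rates are censoring artifacts (no seed
#' crossed the stage within the test), not model points, and are dropped.
#'
#' @param psi water potentials, MPa (non-positive).
#' @param rate rates in reciprocal hours; zeros and `NA` dropped.
#' @inheritParams fit_thermal
#' @return A `threshold_fit` with `model = "hydro"`.
#' @examples
#' fit_hydro(c(0, -0.2, -0.4), c(0.02, 0.016, 0.012))  # psi_b = -1, theta = 50
#' @export
fit_hydro <- function(psi, rate, stage = NA_character_,
                      accession = NA_character_, species = NA_character_) {
  ok <- is.finite(psi) & is.finite(rate) & rate > 0
  x <- psi[ok]; y <- rate[ok]
  if (length(unique(x)) < 3)
    st_stop("st_insufficient_data",
            "need nonzero rates at >= 3 distinct water potentials")
  new_threshold_fit("hydro", x, y, x, lm(y ~ x), stage, accession, species)
}

#' @export
print.threshold_fit <- function(x, ...) {
  unit <- if (x$model == "thermal") c("C", "C h") else c("MPa", "MPa h")
  lab <- if (x$model == "thermal") c("Tb", "theta_T") else c("psi_b", "theta_H")
  cat(sprintf("<threshold_fit: %s%s>\n", x$model,
              if (is.na(x$stage)) "" else paste0(", stage ", x$stage)))
  cat(sprintf("  %s = %.4g %s (se %.3g); %s = %.4g %s\n",
              lab[1], x$base, unit[1], x$base_se, lab[2], x$time_constant,
              unit[2]))
  cat(sprintf("  rate = %.4g + %.4g x; R^2 = %.3f; n = %d (treatments: %s)\n",
              x$intercept, x$slope, x$r_squared, x$n_points,
              paste(x$treatments_used, collapse = ", ")))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(base = object$base, time_constant = object$time_constant,
    slope = object$slope, intercept = object$intercept)
}

#' @export
summary.threshold_fit <- function(object, ...) summary(object$lm, ...)

#' @export
predict.threshold_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' Optimum temperature from final percentages
#'
#' Fits a concave quadratic `y = a T^2 + b T + c` to final germination (or
#' seedling) percentages on the viable-seed basis and returns its vertex
#' `-b/(2a)`, the temperature maximising the percentage. A vertex outside
#' the tested range is clamped to the nearest tested boundary and flagged.
#'
#' @param temperature tested temperatures, degrees Celsius (>= 3 distinct).
#' @param percent final percentages (0-100, viable basis).
#' @return An object of class `optimum_fit`: `optimum` (C), `clamped`
#'   (logical), `coefficients`, `r_squared`, `n_points`.
#' @examples
#' optimum_temperature(seq(5, 25, 5), c(40, 77.5, 90, 77.5, 40))  # 15 C
#' @export
optimum_temperature <- function(temperature, percent) {
  ok <- is.finite(temperature) & is.finite(percent)
  x <- temperature[ok]; y <- percent[ok]
  if (length(unique(x)) < 3)
    st_stop("st_insufficient_data", "need >= 3 distinct temperatures")
  fit <- lm(y ~ x + I(x^2))
  co <- coef(fit)
  a <- unname(co[3]); b <- unname(co[2])
  if (!is.finite(a) || a >= 0)
    st_stop("st_concave_up",
            "quadratic is not concave: no interior optimum exists")
  vertex <- -b / (2 * a)
  clamped <- FALSE
  if (vertex < min(x) || vertex > max(x)) {
    clamped <- TRUE
    st_warn("st_boundary_optimum", sprintf(
      "fitted optimum %.2f C lies outside the tested range [%g, %g]; clamped",
      vertex, min(x), max(x)))
    vertex <- min(max(vertex, min(x)), max(x))
  }
  structure(list(optimum = vertex, clamped = clamped,
                 coefficients = c(c = unname(co[1]), b = b, a = a),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n_points = length(x)),
            class = "optimum_fit")
}

#' @export
print.optimum_fit <- function(x, ...) {
  cat(sprintf("<optimum_fit> To = %.3g C%s; y = %.3g %+.3g T %+.3g T^2; R^2 = %.3f; n = %d\n",
              x$optimum, if (x$clamped) " (clamped to tested range)" else "",
              x$coefficients["c"], x$coefficients["b"], x$coefficients["a"],
              x$r_squared, x$n_points))
  invisible(x)
}

#' Linear regression of one accession-level trait on another
#'
#' Germination-stage vs seedling-stage comparisons (e.g. Tb_G against Tb_S)
#' on accession means: ordinary least squares slope and intercept plus the
#' ties-adjusted Spearman correlation with its exact small-sample p-value.
#'
#' @param table a [trait_table()].
#' @param x_trait,y_trait trait column names.
#' @param ... passed to [spearman()] (e.g. `exact_n_max`, `seed`).
#' @return An object of class `stage_regression`: `slope`, `intercept`,
#'   `rho`, `p`, `n`, trait names.
#' @export
stage_regression <- function(table, x_trait, y_trait, ...) {
  stopifnot(inherits(table, "trait_table"))
  if (!all(c(x_trait, y_trait) %in% names(table)))
    st_stop("st_validation_error", "trait not present in table")
  x <- table[[x_trait]]; y <- table[[y_trait]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    st_stop("st_insufficient_data", "need >= 3 accessions with both traits")
  if (stats::sd(x) == 0)
    st_stop("st_degenerate_regression", sprintf("trait %s is constant", x_trait))
  co <- coef(lm(y ~ x))
  sp <- spearman(x, y, ...)
  structure(list(x_trait = x_trait, y_trait = y_trait,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 rho = sp$rho, p = sp$p, n = length(x)),
            class = "stage_regression")
}

#' @export
print.stage_regression <- function(x, ...) {
  cat(sprintf("<stage_regression> %s ~ %s: slope %.4g, intercept %.4g (n = %d)\n",
              x$y_trait, x$x_trait, x$slope, x$intercept, x$n))
  cat(sprintf("  Spearman rho = %.3f, p = %.4g\n", x$rho, x$p))
  invisible(x)
}
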