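#' Fit a Boltzmann sigmoid to a cumulative germination time course
#'
#' Least-squares fit of
#' \deqn{f(t) = A_2 + \frac{A_1 - A_2}{1 + e^{(t - x_0)/d_x}}}{f(t) = A2 + (A1 - A2)/(1 + exp((t - x0)/dx))}
#' to a cumulative fraction series (fractions of viable seeds for a
#' germination course; fractions of germinated seeds for a seedling course).
#' `x0` is the curve midpoint (hours) and `dx` the steepness scale (hours).
#' By default the lower asymptote is fixed at `A1 = 0` (nothing has
#' germinated at sowing), which stabilises shallow curves; `fix_A1 = FALSE`
#' frees it.
#'
#' t50 -- the time to 50% germination whose reciprocal is the germination
#' (or seedling) rate -- is taken, by default, as the time at which the
#' *fitted curve* crosses `t50_fraction` (0.5) of the normalising population,
#' i.e. the population-percentile definition used by thermal-time and
#' hydrotime theory. When the fitted plateau `A2` does not reach
#' `t50_fraction` the percentile is never attained and `t50` is `NA` (such
#' treatments drop out of rate regressions). `t50_basis = "midpoint"`
#' instead returns the curve's own midpoint `x0` (half of the dish's final
#' plateau) regardless of the plateau height; this estimates the median of
#' the germinating subpopulation and is biased for threshold extrapolation
#' whenever part of the population never germinates.
#'
#' @param times scoring times, hours.
#' @param cum_fraction cumulative fractions in `[0, 1]`, same length.
#' @param fix_A1 fix the lower asymptote at zero (default `TRUE`).
#' @param t50_basis `"fraction"` (population percentile, default) or
#'   `"midpoint"` (`x0`).
#' @param t50_fraction the population fraction defining t50 (default 0.5).
#' @param min_final_fraction minimum final fraction below which the dish is
#'   treated as non-germinating and a `st_no_germination` error is raised
#'   (default 0.10).
#' @param restarts number of deterministic perturbed restarts tried when the
#'   optimizer fails or stalls (default 5).
#' @return An object of class `boltzmann_fit` with components `A1`, `A2`,
#'   `x0`, `dx`, `t50`, `rate` (`1/t50`), `rss`, `n_obs`, `converged`, plus
#'   the data. Methods: `print`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' t <- seq(12, 400, by = 12)
#' f <- 0.9 / (1 + exp((100 - t) / 10))
#' fit <- fit_boltzmann(t, f)
#' coef(fit); fit$t50
#' @export
fit_boltzmann <- function(times, cum_fraction, fix_A1 = TRUE,
                          t50_basis = c("fraction", "midpoint"),
                          t50_fraction = 0.5, min_final_fraction = 0.10,
                          restarts = 5) {
  t50_basis <- match.arg(t50_basis)
  if (length(times) != length(cum_fraction))
    st_stop("st_validation_error", "times and fractions differ in length")
  if (length(times) < 4)
    st_stop("st_insufficient_data", "need at least 4 observations")
  if (any(cum_fraction < -1e-9 | cum_fraction > 1 + 1e-9))
    st_stop("st_validation_error", "cumulative fractions must lie in [0, 1]")
  final <- cum_fraction[length(cum_fraction)]
  if (final < min_final_fraction)
    st_stop("st_no_germination",
            sprintf("final fraction %.3f below threshold %.2f",
                    final, min_final_fraction))

  start <- boltzmann_start(times, cum_fraction)
  lower <- c(A2 = 1e-6, x0 = 0, dx = 1e-3)
  upper <- c(A2 = 1.05, x0 = 50 * max(times), dx = 100 * max(times))
  if (!fix_A1) {
    lower <- c(A1 = 0, lower); upper <- c(A1 = 0.5, upper)
    start <- c(A1 = min(cum_fraction), start)
  }
  form <- if (fix_A1)
    cum_fraction ~ A2 / (1 + exp((x0 - times) / dx))
  else
    cum_fraction ~ A2 + (A1 - A2) / (1 + exp((times - x0) / dx))
  dat <- data.frame(times = times, cum_fraction = cum_fraction)

  # deterministic multiplicative perturbations of (x0, dx) for restarts
  jit <- rbind(c(1, 1), c(0.8, 1.5), c(1.2, 0.6), c(0.6, 2.5),
               c(1.5, 0.4), c(1, 4))
  best <- NULL
  for (k in seq_len(min(restarts + 1L, nrow(jit)))) {
    st <- start
    st["x0"] <- start[["x0"]] * jit[k, 1]
    st["dx"] <- start[["dx"]] * jit[k, 2]
    fit <- try(minpack.lm::nlsLM(
      form, data = dat, start = as.list(st),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss,
                   converged = fit$convInfo$isConv %||% TRUE)
    if (!is.null(best) && best$converged && k == 1) break
  }
  if (is.null(best))
    st_stop("st_fit_failure", "Boltzmann fit failed after restarts",
            start = start)

  co <- coef(best$fit)
  A1 <- if (fix_A1) 0 else unname(co["A1"])
  A2 <- unname(co["A2"]); x0 <- unname(co["x0"]); dx <- unname(co["dx"])
  t50 <- boltzmann_t50(A1, A2, x0, dx, t50_basis, t50_fraction)
  structure(list(
    A1 = A1, A2 = A2, x0 = x0, dx = dx,
    t50 = t50, rate = if (is.na(t50)) NA_real_ else 1 / t50,
    rss = best$rss, n_obs = length(times), converged = isTRUE(best$converged),
    t50_basis = t50_basis, t50_fraction = t50_fraction,
    times = times, cum_fraction = cum_fraction
  ), class = "boltzmann_fit")
}

# empirical-curve starting values: plateau, half-crossing, quartile spread
boltzmann_start <- function(times, f) {
  A2 <- max(f)
  cross <- function(level) {
    i <- which(f >= level)[1]
    if (is.na(i)) return(max(times))
    if (i == 1 || f[i] == f[i - 1]) return(times[i])
    approx(f[(i - 1):i], times[(i - 1):i], xout = level, ties = "ordered")$y
  }
  x0 <- cross(A2 / 2)
  dxe <- (cross(0.75 * A2) - cross(0.25 * A2)) / 2.2
  c(A2 = A2, x0 = max(x0, 1e-3), dx = max(dxe, diff(range(times)) / 50))
}

boltzmann_t50 <- function(A1, A2, x0, dx, basis, frac) {
  if (basis == "midpoint") return(x0)
  # time at which the fitted curve reaches `frac` of the population
  if (A2 <= frac || frac <= A1) return(NA_real_)
  x0 - dx * log((A2 - frac) / (frac - A1))
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> A1=%.3g A2=%.3g x0=%.4g h dx=%.3g h\n",
              x$A1, x$A2, x$x0, x$dx))
  cat(sprintf("  t50 (%s basis) = %s h; rate = %s /h; rss = %.3g; n = %d; converged: %s\n",
              x$t50_basis,
              if (is.na(x$t50)) "NA (plateau below target fraction)"
              else sprintf("%.4g", x$t50),
              if (is.na(x$rate)) "NA" else sprintf("%.4g", x$rate),
              x$rss, x$n_obs, x$converged))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(A1 = object$A1, A2 = object$A2, x0 = object$x0, dx = object$dx)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.data.frame(newdata)) newdata$times else newdata
  with(object, A2 + (A1 - A2) / (1 + exp((t - x0) / dx)))
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$cum_fraction - predict(object)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  plot(x$times, x$cum_fraction, xlab = "time (h)",
       ylab = "cumulative fraction", ylim = c(0, 1), ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  if (!is.na(x$t50)) graphics::abline(v = x$t50, lty = 2)
  invisible(x)
}

#' Germination (or seedling) rate from t50
#'
#' @param t50 time to 50% germination, hours (positive).
#' @return The rate `1/t50` in reciprocal hours.
#' @export
rate_from_t50 <- function(t50) {
  if (!is.numeric(t50) || any(!is.finite(t50)) || any(t50 <= 0))
    st_stop("st_domain_error", "t50 must be a positive number of hours")
  1 / t50
}

#' t50 of seedling development from a paired dish
#'
#' Fits the Boltzmann model to the cotyledon-opening counts of a seedling
#' series normalised by the final germinated count of its paired germination
#' series, and returns the time until 50% of the germinated seeds have open
#' cotyledons.
#'
#' @param germ_dish germination-stage [dish_time_course()].
#' @param seedling_dish the paired seedling-stage series (same dish).
#' @param ... passed to [fit_boltzmann()].
#' @return t50 in hours (possibly `NA` when fewer than half of the
#'   germinated seeds ever convert under the default percentile basis).
#' @export
seedling_t50 <- function(germ_dish, seedling_dish, ...) {
  stopifnot(inherits(germ_dish, "dish_time_course"),
            inherits(seedling_dish, "dish_time_course"))
  final_germ <- max(germ_dish$cum_counts)
  if (final_germ == 0)
    st_stop("st_no_germination",
            sprintf("dish %s: no germinated seed", germ_dish$dish_id))
  if (max(seedling_dish$cum_counts) == 0)
    st_stop("st_no_seedlings",
            sprintf("dish %s: no seedlings", seedling_dish$dish_id))
  if (max(seedling_dish$cum_counts) > final_germ)
    st_stop("st_inconsistency",
            sprintf("dish %s: more seedlings than germinated seeds",
                    seedling_dish$dish_id))
  fit <- fit_boltzmann(seedling_dish$times,
                       seedling_dish$cum_counts / final_germ, ...)
  fit$t50
}
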