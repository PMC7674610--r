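#' Thermal-time simulation scenario
#'
#' Describes a population-threshold germination experiment across constant
#' temperatures: each viable, non-dormant seed carries its own thermal-time
#' requirement `theta_i` (lognormal with mean `theta_T` and spread
#' `sigma_theta`, in degree-hours) and germinates at
#' `t_i = theta_i / (T - T_b)` once the temperature exceeds the shared base
#' temperature. Defaults mirror the laboratory design the package targets:
#' 3 replicate dishes of 50 seeds per treatment, 5-30 C in 5 C steps,
#' twice-daily scoring for five weeks.
#'
#' @param T_b base temperature, C.
#' @param theta_T mean thermal time, C h.
#' @param sigma_theta between-seed thermal-time spread (lognormal scale
#'   parameterised by its standard deviation), C h.
#' @param temperatures treatment temperatures, C.
#' @param n_dishes replicate dishes (one per replicate experiment) per
#'   treatment.
#' @param n_seeds seeds sown per dish.
#' @param viability probability a sown seed is alive.
#' @param dormant_fraction probability a viable seed is dormant (never
#'   germinates, scored cut-test viable).
#' @param scoring_interval scoring grid, hours.
#' @param censor_time end of test, hours.
#' @param seed RNG seed making the simulation deterministic.
#' @return A validated list of class `thermal_scenario`.
#' @export
thermal_scenario <- function(T_b = 4, theta_T = 800,
                             sigma_theta = 0.15 * theta_T,
                             temperatures = seq(5, 30, by = 5),
                             n_dishes = 3, n_seeds = 50, viability = 0.95,
                             dormant_fraction = 0, scoring_interval = 12,
                             censor_time = 840, seed = 1) {
  s <- structure(list(T_b = T_b, theta_T = theta_T, sigma_theta = sigma_theta,
                      temperatures = temperatures, n_dishes = n_dishes,
                      n_seeds = n_seeds, viability = viability,
                      dormant_fraction = dormant_fraction,
                      scoring_interval = scoring_interval,
                      censor_time = censor_time, seed = seed),
                 class = "thermal_scenario")
  validate_scenario(s)
}

#' Hydrotime simulation scenario
#'
#' Population-threshold hydrotime experiment at one temperature across
#' osmoticum treatments: each seed draws its own base water potential
#' `psi_b_i ~ Normal(psi_b50, sigma_psi_b)` and germinates at
#' `t_i = theta_H / (psi - psi_b_i)` when the treatment potential exceeds
#' it; otherwise it stays viable-ungerminated. Each germinated seed then
#' converts to a normal seedling with probability
#' `seedling_conversion(psi)` after a fixed lag, scored on a coarser grid.
#' Defaults mirror 0 to -1 MPa in 0.2 MPa steps at 15 C, daily germination
#' scoring, seedling checks every 3 days.
#'
#' @param psi_b50 median base water potential, MPa.
#' @param sigma_psi_b between-seed spread of the base potential, MPa.
#' @param theta_H hydrotime constant, MPa h.
#' @param potentials treatment water potentials, MPa.
#' @param temperature incubation temperature, C (label only).
#' @param seedling_conversion function of psi returning the probability a
#'   germinated seed develops into a normal seedling.
#' @param seedling_lag germination-to-cotyledon lag, hours.
#' @param seedling_interval seedling scoring grid, hours.
#' @inheritParams thermal_scenario
#' @return A validated list of class `hydro_scenario`.
#' @export
hydro_scenario <- function(psi_b50 = -0.9, sigma_psi_b = 0.15, theta_H = 40,
                           potentials = seq(0, -1, by = -0.2),
                           temperature = 15, n_dishes = 3, n_seeds = 50,
                           viability = 0.95, dormant_fraction = 0,
                           scoring_interval = 24, censor_time = 840,
                           seedling_conversion = function(psi)
                             pmin(1, pmax(0, 0.9 + 0.5 * psi)),
                           seedling_lag = 120, seedling_interval = 72,
                           seed = 1) {
  s <- structure(list(psi_b50 = psi_b50, sigma_psi_b = sigma_psi_b,
                      theta_H = theta_H, potentials = potentials,
                      temperature = temperature, n_dishes = n_dishes,
                      n_seeds = n_seeds, viability = viability,
                      dormant_fraction = dormant_fraction,
                      scoring_interval = scoring_interval,
                      censor_time = censor_time,
                      seedling_conversion = seedling_conversion,
                      seedling_lag = seedling_lag,
                      seedling_interval = seedling_interval, seed = seed),
                 class = "hydro_scenario")
  validate_scenario(s)
}

validate_scenario <- function(s) {
  if (!is.null(s$theta_T) && s$theta_T <= 0)
    st_stop("st_domain_error", "theta_T must be positive")
  if (!is.null(s$theta_H) && s$theta_H <= 0)
    st_stop("st_domain_error", "theta_H must be positive")
  if (!is.null(s$sigma_theta) && s$sigma_theta < 0)
    st_stop("st_domain_error", "sigma_theta must be non-negative")
  if (!is.null(s$sigma_psi_b) && s$sigma_psi_b < 0)
    st_stop("st_domain_error", "sigma_psi_b must be non-negative")
  if (s$viability < 0 || s$viability > 1)
    st_stop("st_domain_error", "viability must lie in [0, 1]")
  if (s$dormant_fraction < 0 || s$dormant_fraction > 1)
    st_stop("st_domain_error", "dormant_fraction must lie in [0, 1]")
  if (s$censor_time < s$scoring_interval)
    st_stop("st_domain_error", "censor_time must cover one scoring interval")
  if (!is_count(s$n_dishes) || s$n_dishes < 1 ||
      !is_count(s$n_seeds) || s$n_seeds < 1)
    st_stop("st_domain_error", "n_dishes and n_seeds must be positive counts")
  s
}

# one dish: germination times (hours, Inf = never) -> dish_time_course
build_dish <- function(times_h, id, species, accession, region, stage,
                       kind, value, grid, n_sown, n_dead, n_viab_ungerm,
                       replicate) {
  cum <- vapply(grid, function(g) sum(times_h <= g), 0)
  dish_time_course(id, species, accession, region, stage, kind, value,
                   grid, cum, n_sown, n_viab_ungerm, n_dead, replicate)
}

#' Simulate germination dishes under the thermal-time threshold model
#'
#' @param s a [thermal_scenario()].
#' @param species,accession,region labels for the generated dishes.
#' @return A list of germination-stage [dish_time_course()] objects, one per
#'   temperature x dish, each satisfying the seed-accounting identity.
#'   Deterministic given the scenario seed. The generating parameters are
#'   attached as attribute `truth`.
#' @export
simulate_thermal <- function(s, species = "Synthetic sp.",
                             accession = "ACC01", region = "synthetic") {
  stopifnot(inherits(s, "thermal_scenario"))
  sdlog <- sqrt(log(1 + (s$sigma_theta / s$theta_T)^2))
  meanlog <- log(s$theta_T) - sdlog^2 / 2
  grid <- seq(s$scoring_interval, s$censor_time, by = s$scoring_interval)
  dishes <- with_seed(s$seed, {
    out <- list()
    for (temp in s$temperatures) for (d in seq_len(s$n_dishes)) {
      alive <- stats::runif(s$n_seeds) < s$viability
      n_dead <- sum(!alive)
      dormant <- alive & stats::runif(s$n_seeds) < s$dormant_fraction
      active <- sum(alive & !dormant)
      theta <- rlnorm(active, meanlog, sdlog)
      tt <- if (temp > s$T_b) theta / (temp - s$T_b) else rep(Inf, active)
      tt <- ceiling(tt / s$scoring_interval) * s$scoring_interval
      tt[tt > s$censor_time] <- Inf
      n_germ <- sum(is.finite(tt))
      id <- sprintf("%s_T%02d_R%d", accession, as.integer(round(temp)), d)
      out[[length(out) + 1L]] <- build_dish(
        tt, id, species, accession, region, "germination", "temperature",
        temp, grid, s$n_seeds, n_dead, s$n_seeds - n_dead - n_germ, d)
    }
    out
  })
  attr(dishes, "truth") <- list(T_b = s$T_b, theta_T = s$theta_T)
  dishes
}

#' Simulate germination and seedling dishes under the hydrotime model
#'
#' @param s a [hydro_scenario()].
#' @inheritParams simulate_thermal
#' @return A list of [dish_time_course()] objects: for every potential x
#'   dish a germination series and the paired seedling (cotyledon-opening)
#'   series sharing its `dish_id`. Deterministic given the scenario seed;
#'   generating parameters attached as attribute `truth`.
#' @export
simulate_hydro <- function(s, species = "Synthetic sp.", accession = "ACC01",
                           region = "synthetic") {
  stopifnot(inherits(s, "hydro_scenario"))
  grid <- seq(s$scoring_interval, s$censor_time, by = s$scoring_interval)
  sgrid <- seq(s$seedling_interval, s$censor_time, by = s$seedling_interval)
  dishes <- with_seed(s$seed, {
    out <- list()
    for (psi in s$potentials) for (d in seq_len(s$n_dishes)) {
      alive <- stats::runif(s$n_seeds) < s$viability
      n_dead <- sum(!alive)
      dormant <- alive & stats::runif(s$n_seeds) < s$dormant_fraction
      active <- sum(alive & !dormant)
      psi_b <- rnorm(active, s$psi_b50, s$sigma_psi_b)
      tt <- ifelse(psi > psi_b, s$theta_H / (psi - psi_b), Inf)
      tt <- ceiling(tt / s$scoring_interval) * s$scoring_interval
      tt[tt > s$censor_time] <- Inf
      germinated <- is.finite(tt)
      id <- sprintf("%s_W%03d_R%d", accession,
                    as.integer(round(-psi * 100)), d)
      out[[length(out) + 1L]] <- build_dish(
        tt, id, species, accession, region, "germination", "osmoticum",
        psi, grid, s$n_seeds, n_dead,
        s$n_seeds - n_dead - sum(germinated), d)
      conv <- germinated & stats::runif(length(tt)) < s$seedling_conversion(psi)
      st <- tt[conv] + s$seedling_lag
      st <- ceiling(st / s$seedling_interval) * s$seedling_interval
      st[st > s$censor_time] <- Inf
      out[[length(out) + 1L]] <- build_dish(
        st, id, species, accession, region, "seedling", "osmoticum",
        psi, sgrid, s$n_seeds, n_dead,
        s$n_seeds - n_dead - sum(germinated), d)
    }
    out
  })
  attr(dishes, "truth") <- list(psi_b50 = s$psi_b50, theta_H = s$theta_H)
  dishes
}

# plausible marginal scales for the default trait set
default_trait_marginals <- function() {
  list(
    Tb_G = c(2.5, 1), Tb_S = c(2.2, 1), thetaT_G = c(900, 200),
    thetaT_S = c(1400, 300), To_G = c(18, 3), To_S = c(18, 3),
    psib_G = c(-1.0, 0.15), psib_S = c(-0.75, 0.15),
    thetaH_G = c(45, 12), thetaH_S = c(80, 20), Sm = c(0.9, 0.25),
    AT = c(13, 3), T_min = c(3, 3), T_max = c(26, 3), AP = c(55, 15),
    WP = c(180, 50), SP = c(90, 40), AP_sum = c(650, 150),
    Alt = c(400, 300), Lat = c(45, 5), Long = c(0, 8))
}

#' Simulate an accession trait table with known correlation structure
#'
#' Gaussian-copula draw: latent standard normals with the requested
#' pairwise correlation matrix, scaled to plausible marginal means and
#' standard deviations per trait. With the default identity target all
#' traits are independent, giving a null table for type-I-error studies.
#'
#' @param n_accessions number of accessions (rows).
#' @param target_corr target correlation matrix (symmetric positive
#'   semi-definite, unit diagonal); default identity. Dimension must match
#'   the number of traits.
#' @param traits trait names; default the full [default_trait_classes()]
#'   set.
#' @param marginals named list of `c(mean, sd)` per trait.
#' @param classes trait class map for [trait_table()].
#' @param seed RNG seed.
#' @return A [trait_table()], deterministic given the seed.
#' @export
simulate_trait_table <- function(n_accessions = 10, target_corr = NULL,
                                 traits = names(default_trait_classes()),
                                 marginals = default_trait_marginals(),
                                 classes = default_trait_classes(),
                                 seed = 1) {
  k <- length(traits)
  if (is.null(target_corr)) target_corr <- diag(k)
  if (!is.matrix(target_corr) || nrow(target_corr) != k ||
      ncol(target_corr) != k || any(abs(target_corr - t(target_corr)) > 1e-8))
    st_stop("st_domain_error",
            sprintf("target_corr must be a symmetric %d x %d matrix", k, k))
  ev <- eigen(target_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    st_stop("st_domain_error",
            "target correlation matrix is not positive semi-definite")
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  z <- with_seed(seed, matrix(rnorm(n_accessions * k), n_accessions, k)) %*% root
  vals <- as.data.frame(sapply(seq_len(k), function(j) {
    m <- marginals[[traits[j]]] %||% c(0, 1)
    m[1] + m[2] * z[, j]
  }))
  names(vals) <- traits
  rownames(vals) <- sprintf("ACC%02d", seq_len(n_accessions))
  trait_table(vals, classes)
}
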