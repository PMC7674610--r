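#' Per-dish Boltzmann fits for a collection of dishes
#'
#' Fits every germination dish on the viable-seed fraction scale and every
#' seedling dish normalised by its paired germination dish's final
#' germinated count. Dishes whose final germination is below
#' `min_germination_fraction` of viable seeds (or whose fit fails) are
#' retained in the report with an `excluded_reason` instead of a rate, so
#' they still contribute to percentage outputs while dropping out of rate
#' regressions.
#'
#' @param dishes list of [dish_time_course()] objects (both stages mixed;
#'   seedling dishes are paired to germination dishes by `dish_id`).
#' @param min_germination_fraction exclusion threshold (default 0.10).
#' @param ... passed to [fit_boltzmann()] (e.g. `t50_basis`).
#' @return A data frame with one row per dish and stage: identifiers,
#'   treatment, `A2`, `x0`, `dx`, `t50_h`, `rate_per_h`, `rss`, `converged`,
#'   `pct_final` (viable basis for germination, percent of germinated for
#'   seedlings) and `excluded_reason` (`NA` when usable).
#' @export
fit_dishes <- function(dishes, min_germination_fraction = 0.10, ...) {
  stopifnot(length(dishes) > 0)
  germ <- dishes[vapply(dishes, function(d) d$stage == "germination", TRUE)]
  germ_ids <- vapply(germ, function(d) d$dish_id, "")
  rows <- lapply(dishes, function(d) {
    row <- data.frame(
      dish_id = d$dish_id, species = d$species, accession = d$accession,
      region = d$region, replicate = d$replicate, stage = d$stage,
      treatment_kind = d$treatment_kind, treatment_value = d$treatment_value,
      A2 = NA_real_, x0 = NA_real_, dx = NA_real_, t50_h = NA_real_,
      rate_per_h = NA_real_, rss = NA_real_, converged = NA,
      pct_final = NA_real_, excluded_reason = NA_character_,
      stringsAsFactors = FALSE)
    if (d$stage == "germination") {
      vb <- viable_basis(d)
      row$pct_final <- vb$pct_germination
      denom <- vb$n_viable
    } else {
      g <- germ[germ_ids == d$dish_id]
      if (length(g) == 0) {
        row$excluded_reason <- "no paired germination dish"
        return(row)
      }
      denom <- max(g[[1]]$cum_counts)
      if (denom == 0) {
        row$excluded_reason <- "no germinated seed in paired dish"
        return(row)
      }
      row$pct_final <- 100 * max(d$cum_counts) / denom
    }
    fit <- tryCatch(
      fit_boltzmann(d$times, d$cum_counts / denom,
                    min_final_fraction = min_germination_fraction, ...),
      st_no_germination = function(e) e, st_fit_failure = function(e) e,
      st_insufficient_data = function(e) e)
    if (inherits(fit, "condition")) {
      row$excluded_reason <- class(fit)[1]
      return(row)
    }
    row$A2 <- fit$A2; row$x0 <- fit$x0; row$dx <- fit$dx
    row$t50_h <- fit$t50; row$rate_per_h <- fit$rate
    row$rss <- fit$rss; row$converged <- fit$converged
    if (is.na(fit$t50)) row$excluded_reason <- "plateau below t50 fraction"
    row
  })
  do.call(rbind, rows)
}

#' Threshold parameters per accession and stage from dish fits
#'
#' The full inversion chain: per-dish rates from [fit_dishes()], then, for
#' each accession x stage, a rate regression per replicate experiment
#' ([fit_thermal()] on temperature treatments or [fit_hydro()] on osmoticum
#' treatments), plus the optimum temperature ([optimum_temperature()]) for
#' thermal series. Replicate-level estimates are averaged to accession
#' means; both levels are returned.
#'
#' @param dishes list of [dish_time_course()] objects.
#' @param model `"thermal"` or `"hydro"`; selected by treatment kind.
#' @param suboptimal_max passed to [fit_thermal()].
#' @param min_germination_fraction passed to [fit_dishes()].
#' @param ... passed on to [fit_boltzmann()] via [fit_dishes()].
#' @return A data frame with one row per accession x stage x level
#'   (`"replicate"` rows carry the replicate index; `"accession"` rows the
#'   mean over replicates): `base`, `time_constant`, `optimum` (thermal
#'   germination-level series only), `r_squared`, `n_points`.
#' @export
estimate_thresholds <- function(dishes, model = c("thermal", "hydro"),
                                suboptimal_max = NULL,
                                min_germination_fraction = 0.10, ...) {
  model <- match.arg(model)
  kind <- if (model == "thermal") "temperature" else "osmoticum"
  dishes <- dishes[vapply(dishes, function(d) d$treatment_kind == kind, TRUE)]
  if (length(dishes) == 0)
    st_stop("st_insufficient_data",
            sprintf("no dishes with %s treatments", kind))
  fits <- fit_dishes(dishes, min_germination_fraction, ...)

  out <- list()
  for (acc in unique(fits$accession)) {
    for (stg in unique(fits$stage[fits$accession == acc])) {
      sub <- fits[fits$accession == acc & fits$stage == stg, , drop = FALSE]
      spp <- sub$species[1]
      reps <- sort(unique(sub$replicate))
      rep_rows <- list()
      for (r in reps) {
        rsub <- sub[sub$replicate == r & is.na(sub$excluded_reason), ,
                    drop = FALSE]
        fit <- tryCatch({
          if (model == "thermal")
            fit_thermal(rsub$treatment_value, rsub$rate_per_h,
                        suboptimal_max = suboptimal_max, stage = stg,
                        accession = acc, species = spp)
          else
            fit_hydro(rsub$treatment_value, rsub$rate_per_h, stage = stg,
                      accession = acc, species = spp)
        }, seedthresholds_error = function(e) e)
        if (inherits(fit, "condition")) next
        opt <- NA_real_
        if (model == "thermal") {
          osub <- sub[sub$replicate == r, , drop = FALSE]
          oc <- tryCatch(
            suppressWarnings(
              optimum_temperature(osub$treatment_value, osub$pct_final)),
            seedthresholds_error = function(e) NULL)
          if (!is.null(oc)) opt <- oc$optimum
        }
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          accession = acc, species = spp, stage = stg, model = model,
          level = "replicate", replicate = r,
          base = fit$base, time_constant = fit$time_constant, optimum = opt,
          r_squared = fit$r_squared, n_points = fit$n_points,
          stringsAsFactors = FALSE)
      }
      if (length(rep_rows) == 0) next
      rep_df <- do.call(rbind, rep_rows)
      acc_row <- rep_df[1, , drop = FALSE]
      acc_row$level <- "accession"; acc_row$replicate <- NA_integer_
      for (col in c("base", "time_constant", "optimum", "r_squared"))
        acc_row[[col]] <- mean(rep_df[[col]], na.rm = TRUE)
      acc_row$n_points <- sum(rep_df$n_points)
      out[[length(out) + 1L]] <- rbind(rep_df, acc_row)
    }
  }
  if (length(out) == 0)
    st_stop("st_insufficient_data",
            "no accession yielded an estimable rate regression")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Long-format parameter table from threshold estimates
#'
#' Reshapes the accession-level rows of [estimate_thresholds()] output into
#' the long CSV schema of [write_params_table()].
#'
#' @param estimates data frame from [estimate_thresholds()].
#' @return A data frame with columns `accession, species, stage, model,
#'   param, value, stderr, n_points, r_squared`.
#' @export
threshold_params_table <- function(estimates) {
  acc <- estimates[estimates$level == "accession", , drop = FALSE]
  if (nrow(acc) == 0)
    st_stop("st_validation_error", "no accession-level estimates")
  rows <- list()
  for (i in seq_len(nrow(acc))) {
    e <- acc[i, ]
    params <- c(base = e$base, time_constant = e$time_constant)
    if (!is.na(e$optimum)) params <- c(params, optimum = e$optimum)
    for (p in names(params))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = e$accession, species = e$species, stage = e$stage,
        model = e$model, param = p, value = unname(params[p]),
        stderr = NA_real_, n_points = e$n_points, r_squared = e$r_squared,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
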