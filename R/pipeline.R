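#' Configuration for a full pipeline run
#'
#' A single configuration drives simulate -> fit -> correlate -> network.
#' One global seed fans out to per-stage seeds by fixed offsets, so a
#' configuration plus seed reproduces every artifact byte for byte. When
#' `scoring_csv` is supplied the simulation stage is skipped and the dishes
#' are read from file; likewise `trait_csv` replaces the trait-table draw.
#'
#' @param output_dir directory to create artifacts in (created if absent).
#' @param seed global integer seed.
#' @param alpha network significance threshold.
#' @param exact_n_max passed to [correlation_matrix()].
#' @param min_germination_fraction passed to [fit_dishes()].
#' @param suboptimal_max passed to [fit_thermal()] (NULL = automatic).
#' @param n_accessions accessions in the simulated trait table.
#' @param thermal,hydro scenario objects; `NULL` uses the defaults with
#'   derived seeds.
#' @param scoring_csv,trait_csv optional existing input files.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1, alpha = 0.05, exact_n_max = 10,
                       min_germination_fraction = 0.10,
                       suboptimal_max = NULL, n_accessions = 10,
                       thermal = NULL, hydro = NULL,
                       scoring_csv = NULL, trait_csv = NULL) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    st_stop("st_domain_error", "alpha must lie in (0, 1)")
  for (p in c(scoring_csv, trait_csv))
    if (!is.null(p) && !file.exists(p))
      st_stop("st_validation_error", sprintf("input path does not exist: %s", p))
  seed <- as.integer(seed)
  structure(list(
    output_dir = output_dir, seed = seed, alpha = alpha,
    exact_n_max = exact_n_max,
    min_germination_fraction = min_germination_fraction,
    suboptimal_max = suboptimal_max, n_accessions = n_accessions,
    thermal = thermal %||% thermal_scenario(seed = seed + 101L),
    hydro = hydro %||% hydro_scenario(seed = seed + 202L),
    scoring_csv = scoring_csv, trait_csv = trait_csv
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate thermal and hydrotime dish experiments (or read a
#' scoring CSV) and write the scoring table plus a sidecar JSON of the
#' generating parameters; (2) fit every dish and estimate threshold
#' parameters, writing the per-dish fit report and the long parameter
#' table; (3) draw (or read) the accession trait table and compute the
#' Spearman correlation matrices; (4) build the significance-filtered trait
#' network with Girvan-Newman communities and export it. A manifest JSON
#' listing every artifact with its MD5 checksum is written last; the same
#' configuration and seed reproduce identical checksums.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (class `pipeline_manifest`): artifact
#'   paths, checksums, seed and package version.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character()
  add <- function(p) artifacts <<- c(artifacts, p)

  # -- simulate ---------------------------------------------------------
  say("stage simulate")
  if (is.null(config$scoring_csv)) {
    th <- simulate_thermal(config$thermal)
    hy <- simulate_hydro(config$hydro)
    dishes <- c(th, hy)
    write_scoring_table(dishes, out("scoring.csv"))
    jsonlite::write_json(
      list(thermal = attr(th, "truth"), hydro = attr(hy, "truth")),
      out("true_params.json"), auto_unbox = TRUE, digits = NA)
    add(out("scoring.csv")); add(out("true_params.json"))
  } else {
    dishes <- read_scoring_table(config$scoring_csv)
  }

  # -- fit --------------------------------------------------------------
  say("stage fit")
  fits <- fit_dishes(dishes, config$min_germination_fraction)
  write.csv(fits, out("dish_fits.csv"), row.names = FALSE, quote = FALSE)
  add(out("dish_fits.csv"))
  est <- list()
  for (model in c("thermal", "hydro")) {
    kind <- if (model == "thermal") "temperature" else "osmoticum"
    if (!any(vapply(dishes, function(d) d$treatment_kind == kind, TRUE)))
      next
    est[[model]] <- estimate_thresholds(
      dishes, model = model, suboptimal_max = config$suboptimal_max,
      min_germination_fraction = config$min_germination_fraction)
  }
  params <- do.call(rbind, lapply(est, threshold_params_table))
  write_params_table(params, out("threshold_params.csv"))
  add(out("threshold_params.csv"))

  # -- correlate --------------------------------------------------------
  say("stage correlate")
  tt <- if (is.null(config$trait_csv))
    simulate_trait_table(config$n_accessions, seed = config$seed + 303L)
  else read_trait_table(config$trait_csv)
  if (is.null(config$trait_csv)) {
    df <- cbind(accession = rownames(tt), as.data.frame(tt))
    write.csv(df, out("trait_table.csv"), row.names = FALSE, quote = FALSE)
    add(out("trait_table.csv"))
  }
  cm <- correlation_matrix(tt, exact_n_max = config$exact_n_max,
                           seed = config$seed + 404L)
  write.csv(round(cm$rho, 10), out("correlation_rho.csv"), quote = FALSE)
  write.csv(round(cm$p, 10), out("correlation_p.csv"), quote = FALSE)
  add(out("correlation_rho.csv")); add(out("correlation_p.csv"))

  # -- network ----------------------------------------------------------
  say("stage network")
  net <- girvan_newman(build_network(cm, alpha = config$alpha))
  add(write_network(net, out("network")))

  manifest <- structure(list(
    package = "seedthresholds",
    version = as.character(utils::packageVersion("seedthresholds")),
    seed = config$seed,
    config_hash = config_hash(config),
    artifacts = data.frame(
      path = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stringsAsFactors = FALSE)
  ), class = "pipeline_manifest")
  jsonlite::write_json(unclass(manifest), out("manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_lines <- c(sprintf("seedthresholds %s", manifest$version),
                 sprintf("seed %d", config$seed),
                 sprintf("config %s", manifest$config_hash),
                 sprintf("artifact %s %s", manifest$artifacts$path,
                         manifest$artifacts$md5))
  writeLines(log_lines, out("run.log"))
  invisible(manifest)
}

# stable digest of the configuration (scenario functions deparsed)
config_hash <- function(config) {
  dump <- paste(deparse(config[setdiff(names(config), "output_dir")]),
                collapse = "\n")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(dump, f)
  unname(tools::md5sum(f))
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> seedthresholds %s, seed %d\n",
              x$version, x$seed))
  cat(sprintf("  %d artifacts:\n", nrow(x$artifacts)))
  for (i in seq_len(nrow(x$artifacts)))
    cat(sprintf("   %s  %s\n", x$artifacts$md5[i], x$artifacts$path[i]))
  invisible(x)
}
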