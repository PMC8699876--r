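#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end error-propagation run. A config
#' can also be read from / written to YAML.
#'
#' @param n_vessels number of synthetic vessels (default 20, the study set
#'   size; each yields an original/over/under triplet).
#' @param error geometric area-error fraction (default 0.05).
#' @param flows SmartFFR flow ramp, mL/s.
#' @param rest_flow flow used for the shear field, mL/s.
#' @param run_growth logical; include the plaque-growth stage.
#' @param u_recon reconstruction-level uncertainty entering the quadrature
#'   chain (default 0.09).
#' @param seed global seed fanned out to per-component child seeds.
#' @param growth a [growth_params()].
#' @param kk a [kk_params()].
#' @param cond base [flow_conditions()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_vessels = 20, error = 0.05,
                            flows = c(0, 1, 2, 3, 4), rest_flow = 1,
                            run_growth = TRUE, u_recon = 0.09, seed = 1L,
                            growth = growth_params(), kk = kk_params(),
                            cond = flow_conditions()) {
  stopifnot(n_vessels >= 1, error > 0, error < 1, u_recon >= 0)
  structure(list(n_vessels = n_vessels, error = error, flows = flows,
                 rest_flow = rest_flow, run_growth = run_growth,
                 u_recon = u_recon, seed = as.integer(seed), growth = growth,
                 kk = kk, cond = cond),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return A `pipeline_config` (read); `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("n_vessels", "error", "flows", "rest_flow",
                                  "run_growth", "u_recon", "seed"))]
  cfg <- do.call(pipeline_config, args)
  if (!is.null(y$growth)) cfg$growth <- do.call(growth_params, y$growth)
  if (!is.null(y$kk)) cfg$kk <- do.call(kk_params, y$kk)
  if (!is.null(y$cond)) cfg$cond <- do.call(flow_conditions, y$cond)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  flat <- config
  flat$growth <- unclass(config$growth)
  flat$kk <- unclass(config$kk)
  flat$cond <- unclass(config$cond)
  yaml::write_yaml(unclass(flat), path)
  invisible(path)
}

# order-insensitive content hash (djb2 over the serialized JSON)
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(txt))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full error-propagation pipeline
#'
#' For each synthetic vessel: build the original/over/under triplet, compute
#' the shear field at rest flow and the SmartFFR index for each model,
#' optionally run the plaque-growth simulation, and assemble the comparison
#' reports (per-vessel shear relative errors and quadrature uncertainties,
#' plus the SmartFFR triple table with paired statistics). Outputs are
#' written to `out_dir` together with a manifest carrying the config hash
#' and seed; re-running the same config reproduces the outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips file
#'   output and returns the results only.
#' @return List of class `pipeline_result`: `smartffr` (report tibble),
#'   `ess` (per-station hemodynamics tibble), `ess_re` (per-vessel relative
#'   errors and uncertainties), `smartffr_stats` (paired statistics),
#'   `growth` (per-vessel total plaque volume by tag, if run), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  vessels <- generate_vessel_set(config$n_vessels, seed = child_seed(config$seed, 1))
  cond_rest <- config$cond
  cond_rest$flow <- config$rest_flow
  ess_rows <- list()
  ess_re_rows <- list()
  growth_rows <- list()
  all_models <- list()
  for (v in vessels) {
    trip <- vessel_triplet(v, config$error)
    all_models <- c(all_models, unname(trip))
    tau <- lapply(trip, function(m) compute_ess(axial_profile(m), cond_rest)$tau_Pa)
    ess_rows[[v$case_id]] <- do.call(rbind, lapply(trip, hemodynamics_table,
                                                   cond = cond_rest))
    for (tag in c("overestimated", "underestimated")) {
      rep_row <- propagation_report(tau$original, tau[[tag]], u_prev = config$u_recon)
      ess_re_rows[[paste(v$case_id, tag)]] <-
        cbind(tibble::tibble(case_id = v$case_id, tag = tag), rep_row)
    }
    if (config$run_growth) {
      gr <- lapply(trip, run_growth, kk = config$kk, params = config$growth,
                   cond = cond_rest)
      growth_rows[[v$case_id]] <- tibble::tibble(
        case_id = v$case_id,
        tag = names(gr),
        plaque_volume_total = vapply(gr, function(g) g$plaque_volume_total, numeric(1)),
        status = vapply(gr, function(g) g$status, character(1))
      )
    }
  }
  sf <- smartffr_report(all_models, flows = config$flows, cond = config$cond)
  wide <- split(sf$smartffr, sf$tag)
  comp_over <- paired_comparison(wide$original, wide$overestimated)
  comp_under <- paired_comparison(wide$original, wide$underestimated)
  # correlation needs at least 3 vessels and nonzero spread
  safe_r <- function(x, y) {
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) NA_real_ else pearson_r(x, y)
  }
  sf_stats <- tibble::tibble(
    comparison = c("original_vs_overestimated", "original_vs_underestimated"),
    mean_diff = c(paired_stats(comp_over)$mean_diff, paired_stats(comp_under)$mean_diff),
    sd_diff = c(paired_stats(comp_over)$sd_diff, paired_stats(comp_under)$sd_diff),
    pearson_r = c(safe_r(wide$original, wide$overestimated),
                  safe_r(wide$original, wide$underestimated))
  )
  result <- structure(list(
    smartffr = sf,
    ess = do.call(rbind, ess_rows),
    ess_re = do.call(rbind, ess_re_rows),
    smartffr_stats = sf_stats,
    growth = if (length(growth_rows)) do.call(rbind, growth_rows) else NULL,
    manifest = list(package_version = as.character(utils::packageVersion("coroprop")),
                    config_hash = config_hash(config), seed = config$seed,
                    n_models = length(all_models))
  ), class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(result$smartffr, file.path(out_dir, "smartffr.csv"), row.names = FALSE)
    write.csv(result$ess, file.path(out_dir, "ess.csv"), row.names = FALSE)
    write.csv(result$ess_re, file.path(out_dir, "ess_relative_error.csv"),
              row.names = FALSE)
    write.csv(result$smartffr_stats, file.path(out_dir, "smartffr_stats.csv"),
              row.names = FALSE)
    if (!is.null(result$growth)) {
      write.csv(result$growth, file.path(out_dir, "plaque_growth.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
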