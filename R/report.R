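# Report surface: base-case results table and the command-style entry points
# used by the inst/scripts/zoster-cea wrapper. Every command is a pure
# function of (config, flags, seed) and writes CSVs plus a JSON run manifest.

#' Base-case results table
#'
#' One row per (vaccination age, strategy) with lifetime per-1000 cases, PHN
#' cases, discounted costs and QALYs, and incremental results versus no
#' vaccination — the standard base-case reporting layout.
#'
#' @param params A `zoster_params`.
#' @param ages Vaccination ages.
#' @return A data.frame (strategies ordered no-vaccination, ZVL, RZV within
#'   each age).
#' @export
basecase_table <- function(params, ages = c(50, 60, 70, 80)) {
  as.data.frame(zoster_cea(params, ages = ages))
}

.write_manifest <- function(out_dir, command, config, seed, outputs) {
  manifest <- list(
    command = command,
    config = as.character(config),
    seed = if (is.null(seed)) NA else seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("zostercea")),
    output_dir = out_dir,
    outputs = outputs
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.prepare_out_dir <- function(out_dir, files, force) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  existing <- files[file.exists(file.path(out_dir, files))]
  if (length(existing) && !force) {
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(existing, collapse = ", "), call. = FALSE)
  }
  invisible(out_dir)
}

#' Base-case analysis command
#'
#' Loads a config, runs the three strategies at each requested age, and
#' writes `basecase.csv` plus a `manifest.json` listing every output.
#' Deterministic: the same config yields byte-identical CSVs.
#'
#' @param config Path to a YAML/JSON parameter config.
#' @param ages Vaccination ages.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the path to the written CSV.
#' @export
cli_basecase <- function(config, ages = c(50, 60, 70, 80), out_dir = ".",
                         force = FALSE, quiet = FALSE) {
  params <- load_parameters(config)
  .prepare_out_dir(out_dir, "basecase.csv", force)
  if (!quiet) message("running base case for ages ",
                      paste(ages, collapse = ", "))
  tab <- basecase_table(params, ages)
  path <- file.path(out_dir, "basecase.csv")
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  .write_manifest(out_dir, "basecase", config, NULL, "basecase.csv")
  invisible(path)
}

#' Sensitivity analysis command
#'
#' Dispatches to the sensitivity suite and writes mode-specific CSVs plus a
#' manifest: `tornado.csv` (one-way entries sorted by bar width), `psa.csv` +
#' `ceac.csv`, `compliance.csv`, or `threshold.csv` (one row per age band).
#'
#' @inheritParams cli_basecase
#' @param mode One of `"tornado"`, `"psa"`, `"compliance"`, `"threshold"`.
#' @param seed Integer seed (required for `mode = "psa"`).
#' @param n_draws PSA draws.
#' @param ages Vaccination ages (tornado uses the first).
#' @param rates Compliance rates for `mode = "compliance"`.
#' @return Invisibly, the paths to the written CSVs.
#' @export
cli_sensitivity <- function(config, mode = c("tornado", "psa", "compliance",
                                             "threshold"),
                            seed = NULL, n_draws = 10000,
                            ages = c(50, 60, 70, 80),
                            rates = seq(0.2, 1, by = 0.2), out_dir = ".",
                            force = FALSE, quiet = FALSE) {
  mode <- match.arg(mode)
  params <- load_parameters(config)
  t0 <- Sys.time()
  paths <- switch(
    mode,
    tornado = {
      .prepare_out_dir(out_dir, "tornado.csv", force)
      tor <- one_way_tornado(params, "RZV", start_age = ages[1])
      p <- file.path(out_dir, "tornado.csv")
      utils::write.csv(as.data.frame(tor), p, row.names = FALSE)
      p
    },
    psa = {
      if (is.null(seed)) stop("mode = \"psa\" requires a seed",
                              call. = FALSE)
      .prepare_out_dir(out_dir, c("psa.csv", "ceac.csv"), force)
      psa <- run_psa(params, start_age = ages[1], n_draws = n_draws,
                     seed = seed)
      p1 <- file.path(out_dir, "psa.csv")
      p2 <- file.path(out_dir, "ceac.csv")
      utils::write.csv(psa$draws, p1, row.names = FALSE)
      utils::write.csv(psa$ceac, p2, row.names = FALSE)
      if (!quiet) message(sprintf("PSA: %d draws, seed %d", n_draws, seed))
      c(p1, p2)
    },
    compliance = {
      .prepare_out_dir(out_dir, "compliance.csv", force)
      tab <- compliance_scenario(params, rates = rates, ages = ages)
      p <- file.path(out_dir, "compliance.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      p
    },
    threshold = {
      .prepare_out_dir(out_dir, "threshold.csv", force)
      rows <- lapply(ages, function(a) {
        th <- tryCatch(zvl_price_threshold(params, start_age = a),
                       error = function(e) list(
                         age_band = band_of(a), threshold_price = NA_real_,
                         pct_reduction_from_base = NA_real_,
                         base_price = params$costs$price_zvl_dose,
                         status = conditionMessage(e)))
        data.frame(age = a, age_band = th$age_band,
                   threshold_price = th$threshold_price,
                   pct_reduction_from_base = th$pct_reduction_from_base,
                   base_price = th$base_price, status = th$status,
                   stringsAsFactors = FALSE)
      })
      p <- file.path(out_dir, "threshold.csv")
      utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
      p
    }
  )
  if (!quiet) {
    message(sprintf("%s finished in %.1f s", mode,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  .write_manifest(out_dir, paste0("sens --mode ", mode), config, seed,
                  basename(paths))
  invisible(paths)
}
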