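#' Run configuration files
#'
#' A run configuration is a flat `key=value` text file (one pair per line,
#' `#` comments allowed) driving [run_pipeline()].  Recognised keys:
#' `model` (`SD`, `IT` or `SD,IT`), `data` (survival CSV), `exposure`
#' (optional exposure CSV), `interpolation` (`linear`/`const`), `seed`,
#' `chains`, `iter`, `warmup`, `out` (output directory), `x` and `t`
#' (comma-separated endpoint grids).
#'
#' @param path path to the configuration file.
#' @return a named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) < 2L)
  if (length(bad))
    stop("malformed config line ", bad[1L], ": '", lines[bad[1L]], "'")
  cfg <- stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1L], collapse = "="))),
    trimws(vapply(kv, `[[`, character(1), 1L)))
  cfg$config_path <- path
  cfg
}

#' Fit, check and derive endpoints in one deterministic run
#'
#' Orchestrates the full workflow for one or both GUTS-RED models: reads
#' the data, fits each requested model, and writes posterior draws,
#' diagnostics, goodness-of-fit measures, posterior survival bands per
#' profile, LC(x, t) tables (constant-exposure datasets) and MF(x, t)
#' tables (per profile), plus a manifest recording package version, seed,
#' configuration hash and any convergence warnings.  Re-running the same
#' configuration reproduces all outputs bit for bit.
#'
#' @param config a configuration list from [read_run_config()] (or a named
#'   list with the same keys).
#' @return (invisibly) a named list of `guts_fit` objects, one per model.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("model", "data", "out"))
    if (is.null(config[[key]])) stop("config key '", key, "' is required")
  if (!file.exists(config$data))
    stop("survival data file not found: ", config$data)
  if (!is.null(config$exposure) && !file.exists(config$exposure))
    stop("exposure file not found: ", config$exposure)

  models <- toupper(trimws(strsplit(config$model, ",")[[1L]]))
  if (!all(models %in% c("SD", "IT")))
    stop("config 'model' must be SD, IT or SD,IT")
  seed <- as.integer(config$seed %||% 1L)
  chains <- as.integer(config$chains %||% 3L)
  iter <- as.integer(config$iter %||% 5000L)
  warmup <- as.integer(config$warmup %||% 5000L)
  xs <- .num_list(config$x %||% "10,20,50")
  interp <- config$interpolation %||% "linear"

  data <- read_survival_csv(config$data, exposure_path = config$exposure,
                            interpolation = interp)
  t_end <- max(vapply(data$series, function(s) max(s$time), numeric(1)))
  ts <- .num_list(config$t %||% as.character(t_end))

  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_const <- all(vapply(data$series, function(s) {
    is_constant_profile(s$profile)
  }, logical(1)))

  fits <- list()
  manifest <- list(
    package = "gutsred",
    version = as.character(utils::packageVersion("gutsred")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config[setdiff(names(config), "config_path")],
    config_hash = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA_character_,
    models = list())

  for (model in models) {
    fit <- guts_fit(data, model = model, chains = chains, iter = iter,
                    warmup = warmup, seed = seed)
    fits[[model]] <- fit
    utils::write.csv(posterior_draws(fit),
                     file.path(out_dir, paste0("posterior_", model, ".csv")),
                     row.names = FALSE, quote = FALSE)
    g <- gof(fit)
    jsonlite::write_json(
      list(nrmse = as.list(g$nrmse), ppc_pct = g$ppc_pct, waic = g$waic,
           loo = g$loo, n_obs = g$n_obs),
      file.path(out_dir, paste0("gof_", model, ".json")),
      auto_unbox = TRUE, digits = NA)

    for (s in data$series) {
      band <- predict(fit, profile = s$profile,
                      times = seq(0, max(s$time), length.out = 51),
                      mode = "rate")
      utils::write.csv(band,
                       file.path(out_dir, paste0("survival_", model, "_",
                                                 s$label, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }

    if (all_const) {
      lc <- lcx(fit, x = rep(xs, each = length(ts)),
                t = rep(ts, length(xs)))
      utils::write.csv(.endpoint_table(lc),
                       file.path(out_dir, paste0("lcx_", model, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    mf_tabs <- lapply(data$series, function(s) {
      if (max(s$profile$conc) <= 0) return(NULL)
      mf <- mfx(fit, s$profile, x = xs, t = max(s$time))
      cbind(profile = s$label, .endpoint_table(mf))
    })
    mf_tabs <- do.call(rbind, mf_tabs)
    if (!is.null(mf_tabs))
      utils::write.csv(mf_tabs,
                       file.path(out_dir, paste0("mfx_", model, ".csv")),
                       row.names = FALSE, quote = FALSE)

    manifest$models[[model]] <- list(
      rhat = as.list(fit$diagnostics$rhat),
      ess = as.list(fit$diagnostics$ess),
      warnings = fit$diagnostics$warnings,
      n_draws = nrow(fit$draws))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fits)
}

.endpoint_table <- function(e) {
  data.frame(x = e$x, t = e$t, median = e$median, q2.5 = e$q2.5,
             q97.5 = e$q97.5, model = e$model)
}

.num_list <- function(s) as.numeric(trimws(strsplit(s, ",")[[1L]]))

`%||%` <- function(a, b) if (is.null(a)) b else a
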