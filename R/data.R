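#' Survival datasets
#'
#' A `guts_data` object binds one or more survival-count time series to
#' their exposure profiles.  Each series records the number of survivors at
#' increasing observation times (first time 0, giving the initial number of
#' individuals); counts must be non-increasing.
#'
#' The usual way to build one is from a long data frame with columns
#' `profile`, `time`, `Nsurv` and either a `conc` column (measured
#' concentration at each observation time, from which the exposure profile
#' is interpolated) or a separate `exposure` data frame with columns
#' `profile`, `time`, `conc` on its own, possibly finer, time grid.
#'
#' @param survival data frame with columns `profile`, `time`, `Nsurv` and
#'   optionally `conc`.
#' @param exposure optional data frame with columns `profile`, `time`,
#'   `conc`; overrides any `conc` column in `survival`.
#' @param interpolation interpolation rule for the exposure profiles,
#'   `"linear"` (default, for measured chemistry) or `"const"` (exact for
#'   rectangular pulse designs).
#' @return An object of class `guts_data`: a list with element `series`,
#'   each series holding `label`, `profile` (an [exposure_profile()]),
#'   `time` and `Nsurv`.
#' @examples
#' df <- data.frame(profile = "A", time = 0:4, conc = 2,
#'                  Nsurv = c(20, 18, 15, 12, 10))
#' d <- guts_data(df)
#' print(d)
#' @export
guts_data <- function(survival, exposure = NULL,
                      interpolation = c("linear", "const")) {
  interpolation <- match.arg(interpolation)
  survival <- as.data.frame(survival)
  need <- c("profile", "time", "Nsurv")
  if (!all(need %in% names(survival)))
    stop("`survival` must have columns ", paste(need, collapse = ", "))
  if (is.null(exposure) && !("conc" %in% names(survival)))
    stop("either a `conc` column or an `exposure` table is required")
  if (!is.null(exposure)) {
    exposure <- as.data.frame(exposure)
    if (!all(c("profile", "time", "conc") %in% names(exposure)))
      stop("`exposure` must have columns profile, time, conc")
  }

  labels <- unique(as.character(survival$profile))
  series <- lapply(labels, function(lb) {
    rows <- which(as.character(survival$profile) == lb)
    sub <- survival[rows, , drop = FALSE]
    o <- order(sub$time)
    sub <- sub[o, , drop = FALSE]
    rows <- rows[o]
    .check_series_rows(sub, rows, lb)
    if (is.null(exposure)) {
      prof <- exposure_profile(sub$time, sub$conc,
                               interpolation = interpolation, label = lb)
    } else {
      ex <- exposure[as.character(exposure$profile) == lb, , drop = FALSE]
      if (nrow(ex) == 0L)
        stop("no exposure rows for profile '", lb, "'")
      ex <- ex[order(ex$time), , drop = FALSE]
      prof <- exposure_profile(ex$time, ex$conc,
                               interpolation = interpolation, label = lb)
    }
    list(label = lb, profile = prof, time = as.numeric(sub$time),
         Nsurv = as.integer(sub$Nsurv))
  })
  structure(list(series = series), class = "guts_data")
}

.check_series_rows <- function(sub, rows, lb) {
  if (sub$time[1L] != 0)
    stop("profile '", lb, "': first observation time must be 0 (row ",
         rows[1L], ")")
  if (anyDuplicated(sub$time))
    stop("profile '", lb, "': duplicated observation times")
  bad <- which(sub$Nsurv < 0 | sub$Nsurv != round(sub$Nsurv))
  if (length(bad))
    stop("profile '", lb, "': Nsurv must be a non-negative integer (row ",
         rows[bad[1L]], ")")
  up <- which(diff(sub$Nsurv) > 0)
  if (length(up))
    stop("profile '", lb, "': Nsurv increases at row ", rows[up[1L] + 1L],
         " (counts must be non-increasing)")
  if (sub$Nsurv[1L] <= 0)
    stop("profile '", lb, "': initial number of individuals must be > 0")
  invisible(TRUE)
}

#' @export
print.guts_data <- function(x, ...) {
  n_obs <- sum(vapply(x$series, function(s) length(s$time), integer(1)))
  cat("GUTS survival dataset: ", length(x$series), " profile(s), ",
      n_obs, " observations\n", sep = "")
  for (s in x$series)
    cat("  ", s$label, ": N_init = ", s$Nsurv[1L], ", ",
        length(s$time), " times over ", max(s$time), " days",
        if (is_constant_profile(s$profile)) {
          paste0(" (constant conc ", format(s$profile$conc[1L]), ")")
        } else " (time-variable)", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.guts_data <- function(x, ...) {
  do.call(rbind, lapply(x$series, function(s) {
    data.frame(profile = s$label, time = s$time,
               conc = conc_at(s$profile, s$time), Nsurv = s$Nsurv,
               stringsAsFactors = FALSE)
  }))
}

#' Read and write survival / exposure CSV files
#'
#' The survival CSV is long format with header `profile,time,conc,Nsurv`
#' (`conc` optional when a separate exposure CSV is given); the exposure CSV
#' has header `profile,time,conc`.  One file may hold several profiles.
#'
#' @param path path to the survival CSV.
#' @param exposure_path optional path to an exposure CSV.
#' @param interpolation passed to [guts_data()].
#' @return `read_survival_csv()` returns a [guts_data()] object.
#' @export
read_survival_csv <- function(path, exposure_path = NULL,
                              interpolation = c("linear", "const")) {
  if (!file.exists(path)) stop("file not found: ", path)
  surv <- utils::read.csv(path, stringsAsFactors = FALSE)
  expo <- NULL
  if (!is.null(exposure_path)) {
    if (!file.exists(exposure_path))
      stop("exposure file not found: ", exposure_path)
    expo <- utils::read.csv(exposure_path, stringsAsFactors = FALSE)
  }
  guts_data(surv, exposure = expo, interpolation = interpolation)
}

#' @rdname read_survival_csv
#' @param data a [guts_data()] object.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "guts_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_survival_csv
#' @export
write_exposure_csv <- function(data, path) {
  stopifnot(inherits(data, "guts_data"))
  df <- do.call(rbind, lapply(data$series, function(s) {
    data.frame(profile = s$label, time = s$profile$time,
               conc = s$profile$conc, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
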