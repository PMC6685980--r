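#' Default priors from the experimental design
#'
#' All parameters get independent log10-uniform priors whose bounds are
#' derived from what the experimental design can possibly inform:
#'
#' * `kd`: between the rate at which 0.1% of toxicokinetic equilibrium is
#'   reached over the whole experiment duration and the rate at which
#'   99.9% is reached within the shortest interval between two
#'   observations — slower or faster kinetics are invisible to the design.
#' * `z` (SD) / `mw` (IT): between the smallest positive and the largest
#'   tested concentration.
#' * `bw`: `[1e-4, 1e4]`; `beta`: `[1e-2, 1e2]`.
#' * `hb`: log10-uniform up to the worst-case control mortality rate (the
#'   rate at which the largest cohort would be reduced to a single expected
#'   survivor by the end of the experiment), lower bound `1e-6`/day.
#'
#' @param data a [guts_data()] dataset.
#' @param model `"SD"` or `"IT"`.
#' @return A `guts_priors` object: a data frame with columns `param`,
#'   `lower`, `upper` (natural scale; sampling happens on log10 scale).
#' @export
default_priors <- function(data, model = c("SD", "IT")) {
  model <- match.arg(model)
  stopifnot(inherits(data, "guts_data"))
  t_end <- max(vapply(data$series, function(s) max(s$time), numeric(1)))
  gaps <- unlist(lapply(data$series, function(s) diff(s$time)))
  gap_min <- min(gaps[gaps > 0])
  concs <- unlist(lapply(data$series, function(s) s$profile$conc))
  pos <- concs[concs > 0]
  if (length(pos) == 0L)
    stop("dataset has no positive concentrations: thresholds not identifiable")
  n_max <- max(vapply(data$series, function(s) s$Nsurv[1L], integer(1)))

  kd_b <- c(-log(1 - 0.001) / t_end, -log(0.001) / gap_min)
  thr_b <- c(min(pos), max(pos))
  hb_b <- c(1e-6, -log(1 / (n_max + 1)) / t_end)
  tab <- if (model == "SD") {
    data.frame(param = c("kd", "bw", "z", "hb"),
               lower = c(kd_b[1], 1e-4, thr_b[1], hb_b[1]),
               upper = c(kd_b[2], 1e4, thr_b[2], hb_b[2]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(param = c("kd", "mw", "beta", "hb"),
               lower = c(kd_b[1], thr_b[1], 1e-2, hb_b[1]),
               upper = c(kd_b[2], thr_b[2], 1e2, hb_b[2]),
               stringsAsFactors = FALSE)
  }
  structure(tab, class = c("guts_priors", "data.frame"), model = model)
}

#' @export
print.guts_priors <- function(x, ...) {
  cat("log10-uniform priors (GUTS-RED-", attr(x, "model"), "):\n", sep = "")
  print.data.frame(x)
  invisible(x)
}
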