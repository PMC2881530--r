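# Carbon-fate accounting: where does consumed acetate carbon go?
# Three fates: incorporation into biomass (via the TOC-per-OD slope),
# respiration to CO2 (via the respiratory exchange ratio, RER), and an
# unaccounted delta reported neutrally.

#' Create a growth experiment
#'
#' @param time_h Sampling times (hours), strictly increasing.
#' @param od Optical densities (> 0).
#' @param acetate_mM Acetate concentrations (mM).
#' @param o2_cum_umol Cumulative O2 consumed (umol), non-decreasing.
#' @param volume_ml Culture volume (ml); scalar (constant) or per-row.
#' @return A `growth_experiment`.
#' @export
growth_experiment <- function(time_h, od, acetate_mM, o2_cum_umol, volume_ml) {
  n <- length(time_h)
  stopifnot(n >= 1, length(od) == n, length(acetate_mM) == n,
            length(o2_cum_umol) == n)
  if (n > 1 && any(diff(time_h) <= 0)) {
    stop("time_h must be strictly increasing")
  }
  if (n > 1 && any(diff(o2_cum_umol) < -1e-9)) {
    stop("o2_cum_umol must be non-decreasing")
  }
  if (any(od <= 0)) stop("optical densities must be positive")
  if (length(volume_ml) == 1L) volume_ml <- rep(volume_ml, n)
  stopifnot(length(volume_ml) == n, all(volume_ml > 0))
  structure(list(time_h = time_h, od = od, acetate_mM = acetate_mM,
                 o2_cum_umol = o2_cum_umol, volume_ml = volume_ml),
            class = "growth_experiment")
}

#' @export
print.growth_experiment <- function(x, ...) {
  cat(sprintf("<growth_experiment> %d samples, %.1f-%.1f h, OD %.3g-%.3g\n",
              length(x$time_h), min(x$time_h), max(x$time_h),
              min(x$od), max(x$od)))
  invisible(x)
}

#' Carbon in consumed acetate
#'
#' Two carbon atoms per acetate molecule.
#' @param acetate_consumed Acetate consumed (umol, >= 0).
#' @return umol C.
#' @export
total_carbon_uptake <- function(acetate_consumed) {
  stopifnot(all(acetate_consumed >= 0))
  2 * acetate_consumed
}

#' Carbon incorporated into biomass
#'
#' @param delta_od Optical-density increase (negative allowed: lysis, sign
#'   preserved).
#' @param volume_l Culture volume (litres).
#' @param toc_slope Total organic carbon per biomass, mmol C per OD*L
#'   (> 0).
#' @return umol C.
#' @export
incorporated_carbon <- function(delta_od, volume_l, toc_slope = 18.2) {
  stopifnot(toc_slope > 0, all(volume_l > 0))
  delta_od * volume_l * toc_slope * 1000
}

#' Carbon respired as CO2
#'
#' CO2 produced = O2 consumed x RER; one carbon per CO2. For complete
#' acetate oxidation the RER is close to one.
#'
#' @param o2_consumed O2 consumed (umol, >= 0).
#' @param rer Respiratory exchange ratio (> 0), default 1.
#' @return umol C.
#' @export
respired_carbon <- function(o2_consumed, rer = 1.0) {
  stopifnot(all(o2_consumed >= 0), rer > 0)
  o2_consumed * rer
}

#' Carbon-fate ledger of a growth experiment
#'
#' Per sampling interval and cumulatively: carbon uptake from acetate
#' disappearance, carbon incorporated (TOC slope x delta-OD x volume),
#' carbon respired (O2 x RER), and the unaccounted delta
#' `uptake - incorporated - respired` (exact by construction). Intervals
#' where acetate increases are flagged and excluded from uptake with a
#' warning.
#'
#' @param experiment A [growth_experiment()].
#' @param toc_slope mmol C per OD*L.
#' @param rer Respiratory exchange ratio.
#' @return A `carbon_fate_result`: `intervals` (data.frame with per-interval
#'   and cumulative columns), `totals` (umol C) and `fractions` (of total
#'   uptake; sum to 1 with the delta included).
#' @export
carbon_fate_accounting <- function(experiment, toc_slope = 18.2, rer = 1.0) {
  stopifnot(inherits(experiment, "growth_experiment"))
  n <- length(experiment$time_h)
  if (n < 2) stop("carbon-fate accounting needs at least two samples")
  t0 <- experiment$time_h[-n]; t1 <- experiment$time_h[-1]
  vol_ml <- experiment$volume_ml[-1]
  d_acetate_umol <- -diff(experiment$acetate_mM) * vol_ml  # mM * ml = umol
  excluded <- d_acetate_umol < 0
  if (any(excluded)) {
    warning(sprintf("%d interval(s) with increasing acetate excluded from uptake",
                    sum(excluded)))
  }
  uptake <- total_carbon_uptake(pmax(d_acetate_umol, 0))
  incorporated <- incorporated_carbon(diff(experiment$od), vol_ml / 1000,
                                      toc_slope)
  respired <- respired_carbon(pmax(diff(experiment$o2_cum_umol), 0), rer)
  delta <- uptake - incorporated - respired
  intervals <- data.frame(
    t_start = t0, t_end = t1,
    uptake_C = uptake, incorporated_C = incorporated,
    respired_C = respired, delta_C = delta,
    excluded_from_uptake = excluded,
    cum_uptake_C = cumsum(uptake),
    cum_incorporated_C = cumsum(incorporated),
    cum_respired_C = cumsum(respired),
    cum_delta_C = cumsum(delta))
  totals <- c(uptake_C = sum(uptake), incorporated_C = sum(incorporated),
              respired_C = sum(respired), delta_C = sum(delta))
  fractions <- if (totals[["uptake_C"]] > 0) {
    c(incorporated = totals[["incorporated_C"]] / totals[["uptake_C"]],
      respired = totals[["respired_C"]] / totals[["uptake_C"]],
      delta = totals[["delta_C"]] / totals[["uptake_C"]])
  } else c(incorporated = NA_real_, respired = NA_real_, delta = NA_real_)
  structure(list(intervals = intervals, totals = totals, fractions = fractions,
                 toc_slope = toc_slope, rer = rer),
            class = "carbon_fate_result")
}

#' @export
print.carbon_fate_result <- function(x, ...) {
  cat(sprintf(paste0("<carbon_fate_result> uptake %.1f umol C: ",
                     "%.1f%% incorporated, %.1f%% respired, %.1f%% delta\n"),
              x$totals[["uptake_C"]], 100 * x$fractions[["incorporated"]],
              100 * x$fractions[["respired"]], 100 * x$fractions[["delta"]]))
  invisible(x)
}

#' Write a carbon-fate ledger as TSV
#'
#' @param result A `carbon_fate_result`.
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_carbon_fate_table <- function(result, path) {
  stopifnot(inherits(result, "carbon_fate_result"))
  df <- result$intervals[, c("t_start", "t_end", "uptake_C", "incorporated_C",
                             "respired_C", "delta_C")]
  utils::write.table(format(df, trim = TRUE, scientific = FALSE, digits = 12),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
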