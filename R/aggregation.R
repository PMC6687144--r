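# Aggregation kinetics (turbidity at 360 nm) and DLS size-distribution
# summaries.

#' Summarize an aggregation trace
#'
#' Initial slope (least squares over the first `slope_window_min` minutes),
#' plateau (mean of the trailing `plateau_frac` of points) and fold change
#' (plateau over the first point, or over `floor` if the first point is
#' smaller).
#'
#' @param trace An [aggregation_trace()] with at least 5 points.
#' @param slope_window_min Initial-slope window, minutes (default 10).
#' @param plateau_frac Trailing fraction used for the plateau (default 0.1).
#' @param floor Optional lower bound for the fold-change denominator.
#' @return List with `initial_slope` (OD/min), `plateau` (OD),
#'   `fold_change`.
#' @export
scatter_summary <- function(trace, slope_window_min = 10,
                            plateau_frac = 0.1, floor = NULL) {
  if (!inherits(trace, "uvf_aggregation_trace"))
    abort_uvf("`trace` must be an aggregation_trace", "uvf_invalid_input")
  if (length(trace$time_min) < 5L)
    abort_uvf("aggregation summary needs >= 5 points",
              "uvf_insufficient_data")
  sel <- trace$time_min <= trace$time_min[1L] + slope_window_min
  slope <- if (sum(sel) >= 2L)
    unname(coef(lm(trace$od360[sel] ~ trace$time_min[sel]))[2L])
  else 0
  k <- max(1L, ceiling(plateau_frac * length(trace$od360)))
  plateau <- mean(tail(trace$od360, k))
  denom <- max(trace$od360[1L], if (is.null(floor)) -Inf else floor)
  if (denom <= 0)
    abort_uvf("first OD <= 0 and no floor given: fold change undefined",
              "uvf_undefined_ratio")
  list(initial_slope = slope, plateau = plateau,
       fold_change = plateau / denom)
}

#' Summarize a DLS size distribution
#'
#' Intensity-weighted mean radius, modal radius, a monomer flag (mode at or
#' below the cutoff, default 2 nm — the monomer size range for these
#' proteins) and the intensity fraction above the cutoff.
#'
#' @param dist A [dls_distribution()].
#' @param monomer_cutoff_nm Monomer/aggregate boundary, nm (default 2).
#' @return List with `mean_rh`, `mode_rh`, `monomer_flag`,
#'   `aggregate_fraction`.
#' @export
dls_summary <- function(dist, monomer_cutoff_nm = 2.0) {
  if (!inherits(dist, "uvf_dls"))
    abort_uvf("`dist` must be a dls_distribution", "uvf_invalid_input")
  w <- dist$intensity_frac
  if (sum(w) <= 0)
    abort_uvf("zero total intensity", "uvf_invalid_input")
  mean_rh <- sum(dist$rh_nm * w) / sum(w)
  mode_rh <- dist$rh_nm[which.max(w)]
  agg <- sum(w[dist$rh_nm > monomer_cutoff_nm])
  list(mean_rh = mean_rh, mode_rh = mode_rh,
       monomer_flag = mode_rh <= monomer_cutoff_nm,
       aggregate_fraction = agg)
}
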