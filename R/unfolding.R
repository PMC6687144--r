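# Equilibrium denaturation by the linear extrapolation method (LEM).
#
# Sequential three-state scheme N <=> I <=> U with per-step free energies
# that depend linearly on denaturant concentration c:
#   dG_i(c) = dG_i - m_i * c,   K_i(c) = exp(-dG_i(c) / RT)
# Populations follow from the partition function Z = 1 + K1 + K1*K2.
# The observable is the population-weighted I337/I350 signal.

R_KJ <- 8.314e-3 # gas constant, kJ/mol/K

#' Three-state equilibrium populations
#'
#' Fractional populations of the native (N), intermediate (I) and unfolded
#' (U) states of a sequential N <=> I <=> U scheme under the linear
#' extrapolation model. Evaluated in the log domain (log-sum-exp) so the
#' fractions are finite and sum to one for any finite parameters.
#'
#' @param urea_M Urea concentration(s), M. Vectorised.
#' @param dG1,dG2 Step free energies at zero denaturant, kJ/mol.
#' @param m1,m2 Denaturant dependence of each step, kJ/mol/M.
#' @param temperature_K Temperature, K (default 298.15).
#' @return A data frame with columns `urea_M`, `fN`, `fI`, `fU`; each row
#'   sums to 1.
#' @examples
#' three_state_populations(4, dG1 = 11.6, dG2 = 5.1, m1 = 3.5, m2 = 1.8)
#' @export
three_state_populations <- function(urea_M, dG1, dG2, m1, m2,
                                    temperature_K = 298.15) {
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  for (nm in c("dG1", "dG2", "m1", "m2"))
    check_scalar(get(nm), nm)
  f <- three_state_frac(as.numeric(urea_M), dG1, dG2, m1, m2,
                        R_KJ * temperature_K)
  data.frame(urea_M = as.numeric(urea_M),
             fN = f$fN, fI = f$fI, fU = f$fU)
}

# unvalidated fast path shared with the fitters
three_state_frac <- function(c_, dG1, dG2, m1, m2, rt) {
  l1 <- -(dG1 - m1 * c_) / rt          # log K1
  l12 <- l1 + (-(dG2 - m2 * c_) / rt)  # log K1*K2
  mx <- pmax(0, l1, l12)               # log-sum-exp guard
  lz <- mx + log(exp(-mx) + exp(l1 - mx) + exp(l12 - mx))
  list(fN = exp(-lz), fI = exp(l1 - lz), fU = exp(l12 - lz))
}

signal_3s <- function(par, c_, rt) {
  f <- three_state_frac(c_, par[["dG1"]], par[["dG2"]], par[["m1"]],
                        par[["m2"]], rt)
  par[["yN"]] * f$fN + par[["yI"]] * f$fI + par[["yU"]] * f$fU
}

two_state_fraction_unfolded <- function(urea_M, dG0, m,
                                        temperature_K = 298.15) {
  rt <- R_KJ * temperature_K
  lk <- -(dG0 - m * urea_M) / rt
  # K/(1+K) computed stably as plogis(log K)
  stats::plogis(lk)
}

#' Predicted unfolding signal
#'
#' Population-weighted spectroscopic signal for a two- or three-state model
#' with flat (urea-independent) state baselines.
#'
#' @param params Named list. Three-state: `dG1`, `dG2`, `m1`, `m2`, `yN`,
#'   `yI`, `yU`. Two-state: `dG0`, `m`, `yN`, `yU`.
#' @param urea_M Urea concentrations, M.
#' @param model `"three_state"` or `"two_state"`.
#' @param temperature_K Temperature, K.
#' @return Numeric vector of predicted signal values.
#' @export
predict_unfolding_signal <- function(params, urea_M,
                                     model = c("three_state", "two_state"),
                                     temperature_K = 298.15) {
  model <- match.arg(model)
  need <- if (model == "three_state")
    c("dG1", "dG2", "m1", "m2", "yN", "yI", "yU")
  else c("dG0", "m", "yN", "yU")
  missing <- setdiff(need, names(params))
  if (length(missing))
    abort_uvf(sprintf("missing unfolding parameter(s): %s",
                      paste(missing, collapse = ", ")),
              "uvf_invalid_input")
  if (model == "three_state") {
    p <- three_state_populations(urea_M, params$dG1, params$dG2,
                                 params$m1, params$m2, temperature_K)
    params$yN * p$fN + params$yI * p$fI + params$yU * p$fU
  } else {
    fu <- two_state_fraction_unfolded(urea_M, params$dG0, params$m,
                                      temperature_K)
    params$yN * (1 - fu) + params$yU * fu
  }
}

new_unfolding_fit <- function(model, params, curve, fitted, se, cov,
                              converged, flags) {
  res <- curve$ratio - fitted
  tss <- sum((curve$ratio - mean(curve$ratio))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  out <- list(model = model, params = params, se = se, cov = cov,
              curve = curve, fitted = fitted, residuals = res, r2 = r2,
              rss = sum(res^2), converged = converged, flags = flags,
              temperature_K = curve$temperature_K)
  if (model == "three_state") {
    out$dG_total <- params[["dG1"]] + params[["dG2"]]
  } else {
    out$cm <- params[["dG0"]] / params[["m"]]
  }
  class(out) <- c(paste0("uvf_", model, "_fit"), "uvf_unfolding_fit")
  out$c_half <- tryCatch(c_half(out), error = function(e) NA_real_)
  out
}

#' @export
print.uvf_unfolding_fit <- function(x, ...) {
  cat(sprintf("<%s unfolding fit> rss %.3g, r2 %.5f\n", x$model, x$rss,
              x$r2))
  print(round(rbind(estimate = x$params, se = x$se), 5))
  if (x$model == "three_state")
    cat(sprintf("dG_total = %.4f kJ/mol; C0.5 = %.4f M\n",
                x$dG_total, x$c_half))
  else
    cat(sprintf("Cm = dG0/m = %.4f M; C0.5 (bisection) = %.4f M\n",
                x$cm, x$c_half))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# residual function used by both fitters
unfold_rss <- function(par, curve, model) {
  pred <- predict_unfolding_signal(as.list(par), curve$urea_M, model,
                                   curve$temperature_K)
  sum((curve$ratio - pred)^2)
}

#' Fit the three-state unfolding model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the sequential
#' three-state LEM model to an I337/I350 unfolding curve, over the seven
#' parameters (dG1, dG2, m1, m2, yN, yI, yU). Because the residual surface
#' is multimodal the fit is multistarted over a grid of thermodynamic
#' initial values (dG in \{5, 10, 15, 20\} kJ/mol, m in \{1, 3, 6\}
#' kJ/mol/M) with baselines seeded from the first/last two points; the
#' lowest-residual converged fit is returned.
#'
#' @param curve An [unfolding_curve()] with at least 10 points.
#' @param init Optional named vector of starting values tried before the
#'   grid.
#' @return An object of class `uvf_three_state_fit` with elements `params`,
#'   `se`, `cov`, `dG_total` (= dG1 + dG2 exactly), `c_half`, `r2`, `flags`.
#' @export
fit_three_state <- function(curve, init = NULL) {
  if (!inherits(curve, "uvf_unfolding_curve"))
    abort_uvf("`curve` must be an unfolding_curve", "uvf_invalid_input")
  if (length(curve$urea_M) < 10L)
    abort_uvf("three-state fit needs >= 10 points spanning both transitions",
              "uvf_insufficient_data")
  yN0 <- mean(head(curve$ratio, 2))
  yU0 <- mean(tail(curve$ratio, 2))
  yI0 <- (yN0 + yU0) / 2
  starts <- list()
  if (!is.null(init)) starts[[1L]] <- init
  grid <- expand.grid(dG1 = c(5, 10, 15, 20), dG2 = c(5, 10, 15, 20),
                      m1 = c(1, 3, 6), m2 = c(1, 3, 6))
  for (i in seq_len(nrow(grid))) {
    starts[[length(starts) + 1L]] <-
      c(dG1 = grid$dG1[i], dG2 = grid$dG2[i], m1 = grid$m1[i],
        m2 = grid$m2[i], yN = yN0, yI = yI0, yU = yU0)
  }
  rt <- R_KJ * curve$temperature_K
  resid_fn <- function(par) {
    curve$ratio - signal_3s(par, curve$urea_M, rt)
  }
  # physical box: step free energies nonnegative and capped (the cap is the
  # effective two-state limit; a step pegged there marks the intermediate
  # redundant), m-values nonnegative
  lower <- c(dG1 = 0, dG2 = 0, m1 = 0, m2 = 0,
             yN = -Inf, yI = -Inf, yU = -Inf)
  upper <- c(dG1 = 60, dG2 = 60, m1 = 30, m2 = 30,
             yN = Inf, yI = Inf, yU = Inf)
  # two-phase multistart: a cheap pass over the whole grid, then a
  # tight-tolerance polish of the best start; an essentially perfect fit
  # short-circuits the remaining starts
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, fn = resid_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 50, ftol = 1e-8, ptol = 1e-8))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
    if (deviance(best) < 1e-14) break
  }
  if (!is.null(best)) {
    polished <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = coef(best), fn = resid_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) NULL)
    if (!is.null(polished) && deviance(polished) <= deviance(best))
      best <- polished
  }
  if (is.null(best))
    abort_uvf("three-state fit failed to converge from any start",
              "uvf_fit_failure")
  par <- coef(best)
  flags <- character()
  if (par[["m1"]] <= 0 || par[["m2"]] <= 0)
    flags <- c(flags, "nonphysical_m")
  if (par[["dG1"]] >= upper[["dG1"]] - 1e-6 ||
      par[["dG2"]] >= upper[["dG2"]] - 1e-6)
    flags <- c(flags, "step_at_bound")
  # model-comparison diagnostic: if the two-state model explains the curve
  # essentially as well, the fitted intermediate is redundant
  rss3 <- deviance(best)
  two <- tryCatch(fit_two_state(curve), error = function(e) NULL)
  if (!is.null(two)) {
    tss <- sum((curve$ratio - mean(curve$ratio))^2)
    if (two$rss - rss3 <= max(1e-12, 1e-4 * tss))
      flags <- c(flags, "redundant_intermediate")
  }
  cov <- tryCatch(vcov(best), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else
    rep(NA_real_, length(par))
  names(se) <- names(par)
  fitted <- predict_unfolding_signal(as.list(par), curve$urea_M,
                                     "three_state", curve$temperature_K)
  new_unfolding_fit("three_state", par, curve, fitted, se, cov,
                    converged = best$info %in% 1:4, flags = flags)
}

#' Fit the two-state unfolding model
#'
#' Nonlinear least squares of the two-state LEM model (parameters dG0, m,
#' yN, yU) to an unfolding curve. The closed-form midpoint Cm = dG0/m is
#' returned alongside the bisection-based `c_half`.
#'
#' @param curve An [unfolding_curve()] with at least 6 points.
#' @param init Optional named starting vector.
#' @return An object of class `uvf_two_state_fit`.
#' @export
fit_two_state <- function(curve, init = NULL) {
  if (!inherits(curve, "uvf_unfolding_curve"))
    abort_uvf("`curve` must be an unfolding_curve", "uvf_invalid_input")
  if (length(curve$urea_M) < 6L)
    abort_uvf("two-state fit needs >= 6 points", "uvf_insufficient_data")
  yN0 <- mean(head(curve$ratio, 2))
  yU0 <- mean(tail(curve$ratio, 2))
  # midpoint guess: urea where signal crosses halfway between baselines
  half <- (yN0 + yU0) / 2
  i <- which.min(abs(curve$ratio - half))
  cm0 <- max(curve$urea_M[i], 0.5)
  starts <- list()
  if (!is.null(init)) starts[[1L]] <- init
  for (m0 in c(1, 2, 4, 8))
    starts[[length(starts) + 1L]] <-
      c(dG0 = m0 * cm0, m = m0, yN = yN0, yU = yU0)
  resid_fn <- function(par) {
    curve$ratio - predict_unfolding_signal(as.list(par), curve$urea_M,
                                           "two_state", curve$temperature_K)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best))
    abort_uvf("two-state fit failed to converge", "uvf_fit_failure")
  par <- coef(best)
  flags <- if (par[["m"]] <= 0) "nonphysical_m" else character()
  cov <- tryCatch(vcov(best), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else
    rep(NA_real_, length(par))
  names(se) <- names(par)
  fitted <- predict_unfolding_signal(as.list(par), curve$urea_M,
                                     "two_state", curve$temperature_K)
  new_unfolding_fit("two_state", par, curve, fitted, se, cov,
                    converged = best$info %in% 1:4, flags = flags)
}

#' Apparent fraction unfolded
#'
#' Signal-normalised apparent unfolded fraction
#' fapp(c) = (yN - Y(c)) / (yN - yU), clipped to `[0, 1]` (clip count kept
#' as an attribute). This is the quantity on which the half-denaturation
#' point C0.5 is defined, because the experimental midpoint is read from
#' the I337/I350 profile, not from the native-state population.
#'
#' @param fit A fitted unfolding model (`uvf_unfolding_fit`).
#' @param urea_M Urea concentration(s), M.
#' @return Numeric vector of apparent unfolded fractions in `[0, 1]` with
#'   attribute `clipped` (number of values clipped).
#' @export
apparent_fraction_unfolded <- function(fit, urea_M) {
  if (!inherits(fit, "uvf_unfolding_fit"))
    abort_uvf("`fit` must be a fitted unfolding model", "uvf_invalid_input")
  p <- as.list(fit$params)
  if (abs(p$yN - p$yU) < 1e-12)
    abort_uvf("yN = yU: no spectroscopic contrast, fapp undefined",
              "uvf_undefined_contrast")
  y <- predict_unfolding_signal(p, urea_M, fit$model, fit$temperature_K)
  fapp <- (p$yN - y) / (p$yN - p$yU)
  clipped <- sum(fapp < 0 | fapp > 1)
  fapp <- pmin(pmax(fapp, 0), 1)
  attr(fapp, "clipped") <- clipped
  fapp
}

#' Half-denaturation concentration C0.5
#'
#' The urea concentration at which the apparent fraction unfolded equals
#' 0.5, found by bracketed bisection on `[0, 10]` M. The bracket is first
#' scanned on a dense grid; if several sign changes exist the smallest root
#' is returned with a `multiple_roots` attribute.
#'
#' @param fit A fitted unfolding model.
#' @param interval Search interval in M (default `c(0, 10)`).
#' @param tol Bisection tolerance in M (default 1e-10).
#' @return C0.5 in M.
#' @export
c_half <- function(fit, interval = c(0, 10), tol = 1e-10) {
  f <- function(c_) apparent_fraction_unfolded(fit, c_) - 0.5
  grid <- seq(interval[1], interval[2], length.out = 2001L)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  # treat exact zeros as roots
  hit <- which(vals == 0)
  if (length(hit)) return(grid[hit[1L]])
  changes <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(changes))
    abort_uvf("no 50% crossing inside the search interval",
              "uvf_no_midpoint")
  lo <- grid[changes[1L]]
  hi <- grid[changes[1L] + 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  root <- (lo + hi) / 2
  if (length(changes) > 1L) attr(root, "multiple_roots") <- length(changes)
  root
}
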