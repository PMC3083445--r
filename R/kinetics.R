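#' Kinetic model functions
#'
#' Closed-form rate laws used throughout the inhibition analysis. Units are
#' explicit in the argument names: substrate and Michaelis constants in
#' micromolar, inhibitor and inhibition constants in nanomolar, so that the
#' unit ratios inside each expression are dimensionless.
#'
#' @name kinetic_models
NULL

#' Competitive-inhibition velocity
#'
#' `v = Vmax * S / (Km * (1 + I/Ki) + S)`. With `I = 0` this is the classical
#' Michaelis-Menten rate; as `S` grows the velocity approaches `Vmax`
#' regardless of inhibitor, the signature of competitive inhibition.
#'
#' @param S_uM Substrate concentration, micromolar.
#' @param I_nM Inhibitor concentration, nanomolar.
#' @param Vmax Maximal velocity (signal/min).
#' @param Km_uM Michaelis constant, micromolar.
#' @param Ki_nM Competitive inhibition constant, nanomolar.
#' @return Velocity in the units of `Vmax` (vectorised).
#' @export
competitive_velocity <- function(S_uM, I_nM, Vmax, Km_uM, Ki_nM) {
  if (any(Km_uM <= 0) || any(Ki_nM <= 0)) abort("Km and Ki must be > 0")
  Vmax * S_uM / (Km_uM * (1 + I_nM / Ki_nM) + S_uM)
}

#' Morrison tight-binding fractional velocity
#'
#' Fractional residual velocity when inhibitor depletion by the enzyme is
#' non-negligible (inhibitor and enzyme concentrations of comparable order):
#' `v_i/v_0 = 1 - ((E + I + Ki_app) - sqrt((E + I + Ki_app)^2 - 4 E I)) / (2 E)`.
#' The apparent constant is `Ki_app = Ki * (1 + S/Km)` for a competitive
#' mechanism.
#'
#' @param E_nM Active enzyme concentration, nanomolar.
#' @param I_nM Total inhibitor concentration, nanomolar.
#' @param Ki_app_nM Apparent inhibition constant, nanomolar.
#' @return Fractional velocity in `[0, 1]` (vectorised).
#' @export
morrison_fraction <- function(E_nM, I_nM, Ki_app_nM) {
  if (any(E_nM <= 0)) abort("enzyme concentration must be > 0")
  s <- E_nM + I_nM + Ki_app_nM
  disc <- pmax(s^2 - 4 * E_nM * I_nM, 0)  # numerical guard
  frac <- 1 - (s - sqrt(disc)) / (2 * E_nM)
  pmin(pmax(frac, 0), 1)
}

#' Apparent competitive inhibition constant
#'
#' @param Ki_nM Inhibition constant, nanomolar.
#' @param S_uM Substrate concentration, micromolar.
#' @param Km_uM Michaelis constant, micromolar.
#' @return `Ki * (1 + S/Km)`, nanomolar.
#' @export
ki_apparent <- function(Ki_nM, S_uM, Km_uM) Ki_nM * (1 + S_uM / Km_uM)

#' Slow-binding progress curve
#'
#' Accumulated product signal for a reaction whose rate relaxes from an
#' initial velocity `v0` to a steady-state velocity `vs` with apparent rate
#' constant `k_obs`:
#' `P(t) = vs * t + (v0 - vs) * (1 - exp(-k_obs * t)) / k_obs`.
#' With `v0 = vs` the curve is exactly linear (no lag).
#'
#' @param t_s Time, seconds.
#' @param v0,vs Initial and steady-state velocities (signal/second).
#' @param k_obs Apparent first-order rate constant, per second.
#' @return Product signal (vectorised over `t_s`).
#' @export
slow_binding_progress <- function(t_s, v0, vs, k_obs) {
  if (any(k_obs <= 0)) abort("k_obs must be > 0")
  vs * t_s + (v0 - vs) * (1 - exp(-k_obs * t_s)) / k_obs
}

#' Association rate constant from dissociation rate and affinity
#'
#' `k_on = k_off / Ki`, with Ki converted from nanomolar to molar, so the
#' result is in inverse molar inverse seconds. Values approaching 1e9 indicate
#' diffusion-limited binding.
#'
#' @param k_off_s Dissociation rate constant, per second.
#' @param Ki_nM Equilibrium inhibition constant, nanomolar.
#' @return `k_on` in M^-1 s^-1.
#' @export
second_order_kon <- function(k_off_s, Ki_nM) {
  if (any(Ki_nM <= 0)) abort("Ki must be > 0")
  k_off_s / (Ki_nM * 1e-9)
}

#' Fold improvement in potency
#'
#' Ratio of a reference potency value (IC50 or Ki) over an improved one,
#' reported to 3 significant figures.
#'
#' @param reference_value,improved_value Potencies in the same units;
#'   `improved_value` must be > 0.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(reference_value, improved_value) {
  if (any(improved_value <= 0)) abort("improved_value must be > 0")
  signif(reference_value / improved_value, 3)
}

new_kin_fit <- function(model, params, se, rss, n, converged, extra = list()) {
  structure(
    c(list(model = model, params = params, std_errors = se,
           residual_sum_squares = rss, n_points = n, converged = converged),
      extra),
    class = "kin_fit"
  )
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("<kin_fit: %s> %s (n = %d, rss = %.3g)\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_sum_squares))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.kin_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(x$params),
         std.error = unname(x$std_errors[names(x$params)]))
}

#' @export
glance.kin_fit <- function(x, ...) {
  tibble(model = x$model, residual_sum_squares = x$residual_sum_squares,
         n_points = x$n_points, converged = x$converged)
}

nls_safely <- function(formula, data, start, lower = NULL, ...) {
  args <- list(formula, data = data, start = start,
               control = minpack.lm::nls.lm.control(
                 maxiter = 200, ftol = 1e-12, ptol = 1e-12),
               ...)
  if (!is.null(lower)) args$lower <- lower
  fit <- try(do.call(minpack.lm::nlsLM, args), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(fit = NULL, converged = FALSE,
                diagnostics = attr(fit, "condition")$message))
  }
  list(fit = fit, converged = fit$convInfo$isConv %||% TRUE, diagnostics = NULL)
}

fit_params <- function(fit) {
  co <- summary(fit)$coefficients
  list(est = setNames(co[, "Estimate"], rownames(co)),
       se = setNames(co[, "Std. Error"], rownames(co)),
       rss = sum(stats::resid(fit)^2), vcov = stats::vcov(fit))
}

#' Fit the competitive-inhibition model to rate data
#'
#' Least-squares fit of [competitive_velocity()] to velocities measured at
#' two or more substrate and inhibitor levels. `Km` can be fixed (as when a
#' substrate's Michaelis constant is known independently) or fitted.
#'
#' @param data Data frame with columns `substrate_uM`, `inhibitor_nM`,
#'   `velocity`.
#' @param Km_uM If supplied, Km is fixed at this value; otherwise fitted.
#' @return A `kin_fit` with terms `Vmax`, `Km_uM` (if fitted), `Ki_nM`.
#' @export
fit_competitive <- function(data, Km_uM = NULL) {
  data <- as_tibble(data)
  check_cols(data, c("substrate_uM", "inhibitor_nM", "velocity"))
  if (length(unique(data$inhibitor_nM)) < 2 || all(data$inhibitor_nM == 0)) {
    abort("Ki is unidentifiable: data needs >= 2 inhibitor levels incl. > 0")
  }
  if (!any(data$velocity > 0)) abort("no positive velocities in data")
  vmax0 <- max(data$velocity)
  ki0 <- stats::median(data$inhibitor_nM[data$inhibitor_nM > 0])
  if (is.null(Km_uM)) {
    if (length(unique(data$substrate_uM)) < 2) {
      abort("Km is unidentifiable from a single substrate level; fix Km_uM")
    }
    res <- nls_safely(
      velocity ~ Vmax * substrate_uM /
        (Km * (1 + inhibitor_nM / Ki) + substrate_uM),
      data, start = list(Vmax = vmax0, Km = stats::median(data$substrate_uM),
                         Ki = ki0),
      lower = c(Vmax = 1e-12, Km = 1e-12, Ki = 1e-12)
    )
    names_map <- c(Vmax = "Vmax", Km = "Km_uM", Ki = "Ki_nM")
  } else {
    Km <- Km_uM
    res <- nls_safely(
      velocity ~ Vmax * substrate_uM /
        (Km * (1 + inhibitor_nM / Ki) + substrate_uM),
      data, start = list(Vmax = vmax0, Ki = ki0),
      lower = c(Vmax = 1e-12, Ki = 1e-12)
    )
    names_map <- c(Vmax = "Vmax", Ki = "Ki_nM")
  }
  if (is.null(res$fit)) {
    return(new_kin_fit("competitive", c(Ki_nM = NA_real_), c(Ki_nM = NA_real_),
                       NA_real_, nrow(data), FALSE,
                       list(diagnostics = res$diagnostics)))
  }
  p <- fit_params(res$fit)
  est <- setNames(p$est, names_map[names(p$est)])
  se <- setNames(p$se, names_map[names(p$se)])
  new_kin_fit("competitive", est, se, p$rss, nrow(data), res$converged)
}

#' Fit the Morrison tight-binding equation to fractional velocities
#'
#' Fits the apparent constant `Ki_app` by least squares on
#' [morrison_fraction()], then converts to the true constant
#' `Ki = Ki_app / (1 + S/Km)` with Km fixed at the supplied value. Km
#' uncertainty is not propagated into Ki unless `propagate_km` is set, in
#' which case `Km_se_uM` is combined by first-order error propagation.
#'
#' @param data Data frame with columns `inhibitor_nM`, `frac_velocity`.
#' @param enzyme_nM Active enzyme concentration, nanomolar.
#' @param substrate_uM Assay substrate concentration, micromolar.
#' @param Km_uM Substrate Michaelis constant, micromolar (fixed).
#' @param propagate_km Include Km uncertainty in the Ki standard error.
#' @param Km_se_uM Standard error of Km, used when `propagate_km = TRUE`.
#' @return A `kin_fit` with terms `Ki_app_nM` and `Ki_nM`.
#' @export
fit_morrison <- function(data, enzyme_nM, substrate_uM, Km_uM,
                         propagate_km = FALSE, Km_se_uM = 0) {
  data <- as_tibble(data)
  check_cols(data, c("inhibitor_nM", "frac_velocity"))
  if (nrow(data) < 4) abort("at least 4 inhibitor levels are required")
  if (min(data$frac_velocity) > 0.9) {
    abort("Ki is unidentifiable: no measurable inhibition in the data")
  }
  if (max(data$inhibitor_nM) < enzyme_nM / 10) {
    warn(paste0("inhibitor concentrations are far below the enzyme ",
                "concentration; the tight-binding fit is poorly conditioned"))
  }
  E <- enzyme_nM
  below <- data$inhibitor_nM[data$frac_velocity < 0.5]
  ki_app0 <- max(min(below, Inf) - E / 2, 1e-4)
  if (!is.finite(ki_app0)) ki_app0 <- stats::median(data$inhibitor_nM)
  res <- nls_safely(
    frac_velocity ~ morrison_fraction(E, inhibitor_nM, Ki_app),
    data, start = list(Ki_app = ki_app0), lower = c(Ki_app = 1e-12)
  )
  if (is.null(res$fit)) {
    return(new_kin_fit("morrison", c(Ki_nM = NA_real_), c(Ki_nM = NA_real_),
                       NA_real_, nrow(data), FALSE,
                       list(diagnostics = res$diagnostics)))
  }
  p <- fit_params(res$fit)
  scale <- 1 + substrate_uM / Km_uM
  ki <- unname(p$est["Ki_app"]) / scale
  ki_se <- unname(p$se["Ki_app"]) / scale
  if (propagate_km && Km_se_uM > 0) {
    # d Ki / d Km = Ki_app * S / (Km + S)^2 expressed on matched scales
    dki_dkm <- unname(p$est["Ki_app"]) * substrate_uM /
      (Km_uM + substrate_uM)^2
    ki_se <- sqrt(ki_se^2 + (dki_dkm * Km_se_uM)^2)
  }
  new_kin_fit(
    "morrison",
    c(Ki_app_nM = unname(p$est["Ki_app"]), Ki_nM = ki),
    c(Ki_app_nM = unname(p$se["Ki_app"]), Ki_nM = ki_se),
    p$rss, nrow(data), res$converged,
    extra = list(enzyme_nM = enzyme_nM, substrate_uM = substrate_uM,
                 Km_uM = Km_uM)
  )
}

#' Fit a four-parameter logistic to a dose-response series
#'
#' Logistic on log10 inhibitor concentration:
#' `y = bottom + (top - bottom) / (1 + 10^(slope * (log10(I) - log10(IC50))))`,
#' with the IC50 at the inflection point. Top and bottom may be fixed (at 1
#' and 0 for fractional activity) or fitted. IC50 from this model is
#' descriptive; under tight-binding conditions it depends on enzyme
#' concentration and is not a binding constant.
#'
#' @param data Data frame with columns `inhibitor_nM` (> 0) and `activity`.
#' @param fix_top,fix_bottom Fixed asymptote values, or `NULL` to fit them.
#' @return A `kin_fit` with terms `IC50_nM`, `hill_slope`, and any fitted
#'   asymptotes.
#' @export
fit_ic50 <- function(data, fix_top = 1, fix_bottom = 0) {
  data <- as_tibble(data)
  check_cols(data, c("inhibitor_nM", "activity"))
  data <- dplyr::filter(data, .data$inhibitor_nM > 0)
  if (nrow(data) < 4) abort("at least 4 positive inhibitor levels are required")
  if (diff(range(data$activity)) < 0.2 * max(abs(data$activity), 1e-12)) {
    abort("IC50 is unidentifiable: no transition within the data range")
  }
  data$logI <- log10(data$inhibitor_nM)
  mid <- (max(data$activity) + min(data$activity)) / 2
  l50_0 <- data$logI[which.min(abs(data$activity - mid))]
  start <- list(l50 = l50_0, slope = 1)
  lower <- c(l50 = -12, slope = 1e-6)
  top_expr <- if (is.null(fix_top)) quote(top) else fix_top
  bot_expr <- if (is.null(fix_bottom)) quote(bottom) else fix_bottom
  if (is.null(fix_top)) { start$top <- max(data$activity); lower <- c(lower, top = -Inf) }
  if (is.null(fix_bottom)) { start$bottom <- min(data$activity); lower <- c(lower, bottom = -Inf) }
  form <- stats::as.formula(bquote(
    activity ~ .(bot_expr) + (.(top_expr) - .(bot_expr)) /
      (1 + 10^(slope * (logI - l50)))
  ))
  res <- nls_safely(form, data, start = start, lower = lower)
  if (is.null(res$fit)) {
    return(new_kin_fit("ic50", c(IC50_nM = NA_real_), c(IC50_nM = NA_real_),
                       NA_real_, nrow(data), FALSE,
                       list(diagnostics = res$diagnostics)))
  }
  p <- fit_params(res$fit)
  ic50 <- 10^unname(p$est["l50"])
  ic50_se <- log(10) * ic50 * unname(p$se["l50"])  # delta method
  est <- c(IC50_nM = ic50, hill_slope = unname(p$est["slope"]))
  se <- c(IC50_nM = ic50_se, hill_slope = unname(p$se["slope"]))
  for (nm in intersect(c("top", "bottom"), names(p$est))) {
    est[nm] <- unname(p$est[nm]); se[nm] <- unname(p$se[nm])
  }
  new_kin_fit("ic50", est, se, p$rss, nrow(data), res$converged)
}

#' Fit a slow-binding progress curve
#'
#' Fits [slow_binding_progress()] (parameters `v0`, `vs`, `k_obs`) to a
#' product-signal time series.
#'
#' @param data Data frame with columns `time_s`, `signal`.
#' @return A `kin_fit` with terms `v0`, `vs`, `k_obs` and the parameter
#'   covariance in `$vcov`.
#' @export
fit_slow_binding <- function(data) {
  data <- as_tibble(data)
  check_cols(data, c("time_s", "signal"))
  if (nrow(data) < 5) abort("at least 5 time points are required")
  t_max <- max(data$time_s)
  early <- data[data$time_s <= t_max / 10 & data$time_s > 0, ]
  v0_0 <- if (nrow(early) >= 2) {
    stats::coef(stats::lm(signal ~ time_s, early))[["time_s"]]
  } else diff(range(data$signal)) / t_max
  late <- data[data$time_s >= 0.7 * t_max, ]
  vs_0 <- stats::coef(stats::lm(signal ~ time_s, late))[["time_s"]]
  res <- nls_safely(
    signal ~ vs * time_s + (v0 - vs) * (1 - exp(-k_obs * time_s)) / k_obs,
    data, start = list(v0 = v0_0, vs = max(vs_0, 1e-8), k_obs = 3 / t_max),
    lower = c(v0 = 0, vs = 0, k_obs = 1e-10)
  )
  if (is.null(res$fit)) {
    return(new_kin_fit("slow_binding", c(k_obs = NA_real_),
                       c(k_obs = NA_real_), NA_real_, nrow(data), FALSE,
                       list(diagnostics = res$diagnostics)))
  }
  p <- fit_params(res$fit)
  if (unname(p$est["k_obs"]) * t_max < 1) {
    warn("no measurable lag within the observation window (k_obs * t_max < 1)")
  }
  new_kin_fit("slow_binding", p$est, p$se, p$rss, nrow(data), res$converged,
              extra = list(vcov = p$vcov))
}

#' Dissociation rate constant from paired slow-binding progress curves
#'
#' Analyses the standard three-curve design: (A) the uninhibited reaction,
#' (B) simultaneous addition of substrate and inhibitor (rate relaxes from v0
#' down to vs), and (C) a preformed enzyme-inhibitor complex diluted into
#' substrate (rate relaxes up to vs). The primary estimator is the standard
#' slow-binding relation `k_off = k_obs * vs / v0` from curve B. A secondary
#' estimator reads the back-extrapolated steady-state intercepts of curves B
#' and C: `k_off = vs / |intercept_B - intercept_C|`. Both are reported with
#' standard errors (first-order propagation from the curve-B fit covariance).
#'
#' @param uninhibited,coadd,preformed Data frames with columns `time_s`,
#'   `signal`.
#' @return A `kin_fit` with terms `k_obs`, `v0`, `vs`, `k_off` (primary) and
#'   `k_off_intercept` (secondary).
#' @export
fit_koff <- function(uninhibited, coadd, preformed) {
  ctrl <- as_tibble(uninhibited)
  check_cols(ctrl, c("time_s", "signal"))
  v0_ctrl <- stats::coef(stats::lm(signal ~ time_s, ctrl))[["time_s"]]

  fb <- fit_slow_binding(coadd)
  if (!fb$converged) abort("co-addition curve fit did not converge")
  fc <- fit_slow_binding(preformed)
  v0 <- unname(fb$params["v0"]); vs <- unname(fb$params["vs"])
  k <- unname(fb$params["k_obs"])
  if (vs / v0 > 0.99) {
    abort("no inhibition: steady-state and initial rates coincide, k_off undefined")
  }
  k_off <- k * vs / v0
  # delta-method SE over (v0, vs, k_obs) using the curve-B covariance
  g <- c(v0 = -k * vs / v0^2, vs = k / v0, k_obs = vs / v0)
  V <- fb$vcov[c("v0", "vs", "k_obs"), c("v0", "vs", "k_obs")]
  k_off_se <- sqrt(drop(t(g) %*% V %*% g))

  int_b <- (v0 - vs) / k
  int_c <- (unname(fc$params["v0"]) - unname(fc$params["vs"])) /
    unname(fc$params["k_obs"])
  k_off2 <- vs / abs(int_b - int_c)
  new_kin_fit(
    "koff",
    c(k_obs = k, v0 = v0, vs = vs, k_off = k_off, k_off_intercept = k_off2),
    c(k_obs = unname(fb$std_errors["k_obs"]), v0 = unname(fb$std_errors["v0"]),
      vs = unname(fb$std_errors["vs"]), k_off = k_off_se,
      k_off_intercept = NA_real_),
    fb$residual_sum_squares, fb$n_points + fc$n_points + nrow(ctrl),
    fb$converged && fc$converged,
    extra = list(v0_uninhibited = v0_ctrl)
  )
}

#' Fit an exponential decay and its half-life
#'
#' Least-squares fit of `A(t) = A0 * exp(-lambda * t)`; the half-life is
#' `t_half = ln(2) / lambda` with its standard error by first-order
#' propagation. Time and half-life are in whatever unit the data uses.
#'
#' @param data Data frame with columns `time` and `activity` (positive).
#' @return A `kin_fit` with terms `A0`, `decay_rate`, `t_half`.
#' @export
fit_half_life <- function(data) {
  data <- as_tibble(data)
  check_cols(data, c("time", "activity"))
  if (nrow(data) < 3) abort("at least 3 time points are required")
  if (!all(data$activity > 0)) abort("activities must be positive")
  lmfit <- stats::lm(log(activity) ~ time, data)
  lambda0 <- -stats::coef(lmfit)[["time"]]
  if (lambda0 <= 0) {
    warn("series is not decaying; half-life is undefined")
    return(new_kin_fit(
      "decay",
      c(A0 = exp(stats::coef(lmfit)[["(Intercept)"]]), decay_rate = lambda0,
        t_half = NA_real_),
      c(A0 = NA_real_, decay_rate = NA_real_, t_half = NA_real_),
      NA_real_, nrow(data), FALSE
    ))
  }
  res <- nls_safely(
    activity ~ A0 * exp(-lambda * time), data,
    start = list(A0 = max(data$activity), lambda = lambda0),
    lower = c(A0 = 1e-12, lambda = 1e-12)
  )
  if (is.null(res$fit)) {
    return(new_kin_fit("decay", c(t_half = NA_real_), c(t_half = NA_real_),
                       NA_real_, nrow(data), FALSE,
                       list(diagnostics = res$diagnostics)))
  }
  p <- fit_params(res$fit)
  lambda <- unname(p$est["lambda"])
  t_half <- log(2) / lambda
  t_half_se <- log(2) / lambda^2 * unname(p$se["lambda"])
  new_kin_fit(
    "decay",
    c(A0 = unname(p$est["A0"]), decay_rate = lambda, t_half = t_half),
    c(A0 = unname(p$se["A0"]), decay_rate = unname(p$se["lambda"]),
      t_half = t_half_se),
    p$rss, nrow(data), res$converged
  )
}

check_cols <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("data is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
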