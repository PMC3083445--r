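test_that("competitive velocity: limits and hand-computed value", {
  # no inhibitor: classical Michaelis-Menten
  expect_equal(competitive_velocity(100, 0, 50, 200, 5),
               50 * 100 / (200 + 100))
  # saturating substrate approaches Vmax regardless of inhibitor
  expect_equal(competitive_velocity(1e9, 500, 50, 200, 5), 50,
               tolerance = 1e-4)
  # S = Km, I = Ki: v = Vmax*Km/(2Km + Km) = Vmax/3
  expect_equal(competitive_velocity(679.9, 3.62, 100, 679.9, 3.62),
               100 * 679.9 / (679.9 * 2 + 679.9))
  expect_equal(competitive_velocity(679.9, 3.62, 100, 679.9, 3.62), 33.33,
               tolerance = 1e-3)
})

test_that("Morrison fraction: limits, clamping, and the equilibrium oracle", {
  expect_equal(morrison_fraction(0.15, 0, 0.067), 1)
  # stoichiometric titration: Ki_app = 0, I >= E wipes out all activity
  expect_equal(morrison_fraction(0.5, 0.5, 0), 0)
  expect_equal(morrison_fraction(0.5, 2, 0), 0)

  # closed form equals the numeric equilibrium solver across a grid
  for (E in c(0.05, 0.15, 1.5)) {
    for (I in c(0.01, 0.15, 0.5, 3)) {
      for (Ki_app in c(0.0067, 0.067, 0.67, 6.7)) {
        expect_equal(morrison_fraction(E, I, Ki_app),
                     morrison_oracle(E, I, Ki_app), tolerance = 1e-9)
      }
    }
  }

  # E -> 0 recovers the classical isotherm 1/(1 + I/Ki_app)
  I <- c(0.05, 0.2, 1, 5); Ki_app <- 0.4
  expect_equal(morrison_fraction(1e-9, I, Ki_app), 1 / (1 + I / Ki_app),
               tolerance = 1e-6)
})

test_that("slow-binding progress curve: degenerate, limit and hand values", {
  t <- c(0, 10, 50, 200)
  # v0 = vs: exactly linear
  expect_equal(slow_binding_progress(t, 0.3, 0.3, 0.05), 0.3 * t)
  # hand arithmetic: v0=1, vs=0.2, k=0.01, t=100 -> 20 + 0.8*(1-e^-1)/0.01
  expect_equal(slow_binding_progress(100, 1, 0.2, 0.01),
               20 + 0.8 * (1 - exp(-1)) / 0.01)
  expect_equal(slow_binding_progress(100, 1, 0.2, 0.01), 70.57,
               tolerance = 1e-4)
  # early slope ~ v0, late slope ~ vs
  eps <- 1e-6
  expect_equal(slow_binding_progress(eps, 1, 0.2, 0.01) / eps, 1,
               tolerance = 1e-4)
  late <- (slow_binding_progress(2000, 1, 0.2, 0.01) -
             slow_binding_progress(1999, 1, 0.2, 0.01))
  expect_equal(late, 0.2, tolerance = 1e-6)
})

test_that("rate-constant arithmetic and fold changes", {
  expect_equal(second_order_kon(0.031, 0.0386), 8.03e8, tolerance = 1e-3)
  expect_equal(second_order_kon(1e-3, 1), 1e6)
  expect_equal(second_order_kon(0, 1), 0)
  expect_error(second_order_kon(0.03, 0), "Ki")

  expect_equal(fold_change(7.97, 0.0635), 126)
  expect_equal(fold_change(1506, 251), 6.00)
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(1, 0), "improved_value")
})

test_that("competitive fit recovers generating parameters", {
  spec <- kinetics_spec(
    "competitive", list(Vmax = 100, Km_uM = 679.9, Ki_nM = 3.62),
    list(substrate_uM = c(170, 340, 679.9, 1359.8, 2719.6),
         inhibitor_nM = c(0, 1, 2, 4, 8, 16))
  )
  fit <- fit_competitive(make_kinetics(spec)$data)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["Ki_nM"]), 3.62, tolerance = 1e-6)
  expect_equal(unname(fit$params["Km_uM"]), 679.9, tolerance = 1e-6)

  # fixing Km gives the same answer here
  fit2 <- fit_competitive(make_kinetics(spec)$data, Km_uM = 679.9)
  expect_equal(unname(fit2$params["Ki_nM"]), 3.62, tolerance = 1e-6)

  # seeded 2% noise: estimate within 3 SE of truth
  noisy <- kinetics_spec(
    "competitive", list(Vmax = 100, Km_uM = 679.9, Ki_nM = 3.62),
    list(substrate_uM = c(170, 340, 679.9, 1359.8, 2719.6),
         inhibitor_nM = c(0, 1, 2, 4, 8, 16)),
    noise_sigma = 0.02, seed = 41
  )
  fitn <- fit_competitive(make_kinetics(noisy)$data)
  expect_lt(abs(fitn$params["Ki_nM"] - 3.62), 3 * fitn$std_errors["Ki_nM"])

  # inhibitor-free data cannot identify Ki
  flat <- kinetics_spec(
    "competitive", list(Vmax = 100, Km_uM = 679.9, Ki_nM = 3.62),
    list(substrate_uM = c(170, 679.9, 2719.6), inhibitor_nM = 0)
  )
  expect_error(fit_competitive(make_kinetics(flat)$data), "unidentifiable")
})

test_that("Morrison fit recovers tight and moderate binders", {
  design <- function(E) list(inhibitor_nM = E * 10^seq(-2, 1, length.out = 8))
  for (case in list(list(Ki = 0.0386, E = 0.15, S = 500),
                    list(Ki = 3.89, E = 1.5, S = 100))) {
    spec <- kinetics_spec(
      "morrison",
      list(Ki_nM = case$Ki, enzyme_nM = case$E, substrate_uM = case$S,
           Km_uM = 679.9),
      design(case$E)
    )
    made <- make_kinetics(spec)
    fit <- fit_morrison(made$data, case$E, case$S, 679.9)
    expect_true(fit$converged)
    expect_equal(unname(fit$params["Ki_nM"]), case$Ki, tolerance = 1e-6)
    # reported apparent constant matches the generator's derived truth
    expect_equal(unname(fit$params["Ki_app_nM"]), made$truth$Ki_app_nM,
                 tolerance = 1e-6)
  }

  # no inhibition anywhere: unidentifiable
  flat <- tibble::tibble(inhibitor_nM = c(1, 2, 4, 8) * 1e-6,
                         frac_velocity = c(1, 0.999, 1, 0.998))
  expect_error(fit_morrison(flat, 0.15, 500, 679.9), "unidentifiable")

  # inhibitor levels far below enzyme: poorly conditioned regime warning
  weak <- tibble::tibble(inhibitor_nM = c(0.001, 0.002, 0.005, 0.008),
                         frac_velocity = c(0.4, 0.35, 0.3, 0.25))
  expect_warning(fit_morrison(weak, 100, 500, 679.9), "poorly conditioned")
})

test_that("IC50 logistic fit: recovery, flat-data error, tight-binding link", {
  d <- tibble::tibble(inhibitor_nM = 10^seq(-1.5, 2.5, length.out = 10))
  d$activity <- 1 / (1 + d$inhibitor_nM / 6.07)
  fit <- fit_ic50(d)
  expect_equal(unname(fit$params["IC50_nM"]), 6.07, tolerance = 1e-6)
  expect_equal(unname(fit$params["hill_slope"]), 1, tolerance = 1e-6)

  flat <- tibble::tibble(inhibitor_nM = c(1, 2, 4, 8), activity = 1)
  expect_error(fit_ic50(flat), "unidentifiable")

  # Morrison-generated tight-binding data: descriptive IC50 ~ E/2 + Ki_app,
  # cross-checked against a brute-force grid search for the half-activity point
  E <- 1.5; Ki_app <- 0.2
  dd <- tibble::tibble(inhibitor_nM = seq(0.05, 6, length.out = 24))
  dd$activity <- morrison_fraction(E, dd$inhibitor_nM, Ki_app)
  fitm <- fit_ic50(dd)
  grid <- seq(0.01, 6, by = 1e-4)
  ic50_grid <- grid[which.min(abs(morrison_fraction(E, grid, Ki_app) - 0.5))]
  expect_equal(unname(fitm$params["IC50_nM"]), ic50_grid, tolerance = 0.05)
  expect_equal(unname(fitm$params["IC50_nM"]), E / 2 + Ki_app,
               tolerance = 0.15)
})

test_that("slow-binding triple-curve analysis recovers k_off both ways", {
  spec <- kinetics_spec(
    "slow_binding",
    list(k_on_M_s = 8.03e8, k_off_s = 0.031, enzyme_nM = 0.15,
         inhibitor_nM = 0.5, substrate_uM = 500, Km_uM = 679.9, v0 = 1),
    list(time_s = seq(0, 120, by = 2))
  )
  made <- make_kinetics(spec)
  fit <- fit_koff(made$data$uninhibited, made$data$coadd,
                  made$data$preformed)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["k_off"]), 0.031, tolerance = 0.05)
  expect_equal(unname(fit$params["k_obs"]), made$truth$k_obs,
               tolerance = 1e-4)
  # both estimators agree on noiseless curves
  expect_equal(unname(fit$params["k_off_intercept"]),
               unname(fit$params["k_off"]), tolerance = 0.1)

  # no inhibition: estimator degenerate
  lin <- tibble::tibble(time_s = seq(0, 120, by = 2))
  lin$signal <- 1 * lin$time_s
  curved <- made$data$coadd
  expect_error(
    fit_koff(made$data$uninhibited,
             dplyr::mutate(lin, signal = signal + 1e-9 * time_s^0),
             made$data$preformed),
    "no inhibition|converge"
  )
})

test_that("half-life fit: recovery, scale invariance, halving series", {
  spec <- kinetics_spec("decay", list(A0 = 100, t_half = 56.3),
                        list(time = seq(0, 240, length.out = 10)))
  made <- make_kinetics(spec)
  fit <- fit_half_life(made$data)
  expect_equal(unname(fit$params["t_half"]), 56.3, tolerance = 1e-6)
  expect_equal(unname(fit$params["decay_rate"]), log(2) / 56.3,
               tolerance = 1e-6)

  # scale invariance: multiplying the series rescales only A0
  scaled <- dplyr::mutate(made$data, activity = activity * 7)
  fit7 <- fit_half_life(scaled)
  expect_equal(unname(fit7$params["t_half"]), unname(fit$params["t_half"]),
               tolerance = 1e-9)
  expect_equal(unname(fit7$params["A0"]), 7 * unname(fit$params["A0"]),
               tolerance = 1e-9)

  # a 1 h half-life sampled hourly halves each step
  halves <- tibble::tibble(time = 0:2, activity = c(8, 4, 2))
  fith <- fit_half_life(halves)
  expect_equal(unname(fith$params["t_half"]), 1, tolerance = 1e-9)

  # constant series: warning, undefined half-life
  expect_warning(
    flatfit <- fit_half_life(tibble::tibble(time = 0:4, activity = 5)),
    "not decaying")
  expect_true(is.na(flatfit$params["t_half"]))
})

test_that("tidy and glance expose fit results in broom shape", {
  spec <- kinetics_spec("decay", list(A0 = 10, t_half = 2),
                        list(time = seq(0, 8, by = 1)))
  fit <- fit_half_life(make_kinetics(spec)$data)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true("t_half" %in% td$term)
  gl <- glance(fit)
  expect_named(gl, c("model", "residual_sum_squares", "n_points", "converged"))
  expect_true(gl$converged)
})
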