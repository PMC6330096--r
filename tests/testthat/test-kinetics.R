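# Forward column model, inversions and derived quantities.

test_that("forward COS flux has the correct production and zero-rate limits", {
  s <- test_soil()
  expect_equal(forward_flux_cos(0, s, 0), 0)
  # pure production: kappa -> 0 gives P*L, continuously
  P <- 2e-12 / s$depth_L
  s$production_P <- P
  expect_equal(forward_flux_cos(0, s, 0), P * s$depth_L)
  expect_equal(forward_flux_cos(1e-12, s, test_Ca()),
               forward_flux_cos(0, s, test_Ca()), tolerance = 1e-6)
})

test_that("forward COS flux matches the finite-difference steady-state oracle", {
  s <- test_soil(production_P = 3e-10)
  Ca <- test_Ca()
  for (kappa in 10^seq(-5, 2, by = 1)) {
    analytic <- forward_flux_cos(kappa, s, Ca)
    fd <- fd_steady_flux(kappa, s, Ca, "COS", n_nodes = 6000)
    expect_equal(analytic, fd, tolerance = 1e-3)
  }
})

test_that("forward COS flux is strictly decreasing in kappa under net uptake conditions", {
  s <- test_soil(production_P = 1e-10)
  Ca <- test_Ca()
  kappas <- 10^seq(-4, 2, by = 0.5)
  f <- forward_flux_cos(kappas, s, Ca)
  expect_true(all(diff(f) < 0))
})

test_that("deep-column limit reproduces the semi-infinite piston formula", {
  s <- test_soil()
  s$mass_g <- 8000  # very deep layer
  s$depth_L <- (s$mass_g / s$bulk_density) * 1e-6 / s$surface_S
  kappa <- 1
  cc_D <- effective_diffusivity("COS", s$porosity, s$theta, s$T_K)
  a <- kappa * henry_solubility("COS", s$T_K) * s$theta
  expect_gt(s$depth_L / sqrt(cc_D / a), 20)
  Ca <- test_Ca()
  expect_equal(forward_flux_cos(kappa, s, Ca), -sqrt(cc_D * a) * Ca,
               tolerance = 1e-12)
})

test_that("COS inversion is the exact inverse of the forward model", {
  s <- test_soil()
  set.seed(11)
  for (i in 1:50) {
    kappa <- 10^runif(1, -4, 1)
    F_dry <- runif(1, 0, 5e-12)
    s$production_P <- F_dry / s$depth_L
    Ca <- test_Ca(runif(1, 200, 500))
    F_net <- forward_flux_cos(kappa, s, Ca)
    r <- invert_k_cos(F_net, F_dry, Ca, s)
    expect_equal(r$k_total, kappa, tolerance = 1e-8)
    expect_equal(r$k_cat, r$k_total - r$k_uncat)
    expect_equal(r$f_CA, r$k_cat / r$k_uncat)
  }
})

test_that("the tropical-grassland-scale preset is recovered from its own forward flux", {
  s <- test_soil(pH = 6.6)
  kappa_true <- 0.54 + k_uncat_cos(s$T_K, s$pH)
  F_dry <- 2e-12
  s$production_P <- F_dry / s$depth_L
  Ca <- test_Ca()
  F_net <- forward_flux_cos(kappa_true, s, Ca)
  r <- invert_k_cos(F_net, F_dry, Ca, s)
  expect_equal(r$k_cat, 0.54, tolerance = 1e-8)
})

test_that("COS inversion rejects net production beyond the model range", {
  s <- test_soil()
  expect_error(invert_k_cos(5e-12, 2e-12, test_Ca(), s),
               "net production exceeds")
})

test_that("f_eq forward model is zero at kappa 0, increasing and saturating", {
  s <- test_soil()
  ch <- list(flow_lpm = 0.3, C_i = 450, C_o = 480)
  expect_equal(forward_feq(0, s, ch), 0)
  kappas <- 10^seq(-4, 4, by = 0.5)
  f <- forward_feq(kappas, s, ch)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < 1))
  # saturating approach: increments shrink monotonically at the tail
  tail_inc <- diff(f[kappas >= 1])
  expect_true(all(diff(tail_inc) < 0))
  expect_lt(tail_inc[length(tail_inc)], 0.01)
})

test_that("f_eq agrees with a molecule-tracking oracle built on the FD piston velocity", {
  # competing exponential clocks: each chamber CO2 molecule either leaves
  # through the outlet (rate u_vol/V) or invades the soil and returns
  # equilibrated (rate S*v/V), with v taken from the finite-difference
  # column solution, not the analytic closed form.
  s <- test_soil()
  ch <- list(flow_lpm = 0.3, C_i = 450, C_o = 480)
  kappa <- 0.6
  v_fd <- fd_piston_velocity(kappa, s, "CO2", n_nodes = 6000)
  u_vol <- 0.3 * 1e-3 / 60
  V <- 1e-3
  n_mol <- 40000
  set.seed(21)
  t_out <- rexp(n_mol, rate = u_vol / V)
  t_ex <- rexp(n_mol, rate = s$surface_S * v_fd / V)
  exchanged <- t_ex < t_out
  # outlet delta of the simulated molecule population, then the measured
  # equilibrated fraction via the observation formula (with respired CO2
  # entering pre-equilibrated)
  d_i <- 0.5
  d_eq <- 48
  n_resp <- round(n_mol * (ch$C_o - ch$C_i) / ch$C_i)
  d_mol <- c(ifelse(exchanged, d_eq, d_i), rep(d_eq, n_resp))
  d_o <- mean(d_mol)
  f_sim <- compute_feq(ch$C_i, ch$C_o, d_i, d_o, d_eq)
  f_model <- forward_feq(kappa, s, ch)
  se <- sd(exchanged) / sqrt(n_mol) * (1 / f_model)
  expect_equal(f_sim, f_model, tolerance = 4 * se)
})

test_that("CO2 inversion round-trips, floors and rejects out-of-range f_eq", {
  s <- test_soil()
  ch <- list(flow_lpm = 0.3, C_i = 450, C_o = 480)
  set.seed(31)
  for (i in 1:50) {
    kappa <- 10^runif(1, -3, 1)
    f <- forward_feq(kappa, s, ch)
    r <- invert_k_co2(f, s, ch)
    expect_equal(r$k_total, kappa, tolerance = 1e-8)
  }
  kappa_true <- 0.64 + k_uncat_co2_iso(s$T_K, s$pH)
  r <- invert_k_co2(forward_feq(kappa_true, s, ch), s, ch)
  expect_equal(r$k_cat, 0.64, tolerance = 1e-8)
  r0 <- invert_k_co2(-0.01, s, ch)
  expect_equal(r0$k_total, 0)
  expect_true("nonpositive_feq_zero_rate" %in% r0$solver_diagnostics$flags)
  expect_error(invert_k_co2(0.9999, s, ch), "ceiling")
})

test_that("enhancement factor and rate ratio are exact arithmetic with guarded domains", {
  expect_equal(enhancement_factor(0.54, 1.2e-5), 45000)
  expect_equal(enhancement_factor(0, 1.2e-5), 0)
  expect_equal(enhancement_factor(0.3, 0.3), 1)
  expect_error(enhancement_factor(0.5, 0), "positive")
  expect_equal(signif(rate_ratio(0.54, 0.64), 2), 0.84)
  expect_equal(rate_ratio(0.5, 0.5), 1)
  expect_equal(rate_ratio(0.38, 0.46), 0.38 / 0.46)
  expect_error(rate_ratio(0.5, 0), "positive")
})

test_that("soil column geometry is consistent with mass, density and area", {
  s <- soil_column(80, 1.1, 0.58, 0.13, 6.6)
  expect_equal(s$depth_L * s$surface_S * s$bulk_density * 1e6, s$mass_g,
               tolerance = 1e-9)
  expect_error(soil_column(80, 1.1, 0.4, 0.5, 6.6), "porosity")
})
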