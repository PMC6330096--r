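# Steady-state production-diffusion-reaction model of the incubated soil
# column for COS and the CO18O isotopologue, and its numerical inversion to
# total and CA-catalyzed first-order rate constants.
#
# Model: D_eff * C'' = kappa*B*theta * C - P on z in [0, L] (z positive
# downward), C(0) = C_a (well-mixed chamber air), zero flux at the sealed
# jar bottom z = L. With a = kappa*B*theta and z1 = sqrt(D_eff/a), the
# surface flux (positive = emission) is
#   F = P*L*tanh(x)/x - C_a*sqrt(D_eff*a)*tanh(x),   x = L/z1,
# which tends to P*L as kappa -> 0 (pure production).

KAPPA_BRACKET <- c(1e-8, 1e4)

#' Incubated soil column
#'
#' Geometry and physical state of one soil microcosm. The layer depth is
#' derived from the dry soil mass, bulk density and chamber surface area.
#'
#' @param mass_g Dry soil mass, g.
#' @param bulk_density Bulk density, g cm^-3.
#' @param porosity Total porosity (v/v).
#' @param theta Volumetric water content (v/v), at most `porosity`.
#' @param pH Soil-solution pH.
#' @param T_K Incubation temperature, kelvin.
#' @param surface_S Soil surface area, m^2.
#' @param production_P Volumetric COS production, mol m^-3 s^-1.
#' @return An object of class `soil_column` with derived `depth_L` (m).
#' @export
soil_column <- function(mass_g, bulk_density, porosity, theta, pH,
                        T_K = 293.15, surface_S = 0.0078, production_P = 0) {
  stopifnot(mass_g > 0, bulk_density > 0, surface_S > 0,
            porosity > 0, porosity < 1, theta >= 0)
  if (theta > porosity) stop("water content theta exceeds total porosity")
  check_pH(pH)
  check_temperature(T_K)
  depth_L <- (mass_g / bulk_density) * 1e-6 / surface_S  # cm3 -> m3
  structure(list(depth_L = depth_L, surface_S = surface_S,
                 porosity = porosity, theta = theta,
                 bulk_density = bulk_density, mass_g = mass_g,
                 pH = pH, T_K = T_K, production_P = production_P),
            class = "soil_column")
}

#' @export
print.soil_column <- function(x, ...) {
  cat(sprintf(
    "soil_column: %.1f g at %.2f g cm^-3 (L = %.2f mm), phi = %.2f, theta = %.2f, pH %.1f, %.1f K\n",
    x$mass_g, x$bulk_density, 1e3 * x$depth_L, x$porosity, x$theta, x$pH,
    x$T_K))
  invisible(x)
}

# tanh(x)/x with a series fallback near zero.
tanhx_over_x <- function(x) {
  ifelse(x < 1e-4, 1 - x^2 / 3 + 2 * x^4 / 15, tanh(x) / x)
}

# Reaction parameter a = kappa * B(T) * theta and effective diffusivity for
# a substrate in a column.
column_coefficients <- function(species, soil) {
  list(D = effective_diffusivity(species, soil$porosity, soil$theta,
                                 soil$T_K),
       Btheta = henry_solubility(species, soil$T_K) * soil$theta)
}

#' Forward steady-state COS flux of a soil column
#'
#' Analytic surface flux of the production-diffusion-reaction column (see
#' the package vignette for the derivation). Positive flux is emission.
#'
#' @param k_total Total first-order COS hydrolysis rate constant
#'   (uncatalyzed + catalyzed), s^-1. Vectorised.
#' @param soil A [soil_column()]; its `production_P` supplies the uniform
#'   volumetric production term.
#' @param C_a Gas-phase COS concentration at the soil surface, mol m^-3.
#' @return Net flux in mol m^-2 s^-1.
#' @export
forward_flux_cos <- function(k_total, soil, C_a) {
  stopifnot(inherits(soil, "soil_column"), all(k_total >= 0), C_a >= 0)
  cc <- column_coefficients("COS", soil)
  a <- k_total * cc$Btheta
  L <- soil$depth_L
  x <- L * sqrt(a / cc$D)
  soil$production_P * L * tanhx_over_x(x) - C_a * sqrt(cc$D * a) * tanh(x)
}

# Bracketed root of fun(kappa) = 0 on a log grid, relative tolerance ~1e-12
# on kappa. fun must be monotone across the bracket.
solve_kappa <- function(fun, bracket = KAPPA_BRACKET, what = "kappa") {
  g <- function(lk) fun(exp(lk))
  lo <- log(bracket[1])
  hi <- log(bracket[2])
  glo <- g(lo)
  ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || sign(glo) == sign(ghi)) {
    which_bound <- if (!is.na(glo) && !is.na(ghi) && abs(glo) < abs(ghi)) {
      "upper"
    } else {
      "lower"
    }
    stop(sprintf(
      "no sign change for %s in bracket [%g, %g] s^-1 (%s bound failed)",
      what, bracket[1], bracket[2], which_bound))
  }
  r <- stats::uniroot(g, lower = lo, upper = hi, f.lower = glo,
                      f.upper = ghi, tol = 1e-12, maxiter = 2000L)
  list(kappa = exp(r$root), iterations = r$iter, residual = r$f.root)
}

rate_result <- function(substrate, k_total, k_uncat, diag) {
  k_cat <- k_total - k_uncat
  flags <- diag$flags %||% character(0)
  if (k_cat < 0) {
    flags <- c(flags, "k_cat_floored_at_zero")
    k_cat <- 0
  }
  structure(list(substrate = substrate,
                 k_total = k_total,
                 k_uncat = k_uncat,
                 k_cat = k_cat,
                 f_CA = k_cat / k_uncat,
                 solver_diagnostics = c(diag, list(flags = flags))),
            class = "rate_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "rate_result [%s]: k_total = %.4g, k_uncat = %.4g, k_cat = %.4g s^-1 (f_CA = %.3g)\n",
    x$substrate, x$k_total, x$k_uncat, x$k_cat, x$f_CA))
  fl <- x$solver_diagnostics$flags
  if (length(fl)) cat("  flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rate_result <- function(x, ...) {
  data.frame(substrate = x$substrate, k_total = x$k_total,
             k_uncat = x$k_uncat, k_cat = x$k_cat, f_CA = x$f_CA,
             residual = x$solver_diagnostics$residual,
             flags = paste(x$solver_diagnostics$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Invert a net COS flux for the total and catalyzed rate constants
#'
#' Sets the volumetric production to `F_dry / L` (the dry-soil emission
#' proxy spread over the layer) and solves
#' `forward_flux_cos(kappa) = F_net` for the total rate constant by
#' bracketed root finding, then splits it into the uncatalyzed reference
#' [k_uncat_cos()] at the column's temperature and pH and the CA-catalyzed
#' remainder.
#'
#' @param F_net Net COS flux of the moist soil, mol m^-2 s^-1 (positive =
#'   emission).
#' @param F_dry Dry-soil COS emission (production proxy), mol m^-2 s^-1.
#' @param C_a Gas-phase COS concentration at the surface, mol m^-3.
#' @param soil A [soil_column()].
#' @return A `rate_result` for substrate `"COS"`.
#' @export
invert_k_cos <- function(F_net, F_dry, C_a, soil) {
  stopifnot(inherits(soil, "soil_column"), is.finite(F_net),
            is.finite(F_dry), C_a > 0)
  flags <- character(0)
  if (F_dry < 0) flags <- c(flags, "negative_dry_flux_used_as_production")
  soil$production_P <- F_dry / soil$depth_L
  F0 <- F_dry  # kappa -> 0 limit of the forward model is P*L = F_dry
  if (F_net > F0) {
    stop(sprintf(
      "net production exceeds model range: F_net (%.3g) > P*L (%.3g); no consumption to invert",
      F_net, F0))
  }
  sol <- solve_kappa(function(k) forward_flux_cos(k, soil, C_a) - F_net,
                     what = "k_COS")
  k_uncat <- k_uncat_cos(soil$T_K, soil$pH)
  rate_result("COS", sol$kappa, k_uncat,
              list(bracket = KAPPA_BRACKET, iterations = sol$iterations,
                   residual = sol$residual, flags = flags))
}

#' Forward model of the CO2 equilibration fraction
#'
#' The isotopologue exchange with the soil column acts as a piston velocity
#' `v = sqrt(D_eff * kappa * B * theta) * tanh(L/z1)`: the one-way
#' invasion flux of chamber CO2 into the soil is `S*v*C_a`, and invading
#' molecules return fully equilibrated with soil water. Writing the
#' steady-state isotope balance of the well-mixed chamber (inflow at
#' `delta_i`, respiration and soil-returned CO2 at `delta_eq`, outflow at
#' `delta_o`) and evaluating the equilibrated-fraction definition used for
#' the measurements, the outlet/inlet CO2 ratio cancels and
#' `f_eq = Phi / (1 + Phi)` with `Phi = S*v / u_vol` (equal to
#' `S*v*C_o/(u_vol*C_i)` to first order when outlet and inlet CO2 are
#' close). f_eq is zero at `kappa = 0`, strictly increasing in `kappa`,
#' and saturates below one as exchange becomes transport-limited.
#'
#' @param k_total Total CO2-H2O isotope exchange rate constant, s^-1.
#'   Vectorised.
#' @param soil A [soil_column()].
#' @param chamber List with `flow_lpm` (volumetric flow, L min^-1) and,
#'   for interface completeness with the observation tables, `C_i` and
#'   `C_o` (CO2 mole fractions at inlet and outlet; their ratio cancels in
#'   the chamber balance).
#' @return Predicted f_eq (dimensionless, in `[0, 1)`).
#' @export
forward_feq <- function(k_total, soil, chamber) {
  stopifnot(inherits(soil, "soil_column"), all(k_total >= 0),
            chamber$flow_lpm > 0)
  cc <- column_coefficients("CO2", soil)
  a <- k_total * cc$Btheta
  x <- soil$depth_L * sqrt(a / cc$D)
  v <- sqrt(cc$D * a) * tanh(x)
  u_vol <- chamber$flow_lpm * 1e-3 / 60  # m3 s^-1
  Phi <- soil$surface_S * v / u_vol
  Phi / (1 + Phi)
}

#' Invert an equilibration fraction for the CO2 exchange rate constants
#'
#' Solves `forward_feq(kappa) = f_eq` by bracketed root finding and splits
#' the total rate into the uncatalyzed reference [k_uncat_co2_iso()] and
#' the CA-catalyzed remainder. `f_eq <= 0` returns a zero-rate result with
#' a flag; `f_eq` at or above the diffusion-limited ceiling (the forward
#' model evaluated at the upper bracket) is an error.
#'
#' @param f_eq Measured equilibrated fraction (dimensionless).
#' @inheritParams forward_feq
#' @return A `rate_result` for substrate `"CO2"`.
#' @export
invert_k_co2 <- function(f_eq, soil, chamber) {
  stopifnot(inherits(soil, "soil_column"), is.finite(f_eq))
  k_uncat <- k_uncat_co2_iso(soil$T_K, soil$pH)
  if (f_eq <= 0) {
    return(rate_result("CO2", 0, k_uncat,
                       list(bracket = KAPPA_BRACKET, iterations = 0L,
                            residual = 0,
                            flags = "nonpositive_feq_zero_rate")))
  }
  ceiling_feq <- forward_feq(KAPPA_BRACKET[2], soil, chamber)
  if (f_eq >= ceiling_feq) {
    stop(sprintf(
      "f_eq (%.4g) exceeds the diffusion-limited ceiling (%.4g)",
      f_eq, ceiling_feq))
  }
  sol <- solve_kappa(function(k) forward_feq(k, soil, chamber) - f_eq,
                     what = "k_CO2")
  rate_result("CO2", sol$kappa, k_uncat,
              list(bracket = KAPPA_BRACKET, iterations = sol$iterations,
                   residual = sol$residual, flags = character(0)))
}

#' CA enhancement factor
#'
#' Catalyzed rate constant relative to the uncatalyzed reference,
#' `f_CA = k_cat / k_uncat`.
#'
#' @param k_cat Catalyzed rate constant, s^-1.
#' @param k_uncat Uncatalyzed rate constant, s^-1 (> 0).
#' @return Dimensionless enhancement factor.
#' @export
enhancement_factor <- function(k_cat, k_uncat) {
  if (any(k_uncat <= 0, na.rm = TRUE)) stop("k_uncat must be positive")
  k_cat / k_uncat
}

#' Ratio of catalyzed COS to CO2 rate constants
#'
#' @param k_cos_cat Catalyzed COS hydrolysis rate, s^-1.
#' @param k_co2_cat Catalyzed CO2-H2O exchange rate, s^-1 (> 0).
#' @return Dimensionless ratio k_COS/k_CO2.
#' @export
rate_ratio <- function(k_cos_cat, k_co2_cat) {
  if (any(k_co2_cat <= 0, na.rm = TRUE)) stop("k_co2_cat must be positive")
  k_cos_cat / k_co2_cat
}

#' Biome-aggregated rate summary
#'
#' Mean and SD per biome of the catalyzed rate constants, the per-site
#' k_COS/k_CO2 ratio and the enhancement factors, replicating the layout
#' of a biome summary table.
#'
#' @param rates data.frame with columns `biome`, `k_cos_cat`, `k_cos_uncat`,
#'   `k_co2_cat`, `k_co2_uncat` (one row per site or replicate).
#' @return data.frame with one row per biome: `n`, mean and sd of each rate,
#'   ratio and enhancement factor.
#' @export
summarize_biomes <- function(rates) {
  need <- c("biome", "k_cos_cat", "k_cos_uncat", "k_co2_cat", "k_co2_uncat")
  stopifnot(all(need %in% names(rates)))
  rates$ratio <- rate_ratio(rates$k_cos_cat, rates$k_co2_cat)
  rates$f_ca_cos <- enhancement_factor(rates$k_cos_cat, rates$k_cos_uncat)
  rates$f_ca_co2 <- enhancement_factor(rates$k_co2_cat, rates$k_co2_uncat)
  vars <- c("k_cos_uncat", "k_cos_cat", "k_co2_uncat", "k_co2_cat",
            "ratio", "f_ca_cos", "f_ca_co2")
  out <- do.call(rbind, lapply(split(rates, rates$biome), function(d) {
    row <- data.frame(biome = d$biome[1], n = nrow(d))
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- if (nrow(d) > 1) {
        stats::sd(d[[v]], na.rm = TRUE)
      } else {
        0
      }
    }
    row
  }))
  rownames(out) <- NULL
  out
}
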