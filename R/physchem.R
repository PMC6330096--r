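# Physical-chemical parameter layer: solubilities, diffusivities and
# uncatalyzed rate laws for the two CA substrates (COS and CO2/CO18O).
# All coefficients live in inst/extdata/physchem_constants.tsv so that a
# recalibration is a data edit, not a code edit.

.pc_env <- new.env(parent = emptyenv())

#' Physical-chemical constants table
#'
#' Returns the package's constants table (species, parameter, value, units,
#' citation). Every rate law, solubility and diffusivity in the package is
#' evaluated from these entries.
#'
#' @return A data.frame with columns `species`, `parameter`, `value`,
#'   `units`, `citation`.
#' @export
physchem_constants <- function() {
  if (is.null(.pc_env$tab)) {
    path <- system.file("extdata", "physchem_constants.tsv", package = "soilCA")
    if (!nzchar(path)) {
      stop("physchem constants table not found; is the package installed?")
    }
    .pc_env$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .pc_env$tab
}

pc_get <- function(species, parameter) {
  tab <- physchem_constants()
  i <- tab$species == species & tab$parameter == parameter
  if (!any(i)) {
    stop(sprintf("no constant '%s' for species '%s'", parameter, species))
  }
  tab$value[which(i)[1L]]
}

check_temperature <- function(T_K) {
  stopifnot(is.numeric(T_K), all(is.finite(T_K)))
  if (any(T_K <= 273 | T_K >= 323)) {
    stop("temperature out of validity range (273 K, 323 K)")
  }
  invisible(T_K)
}

check_pH <- function(pH) {
  stopifnot(is.numeric(pH), all(is.finite(pH)))
  if (any(pH < 3 | pH > 11)) {
    stop("pH out of validity range [3, 11]")
  }
  invisible(pH)
}

#' Gas species parameter set
#'
#' Bundles the free-air and aqueous reference diffusivities, the Henry
#' solubility law coefficients and the uncatalyzed rate-law coefficients for
#' one substrate.
#'
#' @param name `"COS"` or `"CO2"`.
#' @return An object of class `gas_species`.
#' @export
gas_species <- function(name = c("COS", "CO2")) {
  name <- match.arg(name)
  sp <- list(
    name = name,
    d_air_ref = pc_get(name, "d_air_ref"),
    d_water_ref = pc_get(name, "d_water_ref"),
    solubility_params = c(B_ref = pc_get(name, "B_ref"),
                          B_dH_R = pc_get(name, "B_dH_R")),
    uncat_params = if (name == "COS") {
      c(kw_lnA = pc_get("COS", "kw_lnA"), kw_Ea_R = pc_get("COS", "kw_Ea_R"),
        koh_lnA = pc_get("COS", "koh_lnA"), koh_Ea_R = pc_get("COS", "koh_Ea_R"))
    } else {
      c(kh_ref = pc_get("CO2", "kh_ref"), kh_Ea_R = pc_get("CO2", "kh_Ea_R"),
        koh_ref = pc_get("CO2", "koh_ref"), koh_Ea_R = pc_get("CO2", "koh_Ea_R"),
        pK1 = pc_get("CO2", "pK1"), pK2 = pc_get("CO2", "pK2"),
        iso_exchange_yield = pc_get("CO2", "iso_exchange_yield"))
    }
  )
  structure(sp, class = "gas_species")
}

as_gas_species <- function(species) {
  if (inherits(species, "gas_species")) return(species)
  gas_species(species)
}

#' Dimensionless Henry solubility
#'
#' Ratio of aqueous to gas-phase concentration at equilibrium, van 't Hoff
#' temperature dependence around 25 degrees C.
#'
#' @param species A [gas_species()] object or `"COS"`/`"CO2"`.
#' @param T_K Temperature in kelvin, inside (273, 323).
#' @return Dimensionless solubility B(T) (> 0, decreasing in T).
#' @export
henry_solubility <- function(species, T_K) {
  species <- as_gas_species(species)
  check_temperature(T_K)
  Tref <- pc_get("general", "T_ref")
  p <- species$solubility_params
  unname(p["B_ref"] * exp(p["B_dH_R"] * (1 / T_K - 1 / Tref)))
}

#' Ion product of water
#'
#' pKw(T) = A/T + B + C*T, used to convert pH to hydroxide activity.
#'
#' @param T_K Temperature in kelvin.
#' @return pKw (dimensionless).
#' @export
water_pKw <- function(T_K) {
  check_temperature(T_K)
  pc_get("water", "pKw_A") / T_K + pc_get("water", "pKw_B") +
    pc_get("water", "pKw_C") * T_K
}

#' Uncatalyzed COS hydrolysis rate constant
#'
#' First-order hydrolysis of dissolved COS: neutral pathway plus
#' base-catalyzed pathway acting on the hydroxide activity implied by pH and
#' the temperature-dependent ion product of water.
#'
#' @param T_K Temperature in kelvin, inside (273, 323).
#' @param pH Soil-solution pH in `[3, 11]`.
#' @return Rate constant in s^-1; increasing in both T and pH.
#' @export
k_uncat_cos <- function(T_K, pH) {
  check_temperature(T_K)
  check_pH(pH)
  p <- gas_species("COS")$uncat_params
  k_w <- exp(p["kw_lnA"] - p["kw_Ea_R"] / T_K)
  k_oh <- exp(p["koh_lnA"] - p["koh_Ea_R"] / T_K)
  oh <- 10^(pH - water_pKw(T_K))
  unname(k_w + k_oh * oh)
}

#' Fraction of dissolved inorganic carbon present as CO2(aq)
#'
#' Carbonate speciation at the given pH using the stored dissociation
#' constants; used to scale the hydration rate to the exchangeable CO2 pool.
#'
#' @param pH Soil-solution pH.
#' @return Fraction in (0, 1], decreasing in pH.
#' @export
co2_fraction <- function(pH) {
  check_pH(pH)
  pK1 <- pc_get("CO2", "pK1")
  pK2 <- pc_get("CO2", "pK2")
  1 / (1 + 10^(pH - pK1) + 10^(2 * pH - pK1 - pK2))
}

#' Uncatalyzed CO2-H2O oxygen isotope exchange rate constant
#'
#' Uncatalyzed CO2 hydration (neutral plus hydroxylation pathways) scaled by
#' the fraction of dissolved inorganic carbon present as CO2 and by the 1/3
#' oxygen-isotope exchange yield per hydration event.
#'
#' @inheritParams k_uncat_cos
#' @return Rate constant in s^-1; decreasing in pH above the first
#'   dissociation constant of carbonic acid.
#' @export
k_uncat_co2_iso <- function(T_K, pH) {
  check_temperature(T_K)
  check_pH(pH)
  p <- gas_species("CO2")$uncat_params
  Tref <- pc_get("general", "T_ref")
  k_h <- p["kh_ref"] * exp(-p["kh_Ea_R"] * (1 / T_K - 1 / Tref))
  k_oh <- p["koh_ref"] * exp(-p["koh_Ea_R"] * (1 / T_K - 1 / Tref))
  oh <- 10^(pH - water_pKw(T_K))
  unname((k_h + k_oh * oh) * co2_fraction(pH) * p["iso_exchange_yield"])
}

#' Free-air diffusivity at temperature
#'
#' Power-law temperature scaling of the binary gas diffusivity.
#' @keywords internal
d_air <- function(species, T_K) {
  species <- as_gas_species(species)
  Tref <- pc_get("general", "T_ref")
  species$d_air_ref * (T_K / Tref)^pc_get("general", "gas_diff_T_exponent")
}

#' Aqueous diffusivity at temperature
#'
#' Stokes-Einstein-type scaling: linear in T over the viscosity of water.
#' @keywords internal
d_water <- function(species, T_K) {
  species <- as_gas_species(species)
  Tref <- pc_get("general", "T_ref")
  visc_ratio <- exp(pc_get("general", "water_visc_Ea_R") * (1 / T_K - 1 / Tref))
  species$d_water_ref * (T_K / Tref) / visc_ratio
}

#' Effective soil-column diffusivity
#'
#' Gas plus aqueous parallel-path effective diffusivity with
#' Millington-Quirk tortuosity in both phases:
#' `D_eff = D_air(T) * eps_a^(10/3)/phi^2 + B(T) * D_water(T) * theta^(10/3)/phi^2`
#' with air-filled porosity `eps_a = porosity - theta`.
#'
#' @param species A [gas_species()] object or name.
#' @param porosity Total porosity (v/v).
#' @param theta Volumetric water content (v/v), at most `porosity`.
#' @param T_K Temperature in kelvin.
#' @return Effective diffusivity in m^2 s^-1 (referenced to total soil
#'   cross-section and gas-phase concentration).
#' @export
effective_diffusivity <- function(species, porosity, theta, T_K) {
  species <- as_gas_species(species)
  check_temperature(T_K)
  stopifnot(is.numeric(porosity), is.numeric(theta),
            all(porosity >= 0), all(porosity <= 1), all(theta >= 0))
  if (any(theta > porosity + 1e-12)) {
    stop("water content theta exceeds total porosity")
  }
  if (all(porosity == 0)) return(0 * porosity)
  eps_a <- pmax(porosity - theta, 0)
  tau_gas <- eps_a^(10 / 3) / porosity^2
  tau_aq <- theta^(10 / 3) / porosity^2
  out <- d_air(species, T_K) * tau_gas +
    henry_solubility(species, T_K) * d_water(species, T_K) * tau_aq
  out[porosity == 0] <- 0
  out
}
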