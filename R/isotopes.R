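# Oxygen-isotope utilities: delta-scale conversions, the CO2-water
# equilibrium composition, and the fraction of through-flowing CO2 that
# attained oxygen-isotope equilibrium with soil water (f_eq).

#' Convert a delta value between reference scales
#'
#' Exact conversion through the stored absolute 18O/16O reference ratios:
#' `delta_to = (delta_from + 1000) * R_from / R_to - 1000`.
#'
#' @param delta Delta value(s) in permil.
#' @param from,to `"VSMOW"` or `"VPDB-CO2"`.
#' @return Delta value(s) in permil on the `to` scale.
#' @export
delta_convert <- function(delta, from = c("VSMOW", "VPDB-CO2"),
                          to = c("VSMOW", "VPDB-CO2")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(delta)
  R <- c("VSMOW" = pc_get("isotope", "R18_VSMOW"),
         "VPDB-CO2" = pc_get("isotope", "R18_VPDBCO2"))
  (delta + 1000) * R[[from]] / R[[to]] - 1000
}

#' Equilibrium delta18O of CO2 over soil water
#'
#' Water delta plus the temperature-dependent CO2-water equilibrium
#' fractionation (`eps = A/T + B` permil), converted to the VPDB-CO2 scale.
#' Used by the synthetic-data generator; the measurement pipeline takes the
#' equilibration-jar value instead.
#'
#' @param delta_water delta18O of soil water, permil VSMOW.
#' @param T_K Temperature in kelvin, inside (273, 323).
#' @return Predicted delta18O-CO2 at full equilibrium, permil VPDB-CO2.
#' @export
equilibrium_delta <- function(delta_water, T_K) {
  check_temperature(T_K)
  eps <- pc_get("isotope", "eps_eq_A") / T_K + pc_get("isotope", "eps_eq_B")
  d_vsmow <- (delta_water + 1000) * (1 + eps / 1000) - 1000
  delta_convert(d_vsmow, "VSMOW", "VPDB-CO2")
}

#' Fraction of through-flowing CO2 equilibrated with soil water
#'
#' `f_eq = (C_o*d_o - C_i*d_i - (C_o - C_i)*d_eq) / (C_i*(d_eq - d_i))`.
#' The `(C_o - C_i)*d_eq` term removes respired CO2, which is assumed to
#' leave the soil already equilibrated with soil water.
#'
#' @param C_i,C_o CO2 mole fraction at inlet and outlet (umol mol^-1).
#' @param delta_i,delta_o delta18O-CO2 at inlet and outlet (permil
#'   VPDB-CO2).
#' @param delta_eq Fully equilibrated delta18O-CO2 from the sealed-jar
#'   incubation (permil VPDB-CO2).
#' @param denom_tol Minimum |delta_eq - delta_i| (permil) accepted before
#'   the denominator is declared unstable.
#' @return Numeric f_eq (dimensionless). Values outside `[-0.1, 1.1]`
#'   trigger a warning but are returned unclipped.
#' @export
compute_feq <- function(C_i, C_o, delta_i, delta_o, delta_eq,
                        denom_tol = 1) {
  stopifnot(all(C_i > 0), all(C_o > 0),
            all(abs(c(delta_i, delta_o, delta_eq)) < 1000))
  if (any(abs(delta_eq - delta_i) < denom_tol)) {
    stop(sprintf(
      "unstable denominator: |delta_eq - delta_i| < %g permil", denom_tol))
  }
  f <- (C_o * delta_o - C_i * delta_i - (C_o - C_i) * delta_eq) /
    (C_i * (delta_eq - delta_i))
  if (any(f < -0.1 | f > 1.1)) {
    warning("f_eq outside [-0.1, 1.1] for at least one observation ",
            "(returned unclipped)")
  }
  f
}

#' Select the equilibration-jar delta value
#'
#' Jars are sampled after 1, 2 and 3 days; the day-3 value is used when the
#' day-2 to day-3 change is below `tol` permil, otherwise the observation
#' is flagged as unconverged (NA).
#'
#' @param day1,day2,day3 delta18O-CO2 on successive days (permil VPDB-CO2).
#' @param tol Convergence tolerance (permil).
#' @return data.frame with `delta_eq` (NA when unconverged) and `converged`.
#' @export
select_delta_eq <- function(day1, day2, day3, tol = 0.2) {
  converged <- abs(day3 - day2) < tol
  data.frame(delta_eq = ifelse(converged, day3, NA_real_),
             converged = converged)
}

#' f_eq table from isotope observations
#'
#' Applies [select_delta_eq()] and [compute_feq()] to a table of isotope
#' observations.
#'
#' @param obs data.frame with columns `C_i_ppm`, `C_o_ppm`, `d18O_in`,
#'   `d18O_out`, `d18O_eq_day1`, `d18O_eq_day2`, `d18O_eq_day3` (plus any
#'   id columns, carried through).
#' @param tol Jar convergence tolerance, permil.
#' @return The input table with `delta_eq`, `converged`, `feq` and
#'   `feq_flag` columns appended; unconverged rows get `feq = NA`.
#' @export
feq_table <- function(obs, tol = 0.2) {
  need <- c("C_i_ppm", "C_o_ppm", "d18O_in", "d18O_out",
            "d18O_eq_day1", "d18O_eq_day2", "d18O_eq_day3")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("isotope table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sel <- select_delta_eq(obs$d18O_eq_day1, obs$d18O_eq_day2,
                         obs$d18O_eq_day3, tol = tol)
  obs$delta_eq <- sel$delta_eq
  obs$converged <- sel$converged
  obs$feq <- NA_real_
  ok <- sel$converged
  if (any(ok)) {
    obs$feq[ok] <- suppressWarnings(
      compute_feq(obs$C_i_ppm[ok], obs$C_o_ppm[ok], obs$d18O_in[ok],
                  obs$d18O_out[ok], obs$delta_eq[ok]))
  }
  obs$feq_flag <- !is.na(obs$feq) & (obs$feq < -0.1 | obs$feq > 1.1)
  obs
}
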