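# Dynamic flow-through chamber processing: phase-resolved concentration
# series -> per-cycle phase means -> net soil exchange rates for COS, CO2
# and H2O, and partitioning of net COS exchange into production and
# consumption using the dry-soil emission proxy.

PHASE_SECONDS <- c(inlet = 600, zero = 600, outlet = 1200)

#' Convert a volumetric flow to a molar flow
#'
#' Ideal-gas conversion at the chamber temperature and pressure.
#'
#' @param flow_lpm Volumetric flow in L min^-1.
#' @param T_K Temperature in kelvin.
#' @param P_Pa Pressure in Pa (default 1 atm).
#' @return Molar flow in mol s^-1.
#' @export
molar_flow <- function(flow_lpm, T_K, P_Pa = 101325) {
  stopifnot(flow_lpm > 0, T_K > 0)
  P_Pa * (flow_lpm * 1e-3 / 60) / (pc_get("general", "R_gas") * T_K)
}

#' Flow-through chamber run
#'
#' Bundles the chamber configuration with a phase-resolved concentration
#' series. The measurement program repeats cycles of inlet (10 min, chamber
#' bypass), zero (10 min, N2 for instrument zeroing) and outlet (20 min,
#' chamber air) phases.
#'
#' @param series data.frame with columns `time_s`, `phase`
#'   (`"inlet"`/`"zero"`/`"outlet"`), `cos_ppt`, `co2_ppm`, `h2o_ppth`.
#' @param flow_lpm Volumetric flow rate, L min^-1.
#' @param surface_m2 Soil surface area, m^2.
#' @param volume_L Chamber volume, L.
#' @param temp_K Chamber temperature, kelvin.
#' @return An object of class `chamber_run`.
#' @export
chamber_run <- function(series, flow_lpm = 0.3, surface_m2 = 0.0078,
                        volume_L = 1, temp_K = 293.15) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "phase", "cos_ppt", "co2_ppm", "h2o_ppth") %in%
                  names(series)),
            flow_lpm > 0, surface_m2 > 0, volume_L > 0)
  bad <- setdiff(unique(series$phase), names(PHASE_SECONDS))
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  structure(list(series = series,
                 flow_lpm = flow_lpm,
                 flow_u = molar_flow(flow_lpm, temp_K),
                 surface_S = surface_m2,
                 volume_L = volume_L,
                 temp_K = temp_K),
            class = "chamber_run")
}

#' @export
print.chamber_run <- function(x, ...) {
  cat(sprintf("chamber_run: %d samples, %.2f L min^-1, %.4f m^2, %.1f K\n",
              nrow(x$series), x$flow_lpm, x$surface_S, x$temp_K))
  invisible(x)
}

# Split the series into complete inlet -> zero -> outlet cycles; returns a
# list of per-cycle row-index lists. Incomplete cycles are dropped with a
# warning.
split_cycles <- function(series) {
  r <- rle(as.character(series$phase))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(phase = r$values, start = starts, end = ends,
                     stringsAsFactors = FALSE)
  cycles <- list()
  i <- 1L
  dropped <- 0L
  while (i <= nrow(segs)) {
    if (segs$phase[i] == "inlet" && i + 2L <= nrow(segs) &&
        segs$phase[i + 1L] == "zero" && segs$phase[i + 2L] == "outlet") {
      cycles[[length(cycles) + 1L]] <- list(
        inlet = segs$start[i]:segs$end[i],
        zero = segs$start[i + 1L]:segs$end[i + 1L],
        outlet = segs$start[i + 2L]:segs$end[i + 2L])
      i <- i + 3L
    } else {
      dropped <- dropped + 1L
      i <- i + 1L
    }
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d phase segment(s) not part of a complete %s",
                    dropped, "inlet-zero-outlet cycle"))
  }
  if (!length(cycles)) stop("no complete inlet-zero-outlet cycle in series")
  cycles
}

#' Per-cycle phase means and standard errors
#'
#' For each complete measurement cycle, averages the inlet and outlet
#' concentrations after discarding the first `discard_initial` seconds of
#' each phase (chamber and cell flushing), subtracts the zero-phase mean as
#' an instrument offset, and (optionally) converts COS and CO2 to a dry
#' mole-fraction basis using the water-vapour channel before averaging.
#'
#' @param run A [chamber_run()].
#' @param discard_initial Seconds discarded at the start of every phase.
#' @param dilution_correct Apply the water-vapour dilution correction
#'   (divide by `1 - x_H2O`) to COS and CO2 before averaging.
#' @return data.frame with one row per cycle and gas
#'   (`gas` in `cos`, `co2`, `h2o`), columns `c_in`, `c_out` (mol mol^-1,
#'   zero-corrected) and their standard errors `se_in`, `se_out`.
#' @export
summarize_phases <- function(run, discard_initial = 120,
                             dilution_correct = TRUE) {
  stopifnot(inherits(run, "chamber_run"), discard_initial >= 0)
  s <- run$series
  scale <- c(cos = 1e-12, co2 = 1e-6, h2o = 1e-3)
  conc <- cbind(cos = s$cos_ppt * scale[["cos"]],
                co2 = s$co2_ppm * scale[["co2"]],
                h2o = s$h2o_ppth * scale[["h2o"]])
  if (dilution_correct) {
    dry <- 1 - conc[, "h2o"]
    conc[, "cos"] <- conc[, "cos"] / dry
    conc[, "co2"] <- conc[, "co2"] / dry
  }
  cycles <- split_cycles(s)
  out <- vector("list", length(cycles))
  for (ci in seq_along(cycles)) {
    cyc <- cycles[[ci]]
    keep <- lapply(cyc, function(idx) {
      t0 <- min(s$time_s[idx])
      idx[s$time_s[idx] >= t0 + discard_initial]
    })
    if (any(lengths(keep) == 0L)) {
      stop("discard_initial leaves no samples in at least one phase")
    }
    m <- function(idx, g) mean(conc[idx, g])
    se <- function(idx, g) stats::sd(conc[idx, g]) / sqrt(length(idx))
    rows <- lapply(c("cos", "co2", "h2o"), function(g) {
      zero <- if (g == "h2o") 0 else m(keep$zero, g)
      data.frame(cycle = ci, gas = g,
                 c_in = m(keep$inlet, g) - zero,
                 c_out = m(keep$outlet, g) - zero,
                 se_in = se(keep$inlet, g),
                 se_out = se(keep$outlet, g),
                 stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Net soil exchange rate from an inlet-outlet concentration difference
#'
#' `F = (u/S) * (c_out - c_in)`. Positive flux is emission to the
#' atmosphere (outlet enriched over inlet).
#'
#' @param c_out,c_in Outlet and inlet mole fractions (mol mol^-1).
#' @param flow_u Molar flow through the chamber (mol s^-1).
#' @param surface_S Soil surface area (m^2).
#' @return Flux in mol m^-2 s^-1.
#' @export
compute_flux <- function(c_out, c_in, flow_u, surface_S) {
  stopifnot(all(is.finite(c_out)), all(is.finite(c_in)),
            flow_u > 0, surface_S > 0)
  (flow_u / surface_S) * (c_out - c_in)
}

#' Replicate-level fluxes from a chamber run
#'
#' Computes per-cycle fluxes for COS, CO2 and H2O and aggregates them over
#' cycles (mean, with a standard error propagated from the phase-mean
#' standard errors).
#'
#' @inheritParams summarize_phases
#' @return One-row data.frame of class `flux_result` with columns
#'   `F_cos_pmol`, `F_co2_umol`, `F_h2o_mmol` (positive = emission), their
#'   `*_se` companions, and `n_cycles`.
#' @export
chamber_fluxes <- function(run, discard_initial = 120,
                           dilution_correct = TRUE) {
  ph <- summarize_phases(run, discard_initial, dilution_correct)
  ratio <- run$flow_u / run$surface_S
  unit <- c(cos = 1e12, co2 = 1e6, h2o = 1e3)
  agg <- lapply(c("cos", "co2", "h2o"), function(g) {
    p <- ph[ph$gas == g, ]
    f <- compute_flux(p$c_out, p$c_in, run$flow_u, run$surface_S) * unit[[g]]
    se_cycle <- ratio * sqrt(p$se_in^2 + p$se_out^2) * unit[[g]]
    c(mean(f), sqrt(sum(se_cycle^2)) / length(f))
  })
  res <- data.frame(F_cos_pmol = agg[[1]][1], F_cos_se = agg[[1]][2],
                    F_co2_umol = agg[[2]][1], F_co2_se = agg[[2]][2],
                    F_h2o_mmol = agg[[3]][1], F_h2o_se = agg[[3]][2],
                    n_cycles = length(unique(ph$cycle)))
  class(res) <- c("flux_result", class(res))
  res
}

#' Partition net COS exchange into production and consumption
#'
#' Uses the dry-soil emission as the production proxy:
#' `F_production = F_dry`, `F_consumption = F_net - F_dry`, so the two
#' components sum to the net flux exactly. A dry-soil uptake (`F_dry < 0`)
#' or a positive consumption term (net production exceeding the proxy) is
#' flagged but not rejected.
#'
#' @param F_net_moist Net COS flux of the moist soil (any flux unit).
#' @param F_dry Net COS flux of the air-dried soil (same unit).
#' @return data.frame with `production`, `consumption`, `flagged`.
#' @export
partition_cos <- function(F_net_moist, F_dry) {
  stopifnot(is.numeric(F_net_moist), is.numeric(F_dry),
            length(F_net_moist) == length(F_dry))
  consumption <- F_net_moist - F_dry
  data.frame(production = F_dry,
             consumption = consumption,
             flagged = (F_dry < 0) | (consumption > 0))
}
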