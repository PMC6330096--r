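# Independent oracles used across the suite. These deliberately avoid the
# closed forms under test: the column model is solved by finite
# differences, Spearman correlation by hand-rolled rank arithmetic, and
# rarefied richness by the hypergeometric closed form.

# Finite-difference steady state of D*C'' = a*C - P on [0, L], C(0) = C_a,
# zero-gradient bottom; the surface flux (positive = emission) is
# recovered through the exact steady-state mass balance
# F = P*L - a * integral(C dz) (trapezoid quadrature), which avoids the
# cancellation a one-sided surface derivative suffers at small a.
fd_steady_flux <- function(k_total, soil, C_a, species = "COS",
                           n_nodes = 10000) {
  D <- effective_diffusivity(species, soil$porosity, soil$theta, soil$T_K)
  B <- henry_solubility(species, soil$T_K)
  a <- k_total * B * soil$theta
  L <- soil$depth_L
  P <- soil$production_P
  h <- L / n_nodes
  n <- n_nodes
  main <- rep(-2 * D / h^2 - a, n)
  lower <- rep(D / h^2, n - 1)
  upper <- rep(D / h^2, n - 1)
  lower[n - 1] <- 2 * D / h^2  # ghost-node reflection at the bottom
  rhs <- rep(-P, n)
  rhs[1] <- rhs[1] - D / h^2 * C_a
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(lower, main, upper))
  C <- as.vector(Matrix::solve(A, rhs))
  C_full <- c(C_a, C)
  w <- c(0.5, rep(1, n_nodes - 1), 0.5)
  P * L - a * h * sum(w * C_full)
}

# Piston velocity of a purely consuming column (P = 0) from the FD oracle.
fd_piston_velocity <- function(k_total, soil, species = "CO2",
                               n_nodes = 10000) {
  soil$production_P <- 0
  C_ref <- 1e-5  # arbitrary; flux is linear in C_a when P = 0
  -fd_steady_flux(k_total, soil, C_ref, species, n_nodes) / C_ref
}

# Spearman rho with average ranks, written out long-hand.
brute_spearman <- function(x, y) {
  rk <- function(v) {
    vapply(seq_along(v),
           function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2,
           numeric(1))
  }
  rx <- rk(x)
  ry <- rk(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Expected richness after subsampling `depth` reads without replacement
# (hypergeometric closed form).
expected_rarefied_richness <- function(counts_vec, depth) {
  N <- sum(counts_vec)
  sum(1 - exp(lchoose(N - counts_vec, depth) - lchoose(N, depth)))
}

# A representative moist tropical-grassland-like microcosm.
test_soil <- function(production_P = 0, pH = 6.6) {
  s <- soil_column(mass_g = 80, bulk_density = 1.1, porosity = 0.58,
                   theta = 0.13, pH = pH, T_K = 293.15,
                   surface_S = 0.0078)
  s$production_P <- production_P
  s
}

# Surface gas-phase COS concentration for 450 ppt at 20 C, 1 atm.
test_Ca <- function(ppt = 450) {
  ppt * 1e-12 * 101325 / (8.31446 * 293.15)
}

# Build a synthetic three-phase chamber series with constant values per
# phase (one cycle per call unless n_cycles > 1).
constant_series <- function(inlet, zero, outlet, h2o = 0, dt = 10,
                            n_cycles = 1) {
  one_gas <- function(v) v
  out <- do.call(rbind, lapply(seq_len(n_cycles), function(cy) {
    t0 <- (cy - 1) * 2400
    data.frame(
      time_s = t0 + c(seq(dt, 600, dt), 600 + seq(dt, 600, dt),
                      1200 + seq(dt, 1200, dt)),
      phase = rep(c("inlet", "zero", "outlet"), c(60, 60, 120) * (10 / dt)),
      stringsAsFactors = FALSE)
  }))
  vals <- c(inlet = inlet, zero = zero, outlet = outlet)
  out$cos_ppt <- vals[out$phase]
  out$co2_ppm <- vals[out$phase]
  out$h2o_ppth <- ifelse(out$phase == "zero", 0, h2o)
  rownames(out) <- NULL
  out
}
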