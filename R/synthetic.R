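# Synthetic-data generator: produces every input the pipeline consumes
# (chamber concentration series, isotope observations, OTU and transcript
# tables) from biome presets with known ground truth, so that every stage
# is testable end-to-end. All generators are pure functions of
# (parameters, seed).

#' Biome presets for the synthetic study
#'
#' Seven biome parameter sets spanning the study design: true catalyzed
#' rate constants (mean and between-site SD), soil pH, physical state at
#' 30% water-holding capacity, abiotic COS production and respiration
#' scales. Site counts sum to the 20-site design.
#'
#' @return data.frame with one row per biome.
#' @export
biome_presets <- function() {
  data.frame(
    name = c("tropical_grassland", "temperate_coniferous_forest",
             "temperate_broadleaf_forest", "mediterranean_grassland",
             "desert", "agricultural", "boreal_peatland"),
    n_sites = c(1L, 3L, 2L, 6L, 2L, 5L, 1L),
    k_cos_cat = c(0.54, 0.38, 0.38, 0.20, 0.16, 0.08, 0.04),
    k_cos_cat_sd = c(0, 0.04, 0.02, 0.11, 0.06, 0.08, 0),
    k_co2_cat = c(0.64, 0.49, 0.46, 0.48, 0.53, 0.38, 0.08),
    k_co2_cat_sd = c(0, 0.08, 0.02, 0.22, 0.06, 0.11, 0),
    pH = c(6.6, 6.3, 6.0, 7.1, 9.2, 6.6, 5.9),
    pH_sd = c(0, 0.15, 0.15, 0.2, 0.2, 0.6, 0),
    bulk_density = c(1.1, 0.9, 1.0, 1.2, 1.4, 1.3, 0.4),
    porosity = c(0.58, 0.66, 0.62, 0.55, 0.47, 0.51, 0.71),
    theta = c(0.13, 0.14, 0.14, 0.12, 0.10, 0.12, 0.25),
    production_pmol = c(2, 2, 2, 1.5, 0, 6, 2),
    resp_umol = c(2, 2.5, 2.5, 1.5, 0.5, 2, 3),
    stringsAsFactors = FALSE)
}

#' Default chamber configuration of the synthetic study
#'
#' Flow-through chamber setpoints: ~0.3 L min^-1 flow, 0.0078 m^2 surface,
#' 1 L volume, 20 degrees C, inlet mole fractions of ~450 ppm CO2 and
#' ~450 ppt COS, and 18O-labelled soil water at 47.57 permil VSMOW.
#'
#' @return Named list of chamber setpoints.
#' @export
chamber_defaults <- function() {
  list(flow_lpm = 0.3, surface_m2 = 0.0078, volume_L = 1, temp_K = 293.15,
       cos_in_ppt = 450, co2_in_ppm = 450, h2o_in_ppth = 10,
       h2o_out_ppth = 12, d18O_water = 47.57, d18O_co2_in = 0.5,
       dry_cos_in_ppt = 450, dry_co2_in_ppm = 420, dry_h2o_ppth = 8)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower & sd > 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmax(x, lower)
}

#' Generate the synthetic site table with ground truth
#'
#' Draws per-site true catalyzed rate constants, soil properties and
#' production/respiration scales from the biome presets (triplicate
#' replicates per site share the site truth, mimicking the field's
#' within-site sampling design).
#'
#' @param n_sites Number of sites; `NULL` (default) uses the preset site
#'   counts (20 sites), otherwise biomes are recycled to length.
#' @param presets A [biome_presets()]-shaped data.frame.
#' @param seed Integer seed.
#' @param mass_g Dry soil mass per microcosm, g.
#' @return An object of class `sim_truth`: list with `sites` (site-level
#'   truth), `replicates` (one row per site x replicate), `chamber`
#'   (setpoints) and `seed`.
#' @export
make_sites <- function(n_sites = NULL, presets = biome_presets(), seed = 1,
                       mass_g = 80) {
  if (!nrow(presets)) stop("empty preset table")
  idx <- if (is.null(n_sites)) {
    rep(seq_len(nrow(presets)), presets$n_sites)
  } else {
    stopifnot(n_sites >= 1)
    rep(seq_len(nrow(presets)), length.out = n_sites)
  }
  sites <- withr::with_seed(seed, {
    p <- presets[idx, ]
    n <- nrow(p)
    data.frame(
      site = sprintf("site_%02d", seq_len(n)),
      biome = p$name,
      k_cos_cat_true = rnorm_trunc(n, p$k_cos_cat, p$k_cos_cat_sd, 1e-3),
      k_co2_cat_true = rnorm_trunc(n, p$k_co2_cat, p$k_co2_cat_sd, 1e-3),
      pH = pmin(pmax(stats::rnorm(n, p$pH, p$pH_sd), 3.5), 10.5),
      bulk_density = p$bulk_density,
      porosity = p$porosity,
      theta = p$theta,
      mass_g = mass_g,
      production_pmol = pmax(stats::rnorm(n, p$production_pmol,
                                          0.15 * p$production_pmol), 0),
      resp_umol = pmax(stats::rnorm(n, p$resp_umol, 0.1 * p$resp_umol),
                       0.1),
      stringsAsFactors = FALSE,
      row.names = NULL)
  })
  chamber <- chamber_defaults()
  sites$T_K <- chamber$temp_K
  sites$k_cos_uncat <- k_uncat_cos(sites$T_K, sites$pH)
  sites$k_co2_uncat <- k_uncat_co2_iso(sites$T_K, sites$pH)
  replicates <- sites[rep(seq_len(nrow(sites)), each = 3L), ]
  replicates$replicate <- rep(1:3, nrow(sites))
  rownames(replicates) <- NULL
  structure(list(sites = sites, replicates = replicates, chamber = chamber,
                 seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d sites x 3 replicates (%d biomes), seed %d\n",
              nrow(x$sites), length(unique(x$sites$biome)), x$seed))
  invisible(x)
}

truth_soil_column <- function(row, chamber, dry = FALSE) {
  soil_column(mass_g = row$mass_g, bulk_density = row$bulk_density,
              porosity = row$porosity,
              theta = if (dry) 0 else row$theta,
              pH = row$pH, T_K = row$T_K,
              surface_S = chamber$surface_m2)
}

# Coupled steady state of the well-mixed chamber and the soil column for
# COS: the surface concentration is the outlet concentration, and the
# outlet concentration reflects the flux, so solve the (linear) balance
# c_o = c_i + F(c_o)*S/u exactly.
steady_state_cos <- function(row, chamber, dry = FALSE) {
  soil <- truth_soil_column(row, chamber, dry = dry)
  u <- molar_flow(chamber$flow_lpm, chamber$temp_K)
  S <- chamber$surface_m2
  F_dry <- row$production_pmol * 1e-12
  c_i <- (if (dry) chamber$dry_cos_in_ppt else chamber$cos_in_ppt) * 1e-12
  if (dry) {
    # air-dried soil: no aqueous phase, pure production F = P*L
    c_o <- c_i + F_dry * S / u
    return(list(c_i_ppt = c_i * 1e12, c_o_ppt = c_o * 1e12,
                F_net = F_dry, F_dry = F_dry))
  }
  kappa <- row$k_cos_cat_true + row$k_cos_uncat
  soil$production_P <- F_dry / soil$depth_L
  cc <- column_coefficients("COS", soil)
  a <- kappa * cc$Btheta
  x <- soil$depth_L * sqrt(a / cc$D)
  rho_m <- pc_get("general", "P_atm") /
    (pc_get("general", "R_gas") * chamber$temp_K)
  A_prod <- soil$production_P * soil$depth_L * tanhx_over_x(x)
  B_uptake <- sqrt(cc$D * a) * tanh(x) * rho_m  # flux per unit mole fraction
  c_o <- (c_i + A_prod * S / u) / (1 + B_uptake * S / u)
  list(c_i_ppt = c_i * 1e12, c_o_ppt = c_o * 1e12,
       F_net = A_prod - B_uptake * c_o, F_dry = F_dry)
}

steady_state_co2 <- function(row, chamber, dry = FALSE) {
  u <- molar_flow(chamber$flow_lpm, chamber$temp_K)
  S <- chamber$surface_m2
  c_i <- (if (dry) chamber$dry_co2_in_ppm else chamber$co2_in_ppm) * 1e-6
  F_resp <- (if (dry) 0.2 * row$resp_umol else row$resp_umol) * 1e-6
  c_o <- c_i + F_resp * S / u
  list(c_i_ppm = c_i * 1e6, c_o_ppm = c_o * 1e6, F_net = F_resp)
}

phase_block <- function(t0, phase, dt) {
  tt <- seq(dt, PHASE_SECONDS[[phase]], by = dt)
  data.frame(time_s = t0 + tt, phase = phase, stringsAsFactors = FALSE)
}

#' Simulate chamber concentration series
#'
#' Builds the phase-resolved concentration series of every replicate from
#' the coupled steady state of the soil column and the well-mixed chamber,
#' adds i.i.d. Gaussian instrument noise per sample, an optional common
#' instrument offset (present in all phases, removed by the zero phase),
#' and the water-vapour dilution of the wet sample stream.
#'
#' @param truth A [make_sites()] object.
#' @param condition `"moist"` (30% WHC, biological + abiotic) or `"dry"`
#'   (air-dried, abiotic production only).
#' @param noise_sd Per-gas instrument noise SD: `cos_ppt`, `co2_ppm`,
#'   `h2o_ppth`.
#' @param offset Per-gas constant instrument offset added to all phases.
#' @param dt Sampling interval, s.
#' @param n_cycles Measurement cycles per replicate.
#' @param seed Integer seed.
#' @return List with `runs` (named list of [chamber_run()] per replicate,
#'   names `site.replicate`) and `true` (data.frame of true fluxes and
#'   steady-state concentrations per replicate).
#' @export
simulate_chamber_series <- function(truth, condition = c("moist", "dry"),
                                    noise_sd = list(cos_ppt = 5,
                                                    co2_ppm = 0.5,
                                                    h2o_ppth = 0.05),
                                    offset = list(cos_ppt = 0, co2_ppm = 0),
                                    dt = 10, n_cycles = 3, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  condition <- match.arg(condition)
  ch <- truth$chamber
  reps <- truth$replicates
  dry <- condition == "dry"
  h2o_in <- if (dry) ch$dry_h2o_ppth else ch$h2o_in_ppth
  h2o_out <- if (dry) ch$dry_h2o_ppth else ch$h2o_out_ppth
  template <- do.call(rbind, lapply(seq_len(n_cycles), function(cy) {
    t0 <- (cy - 1) * sum(PHASE_SECONDS)
    rbind(phase_block(t0, "inlet", dt),
          phase_block(t0 + PHASE_SECONDS[["inlet"]], "zero", dt),
          phase_block(t0 + PHASE_SECONDS[["inlet"]] + PHASE_SECONDS[["zero"]],
                      "outlet", dt))
  }))
  withr::with_seed(seed, {
    runs <- vector("list", nrow(reps))
    true <- vector("list", nrow(reps))
    for (i in seq_len(nrow(reps))) {
      row <- reps[i, ]
      sc <- steady_state_cos(row, ch, dry = dry)
      sc2 <- steady_state_co2(row, ch, dry = dry)
      s <- template
      wet_in <- 1 - h2o_in / 1000
      wet_out <- 1 - h2o_out / 1000
      cos_dry <- c(inlet = sc$c_i_ppt, zero = 0, outlet = sc$c_o_ppt)
      co2_dry <- c(inlet = sc2$c_i_ppm, zero = 0, outlet = sc2$c_o_ppm)
      wet <- c(inlet = wet_in, zero = 1, outlet = wet_out)
      h2o <- c(inlet = h2o_in, zero = 0, outlet = h2o_out)
      ph <- s$phase
      n <- nrow(s)
      s$cos_ppt <- cos_dry[ph] * wet[ph] + offset$cos_ppt +
        stats::rnorm(n, 0, noise_sd$cos_ppt)
      s$co2_ppm <- co2_dry[ph] * wet[ph] + offset$co2_ppm +
        stats::rnorm(n, 0, noise_sd$co2_ppm)
      s$h2o_ppth <- h2o[ph] + stats::rnorm(n, 0, noise_sd$h2o_ppth)
      rownames(s) <- NULL
      runs[[i]] <- chamber_run(s, flow_lpm = ch$flow_lpm,
                               surface_m2 = ch$surface_m2,
                               volume_L = ch$volume_L, temp_K = ch$temp_K)
      true[[i]] <- data.frame(site = row$site, replicate = row$replicate,
                              condition = condition,
                              F_cos_net_pmol = sc$F_net * 1e12,
                              F_cos_dry_pmol = sc$F_dry * 1e12,
                              F_co2_umol = sc2$F_net * 1e6,
                              cos_out_ppt = sc$c_o_ppt,
                              co2_out_ppm = sc2$c_o_ppm,
                              stringsAsFactors = FALSE)
    }
    names(runs) <- paste(reps$site, reps$replicate, sep = ".")
    list(runs = runs, true = do.call(rbind, true))
  })
}

#' Simulate CO2 isotope observations
#'
#' Constructs inlet/outlet delta18O-CO2 and sealed-jar equilibration
#' observations per replicate such that, at zero noise, [compute_feq()]
#' applied to the table returns exactly the forward-model equilibration
#' fraction of the true rate constant.
#'
#' @param truth A [make_sites()] object.
#' @param noise_sd_delta Gaussian noise SD on every delta value, permil.
#' @param seed Integer seed.
#' @return data.frame per replicate with columns `site`, `replicate`,
#'   `C_i_ppm`, `C_o_ppm`, `d18O_in`, `d18O_out`, `d18O_eq_day1..3`, plus
#'   the hidden truth columns `feq_true` and `k_co2_total_true`.
#' @export
simulate_isotopes <- function(truth, noise_sd_delta = 0.1, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  ch <- truth$chamber
  reps <- truth$replicates
  d_eq <- equilibrium_delta(ch$d18O_water, ch$temp_K)
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(reps)), function(i) {
      row <- reps[i, ]
      soil <- truth_soil_column(row, ch)
      sc2 <- steady_state_co2(row, ch)
      kappa <- row$k_co2_cat_true + row$k_co2_uncat
      chamber <- list(flow_lpm = ch$flow_lpm, C_i = sc2$c_i_ppm,
                      C_o = sc2$c_o_ppm)
      f <- forward_feq(kappa, soil, chamber)
      d_i <- ch$d18O_co2_in
      # invert the equilibrated-fraction definition for the outlet delta
      d_o <- (f * sc2$c_i_ppm * (d_eq - d_i) + sc2$c_i_ppm * d_i +
                (sc2$c_o_ppm - sc2$c_i_ppm) * d_eq) / sc2$c_o_ppm
      nz <- function(x) x + stats::rnorm(length(x), 0, noise_sd_delta)
      data.frame(site = row$site, replicate = row$replicate,
                 C_i_ppm = sc2$c_i_ppm, C_o_ppm = sc2$c_o_ppm,
                 d18O_in = nz(d_i), d18O_out = nz(d_o),
                 d18O_eq_day1 = nz(d_eq - 1.0),
                 d18O_eq_day2 = nz(d_eq - 0.04),
                 d18O_eq_day3 = nz(d_eq),
                 feq_true = f, k_co2_total_true = kappa,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Default planted OTU-rate links
#'
#' Lineages given a monotone abundance-rate link by the community
#' generator: fungal lineages tied to the COS hydrolysis rate, green algae
#' to the CO2 exchange rate, and a small bacterial contribution to COS.
#'
#' @return data.frame with `marker`, `lineage`, `n_otu`, `variable`,
#'   `effect` (log-abundance slope per SD of log rate).
#' @export
default_planted_otus <- function() {
  data.frame(
    marker = c("ITS2", "ITS2", "ITS2", "ITS2", "16S"),
    lineage = c("Fungi;Ascomycota", "Fungi;Basidiomycota",
                "Fungi;Zygomycota", "Eukaryota;Chlorophyta",
                "Bacteria;Proteobacteria;Alphaproteobacteria"),
    n_otu = c(10L, 6L, 3L, 2L, 2L),
    variable = c("k_cos", "k_cos", "k_cos", "k_co2", "k_cos"),
    effect = c(1.5, 1.5, 1.5, 1.5, 1.5),
    stringsAsFactors = FALSE)
}

background_taxa <- function(marker, n) {
  pools <- list(
    `16S` = c("Bacteria;Actinobacteria", "Bacteria;Acidobacteria",
              "Bacteria;Firmicutes", "Bacteria;Bacteroidetes",
              "Bacteria;Verrucomicrobia", "Bacteria;Chloroflexi",
              "Archaea;Thaumarchaeota",
              "Bacteria;Proteobacteria;Gammaproteobacteria"),
    ITS2 = c("Fungi;Ascomycota", "Fungi;Basidiomycota",
             "Fungi;Chytridiomycota", "Eukaryota;Cercozoa",
             "Eukaryota;Ciliophora", "Fungi;Glomeromycota"))
  sample(pools[[marker]], n, replace = TRUE)
}

simulate_marker_table <- function(marker, n_otus, z_cos, z_co2, planted,
                                  site_names, conc, site_noise_sd,
                                  depth_range) {
  pl <- planted[planted$marker == marker, , drop = FALSE]
  n_planted <- sum(pl$n_otu)
  stopifnot(n_otus > n_planted)
  taxonomy <- character(n_otus)
  beta <- numeric(n_otus)
  zvar <- matrix(0, nrow = length(z_cos), ncol = n_otus)
  j <- 1L
  for (r in seq_len(nrow(pl))) {
    for (k in seq_len(pl$n_otu[r])) {
      taxonomy[j] <- pl$lineage[r]
      beta[j] <- pl$effect[r]
      zvar[, j] <- if (pl$variable[r] == "k_cos") z_cos else z_co2
      j <- j + 1L
    }
  }
  taxonomy[j:n_otus] <- background_taxa(marker, n_otus - j + 1L)
  base <- stats::rnorm(n_otus, 0, 1.5)
  n_sites <- length(z_cos)
  counts <- matrix(0L, nrow = n_sites, ncol = n_otus,
                   dimnames = list(site_names,
                                   sprintf("%s_OTU_%03d", marker,
                                           seq_len(n_otus))))
  depths <- round(stats::runif(n_sites, depth_range[1], depth_range[2]))
  for (s in seq_len(n_sites)) {
    loglam <- base + beta * zvar[s, ] +
      stats::rnorm(n_otus, 0, site_noise_sd)
    p <- exp(loglam - max(loglam))
    p <- p / sum(p)
    g <- stats::rgamma(n_otus, shape = conc * p)
    g <- g / sum(g)
    counts[s, ] <- stats::rmultinom(1, depths[s], g)[, 1]
  }
  list(counts = counts, taxonomy = taxonomy, marker = marker,
       planted = which(beta != 0))
}

#' Simulate OTU and CA transcript tables with planted rate links
#'
#' OTU tables (16S and ITS2) are generated as Dirichlet-multinomial draws
#' around log-normal baseline abundances; OTUs of the planted lineages get
#' a log-linear abundance link to the standardised log rate constant. The
#' CA transcript table plants beta-clade-D expression proportional to the
#' COS rate, beta-clade-A anti-proportional to it, and alpha-CA
#' proportional to the CO2 rate, with Poisson read noise.
#'
#' @param truth A [make_sites()] object.
#' @param n_otus Named vector: OTUs per marker (`"16S"`, `"ITS2"`).
#' @param planted A [default_planted_otus()]-shaped table.
#' @param conc Dirichlet concentration parameter (overdispersion control).
#' @param site_noise_sd Per-site log-abundance noise SD.
#' @param seed Integer seed.
#' @return List with `otu_16s`, `otu_its2` (each: `counts`, `taxonomy`,
#'   `marker`, `planted` column indices) and `transcripts` (`counts`
#'   samples x genes, `genes` metadata with `ca_class`, `clade`,
#'   `cluster_id`, `length_bp`, `genome_gbp`, plus `sample_sites`).
#' @export
simulate_community <- function(truth, n_otus = c(`16S` = 400, ITS2 = 300),
                               planted = default_planted_otus(),
                               conc = 10000, site_noise_sd = 0.4,
                               seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  sites <- truth$sites
  z_cos <- as.vector(scale(log(sites$k_cos_cat_true)))
  z_co2 <- as.vector(scale(log(sites$k_co2_cat_true)))
  withr::with_seed(seed, {
    otu_16s <- simulate_marker_table("16S", n_otus[["16S"]], z_cos, z_co2,
                                     planted, sites$site, conc,
                                     site_noise_sd, c(50000, 70000))
    otu_its2 <- simulate_marker_table("ITS2", n_otus[["ITS2"]], z_cos,
                                      z_co2, planted, sites$site, conc,
                                      site_noise_sd, c(95000, 125000))
    transcripts <- simulate_transcripts(sites, z_cos, z_co2)
    list(otu_16s = otu_16s, otu_its2 = otu_its2, transcripts = transcripts)
  })
}

simulate_transcripts <- function(sites, z_cos, z_co2, effect = 1.0,
                                 gene_noise_sd = 0.3) {
  sample_idx <- seq(1, nrow(sites), by = 2)
  sample_idx <- sample_idx[seq_len(min(10, length(sample_idx)))]
  groups <- data.frame(
    ca_class = c(rep("beta", 18), rep("alpha", 4), rep("gamma", 4),
                 rep("other", 40)),
    clade = c(rep("beta-D", 8), rep("beta-A", 4), rep("beta-B", 3),
              rep("beta-C", 3), rep(NA_character_, 48)),
    stringsAsFactors = FALSE)
  n_genes <- nrow(groups)
  genes <- data.frame(
    gene_id = sprintf("CA_gene_%03d", seq_len(n_genes)),
    ca_class = groups$ca_class,
    clade = groups$clade,
    cluster_id = seq_len(n_genes),
    length_bp = round(stats::runif(n_genes, 500, 2000)),
    genome_gbp = stats::runif(n_genes, 0.3, 5),
    stringsAsFactors = FALSE)
  # a few small-genome decoy genes, excluded upstream of the correlations
  small <- sample(which(genes$ca_class == "other"), 5)
  genes$genome_gbp[small] <- stats::runif(5, 0.01, 0.19)
  slope <- numeric(n_genes)
  slope[which(groups$clade == "beta-D")] <- effect
  slope[which(groups$clade == "beta-A")] <- -effect
  zmat <- matrix(rep(z_cos[sample_idx], n_genes), ncol = n_genes)
  zmat[, groups$ca_class == "alpha"] <- z_co2[sample_idx]
  slope[groups$ca_class == "alpha"] <- effect
  base <- stats::rnorm(n_genes, 4, 0.7)
  base[groups$ca_class == "other"] <- stats::rnorm(40, 5.5, 0.5)
  counts <- matrix(0L, nrow = length(sample_idx), ncol = n_genes,
                   dimnames = list(sites$site[sample_idx], genes$gene_id))
  for (s in seq_along(sample_idx)) {
    mu <- exp(base + slope * zmat[s, ] +
                stats::rnorm(n_genes, 0, gene_noise_sd)) *
      genes$length_bp / 1000
    counts[s, ] <- stats::rpois(n_genes, mu)
  }
  list(counts = counts, genes = genes, sample_sites = sites$site[sample_idx])
}

#' One-call synthetic study
#'
#' Generates the full input set of a study: site truth, moist and dry
#' chamber series, isotope observations and community tables, all from one
#' seed.
#'
#' @param seed Integer seed.
#' @param n_sites Passed to [make_sites()].
#' @param noise_sd Chamber noise (see [simulate_chamber_series()]).
#' @param noise_sd_delta Isotope noise, permil.
#' @param ... Passed to [simulate_community()].
#' @return List with `truth`, `moist`, `dry`, `isotopes`, `community`.
#' @export
simulate_study <- function(seed = 1, n_sites = NULL,
                           noise_sd = list(cos_ppt = 5, co2_ppm = 0.5,
                                           h2o_ppth = 0.05),
                           noise_sd_delta = 0.1, ...) {
  truth <- make_sites(n_sites = n_sites, seed = seed)
  list(truth = truth,
       moist = simulate_chamber_series(truth, "moist", noise_sd = noise_sd,
                                       seed = seed + 1L),
       dry = simulate_chamber_series(truth, "dry", noise_sd = noise_sd,
                                     seed = seed + 2L),
       isotopes = simulate_isotopes(truth, noise_sd_delta = noise_sd_delta,
                                    seed = seed + 3L),
       community = simulate_community(truth, seed = seed + 4L, ...))
}
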