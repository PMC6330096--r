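# End-to-end orchestration: chamber series -> fluxes -> partition ->
# rate-constant inversion for both substrates -> biome summary ->
# community screens, with unit-carrying TSV input/output.

#' Pipeline configuration
#'
#' Thresholds and processing options for [run_pipeline()].
#'
#' @param rho_min,q_max Spearman screen thresholds.
#' @param depth_16s,depth_its2 Rarefaction depths for the two markers.
#' @param discard_initial Seconds discarded at the start of each chamber
#'   phase.
#' @param dilution_correct Apply the water-vapour dilution correction.
#' @param min_genome_gbp Genes from genomes below this size (Gbp) are
#'   excluded from the expression-rate correlations.
#' @return Named list of options.
#' @export
pipeline_config <- function(rho_min = 0.5, q_max = 0.01,
                            depth_16s = 40000, depth_its2 = 80000,
                            discard_initial = 120, dilution_correct = TRUE,
                            min_genome_gbp = 0.2) {
  stopifnot(rho_min > 0, rho_min <= 1, q_max > 0, q_max < 1)
  list(rho_min = rho_min, q_max = q_max, depth_16s = depth_16s,
       depth_its2 = depth_its2, discard_initial = discard_initial,
       dilution_correct = dilution_correct,
       min_genome_gbp = min_genome_gbp)
}

process_flux_stage <- function(runs_moist, runs_dry, truth, config) {
  ch <- truth$chamber
  reps <- truth$replicates
  missing_dry <- setdiff(names(runs_moist), names(runs_dry))
  if (length(missing_dry)) {
    stop("partition stage: missing dry-soil run(s) for replicate(s): ",
         paste(missing_dry, collapse = ", "))
  }
  rho_m <- pc_get("general", "P_atm") /
    (pc_get("general", "R_gas") * ch$temp_K)
  out <- lapply(seq_len(nrow(reps)), function(i) {
    id <- paste(reps$site[i], reps$replicate[i], sep = ".")
    fm <- chamber_fluxes(runs_moist[[id]], config$discard_initial,
                         config$dilution_correct)
    fd <- chamber_fluxes(runs_dry[[id]], config$discard_initial,
                         config$dilution_correct)
    ph <- summarize_phases(runs_moist[[id]], config$discard_initial,
                           config$dilution_correct)
    c_out_cos <- mean(ph$c_out[ph$gas == "cos"])  # mol mol^-1
    data.frame(site = reps$site[i], replicate = reps$replicate[i],
               biome = reps$biome[i],
               F_cos_net_pmol = fm$F_cos_pmol, F_cos_net_se = fm$F_cos_se,
               F_cos_dry_pmol = fd$F_cos_pmol, F_cos_dry_se = fd$F_cos_se,
               F_co2_umol = fm$F_co2_umol, F_co2_se = fm$F_co2_se,
               F_h2o_mmol = fm$F_h2o_mmol,
               cos_out_molm3 = c_out_cos * rho_m,
               n_cycles = fm$n_cycles,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a synthetic (or pre-built) study
#'
#' Executes every stage end-to-end: chamber flux computation for moist and
#' dry soils, COS partitioning, rate-constant inversion for COS and CO2,
#' biome aggregation, and the community screens. With only a seed, the
#' study inputs are generated by [simulate_study()].
#'
#' @param seed Integer seed (generates the synthetic study and fixes the
#'   rarefaction subsampling).
#' @param study Optional pre-built [simulate_study()] bundle; when `NULL`
#'   one is generated from `seed` with `...` passed through.
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every output table is
#'   written as a unit-annotated TSV.
#' @param ... Passed to [simulate_study()] when `study` is `NULL`.
#' @return List with `fluxes`, `partition`, `feq`, `rates`,
#'   `biome_summary`, `diversity`, `screens`, `tpm_correlations`, `truth`
#'   and `log`.
#' @export
run_pipeline <- function(seed = 1, study = NULL,
                         config = pipeline_config(), outdir = NULL, ...) {
  if (is.null(study)) study <- simulate_study(seed = seed, ...)
  truth <- study$truth
  ch <- truth$chamber

  fluxes <- process_flux_stage(study$moist$runs, study$dry$runs, truth,
                               config)
  part <- partition_cos(fluxes$F_cos_net_pmol, fluxes$F_cos_dry_pmol)
  partition <- cbind(fluxes[c("site", "replicate", "biome")], part)

  feq <- feq_table(study$isotopes)

  reps <- truth$replicates
  rates <- lapply(seq_len(nrow(fluxes)), function(i) {
    row <- reps[reps$site == fluxes$site[i] &
                  reps$replicate == fluxes$replicate[i], ]
    soil <- truth_soil_column(row, ch)
    rc <- invert_k_cos(F_net = fluxes$F_cos_net_pmol[i] * 1e-12,
                       F_dry = fluxes$F_cos_dry_pmol[i] * 1e-12,
                       C_a = fluxes$cos_out_molm3[i], soil = soil)
    fq <- feq[feq$site == fluxes$site[i] &
                feq$replicate == fluxes$replicate[i], ]
    r2 <- if (is.na(fq$feq)) {
      # equilibration jar flagged unconverged: no CO2 inversion possible
      structure(list(substrate = "CO2", k_total = NA_real_,
                     k_uncat = k_uncat_co2_iso(soil$T_K, soil$pH),
                     k_cat = NA_real_, f_CA = NA_real_,
                     solver_diagnostics = list(flags = "feq_unconverged")),
                class = "rate_result")
    } else {
      invert_k_co2(fq$feq,
                   soil = soil,
                   chamber = list(flow_lpm = ch$flow_lpm,
                                  C_i = fq$C_i_ppm, C_o = fq$C_o_ppm))
    }
    data.frame(site = fluxes$site[i], replicate = fluxes$replicate[i],
               biome = fluxes$biome[i],
               k_cos_total = rc$k_total, k_cos_uncat = rc$k_uncat,
               k_cos_cat = rc$k_cat,
               k_co2_total = r2$k_total, k_co2_uncat = r2$k_uncat,
               k_co2_cat = r2$k_cat,
               flags = paste(c(rc$solver_diagnostics$flags,
                               r2$solver_diagnostics$flags),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rates)
  biome_summary <- summarize_biomes(rates)

  # site-level recovered rates drive the ecological screens
  site_rates <- stats::aggregate(
    rates[c("k_cos_cat", "k_co2_cat")], by = list(site = rates$site),
    function(x) mean(x, na.rm = TRUE))
  site_rates <- site_rates[match(truth$sites$site, site_rates$site), ]

  comm <- study$community
  rar16 <- rarefy_counts(comm$otu_16s$counts, config$depth_16s,
                         seed = seed + 10L)
  rarits <- rarefy_counts(comm$otu_its2$counts, config$depth_its2,
                          seed = seed + 11L)
  diversity <- rbind(
    cbind(marker = "16S", alpha_diversity(rar16)),
    cbind(marker = "ITS2", alpha_diversity(rarits)))
  screens <- list()
  for (marker in c("16S", "ITS2")) {
    rar <- if (marker == "16S") rar16 else rarits
    rel <- rar / rowSums(rar)
    for (var in c("k_cos_cat", "k_co2_cat")) {
      v <- site_rates[[var]][match(rownames(rel), site_rates$site)]
      screens[[paste(marker, var, sep = ".")]] <-
        spearman_screen(rel, v, config$rho_min, config$q_max)
    }
  }

  tr <- comm$transcripts
  keep <- tr$genes$genome_gbp >= config$min_genome_gbp
  tpm <- tpm_normalize(tr$counts[, keep, drop = FALSE],
                       tr$genes$length_bp[keep])
  tr_rates <- site_rates[match(tr$sample_sites, site_rates$site), ]
  cls <- tr$genes$ca_class[keep]
  clade <- ifelse(is.na(tr$genes$clade[keep]), tr$genes$ca_class[keep],
                  tr$genes$clade[keep])
  tpm_correlations <- rbind(
    cbind(variable = "k_cos_cat", group_by = "clade",
          class_rate_correlation(tpm, clade, tr_rates$k_cos_cat)),
    cbind(variable = "k_co2_cat", group_by = "class",
          class_rate_correlation(tpm, cls, tr_rates$k_co2_cat)))

  out <- list(fluxes = fluxes, partition = partition, feq = feq,
              rates = rates, biome_summary = biome_summary,
              diversity = diversity, screens = screens,
              tpm_correlations = tpm_correlations, truth = truth,
              log = list(seed = seed, config = config,
                         package_version =
                           as.character(utils::packageVersion("soilCA")),
                         timestamp = format(Sys.time(), tz = "UTC")))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_units_table(fluxes, file.path(outdir, "fluxes.tsv"),
                      units = c(F_cos_net_pmol = "pmol m-2 s-1",
                                F_co2_umol = "umol m-2 s-1",
                                F_h2o_mmol = "mmol m-2 s-1",
                                cos_out_molm3 = "mol m-3"))
    write_units_table(partition, file.path(outdir, "partition.tsv"),
                      units = c(production = "pmol m-2 s-1",
                                consumption = "pmol m-2 s-1"))
    write_units_table(feq, file.path(outdir, "feq.tsv"),
                      units = c(C_i_ppm = "umol mol-1",
                                d18O_in = "permil VPDB-CO2"))
    write_units_table(rates, file.path(outdir, "rates.tsv"),
                      units = c(k_cos_cat = "s-1", k_co2_cat = "s-1"))
    write_units_table(biome_summary, file.path(outdir, "biome_summary.tsv"),
                      units = c(k_cos_cat_mean = "s-1"))
  }
  out
}

#' Write a table as TSV with a units header
#'
#' Writes `#units: col=unit; ...` as the first line, then a regular
#' tab-separated table.
#'
#' @param x data.frame.
#' @param path Output path.
#' @param units Named character vector mapping (a subset of) columns to
#'   unit strings.
#' @export
write_units_table <- function(x, path, units = character(0)) {
  if (length(units)) {
    bad <- setdiff(names(units), names(x))
    if (length(bad)) stop("units given for unknown column(s): ",
                          paste(bad, collapse = ", "))
    header <- paste0("#units: ",
                     paste(names(units), units, sep = "=", collapse = "; "))
    writeLines(header, path)
    suppressWarnings(utils::write.table(
      x, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a unit-annotated TSV
#'
#' Counterpart of [write_units_table()]; the parsed units are attached as
#' the `"units"` attribute. Optionally validates the column schema.
#'
#' @param path Input path.
#' @param required Character vector of columns that must be present.
#' @return data.frame with a `"units"` attribute.
#' @export
read_units_table <- function(path, required = character(0)) {
  first <- readLines(path, n = 1L)
  units <- character(0)
  if (startsWith(first, "#units:")) {
    spec <- strsplit(sub("^#units:\\s*", "", first), ";\\s*")[[1]]
    kv <- strsplit(spec, "=")
    units <- stats::setNames(vapply(kv, `[`, "", 2L),
                             vapply(kv, `[`, "", 1L))
  }
  x <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop(sprintf("table %s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  attr(x, "units") <- units
  x
}
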