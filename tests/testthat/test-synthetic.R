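# Synthetic-data generator: determinism, design shape, and exactness of
# the zero-noise round trips through the measurement operators.

test_that("site generation is deterministic and reproduces the 20-site triplicate design", {
  t1 <- make_sites(seed = 3)
  t2 <- make_sites(seed = 3)
  expect_identical(t1$sites, t2$sites)
  expect_equal(nrow(t1$sites), 20L)
  expect_equal(nrow(t1$replicates), 60L)
  expect_equal(unname(table(t1$replicates$replicate)), rep(20L, 3),
               ignore_attr = TRUE)
  expect_false(identical(t1$sites$k_cos_cat_true,
                         make_sites(seed = 4)$sites$k_cos_cat_true))
  expect_true(all(t1$sites$k_cos_cat_true > 0))
  expect_true(all(t1$sites$theta <= t1$sites$porosity))
  expect_error(make_sites(presets = biome_presets()[0, ]), "empty")
})

test_that("biome presets are positive and hold the fixed chamber design constants", {
  p <- biome_presets()
  expect_equal(sum(p$n_sites), 20L)
  expect_true(all(p$k_cos_cat > 0 & p$k_co2_cat > 0))
  ch <- chamber_defaults()
  expect_equal(ch$surface_m2, 0.0078)
  expect_equal(ch$cos_in_ppt, 450)
  expect_equal(ch$co2_in_ppm, 450)
  expect_equal(ch$d18O_water, 47.57)
})

test_that("noise-free chamber series are recovered exactly by the flux stage", {
  truth <- make_sites(seed = 5)
  zero_noise <- list(cos_ppt = 0, co2_ppm = 0, h2o_ppth = 0)
  sim <- simulate_chamber_series(truth, "moist", noise_sd = zero_noise,
                                 seed = 6)
  id <- names(sim$runs)[1]
  f <- chamber_fluxes(sim$runs[[id]])
  expect_equal(f$F_cos_pmol, sim$true$F_cos_net_pmol[1], tolerance = 1e-9)
  expect_equal(f$F_co2_umol, sim$true$F_co2_umol[1], tolerance = 1e-9)
  # zero net flux leaves outlet equal to inlet
  dry <- simulate_chamber_series(truth, "dry", noise_sd = zero_noise,
                                 seed = 6)
  desert <- which(truth$replicates$biome == "desert")[1]
  expect_equal(dry$true$F_cos_net_pmol[desert], 0)
  fd <- chamber_fluxes(dry$runs[[desert]])
  expect_equal(fd$F_cos_pmol, 0, tolerance = 1e-9)
})

test_that("flux standard errors match the analytic error of a phase mean", {
  truth <- make_sites(n_sites = 1, seed = 7)
  truth$replicates <- truth$replicates[1, ]
  noise <- list(cos_ppt = 5, co2_ppm = 0, h2o_ppth = 0)
  draws <- vapply(1:300, function(i) {
    sim <- simulate_chamber_series(truth, "moist", noise_sd = noise,
                                   seed = 1000 + i)
    unlist(chamber_fluxes(sim$runs[[1]])[c("F_cos_pmol", "F_cos_se")])
  }, numeric(2))
  empirical_sd <- sd(draws[1, ])
  mean_reported_se <- mean(draws[2, ])
  expect_equal(mean_reported_se, empirical_sd, tolerance = 0.15)
})

test_that("zero-noise isotope observations return the forward-model f_eq exactly", {
  truth <- make_sites(seed = 8)
  iso <- simulate_isotopes(truth, noise_sd_delta = 0, seed = 9)
  out <- feq_table(iso)
  expect_true(all(out$converged))
  expect_equal(out$feq, iso$feq_true, tolerance = 1e-12)
  # k = 0 would leave the outlet at the inlet composition
  truth0 <- truth
  truth0$replicates$k_co2_cat_true <- 0
  truth0$replicates$k_co2_uncat <- 0
  truth0$replicates$resp_umol <- 0
  iso0 <- simulate_isotopes(truth0, noise_sd_delta = 0, seed = 9)
  expect_equal(iso0$feq_true, rep(0, nrow(iso0)))
  expect_equal(iso0$d18O_out, iso0$d18O_in)
})

test_that("community tables are deterministic and plant detectable lineage links", {
  truth <- make_sites(seed = 10)
  c1 <- simulate_community(truth, seed = 12)
  c2 <- simulate_community(truth, seed = 12)
  expect_identical(c1$otu_16s$counts, c2$otu_16s$counts)
  expect_identical(c1$transcripts$counts, c2$transcripts$counts)
  expect_equal(sum(grepl("Fungi", c1$otu_its2$taxonomy[c1$otu_its2$planted])),
               19L)
  expect_equal(length(c1$otu_16s$planted), 2L)
  # planted ITS2 fungal OTUs pass the screen at the default effect size
  rel <- c1$otu_its2$counts / rowSums(c1$otu_its2$counts)
  res <- spearman_screen(rel, truth$sites$k_cos_cat_true)
  fungal <- c1$otu_its2$planted[grepl("Fungi",
                                      c1$otu_its2$taxonomy[c1$otu_its2$planted])]
  expect_gt(mean(res$hit[fungal]), 0.8)
  expect_lt(mean(res$hit[-c1$otu_its2$planted]), 0.02)
})

test_that("transcript generator plants the documented class and clade links", {
  truth <- make_sites(seed = 14)
  comm <- simulate_community(truth, seed = 15)
  tr <- comm$transcripts
  keep <- tr$genes$genome_gbp >= 0.2
  tpm <- tpm_normalize(tr$counts[, keep], tr$genes$length_bp[keep])
  k_cos <- truth$sites$k_cos_cat_true[match(tr$sample_sites,
                                            truth$sites$site)]
  k_co2 <- truth$sites$k_co2_cat_true[match(tr$sample_sites,
                                            truth$sites$site)]
  clade <- ifelse(is.na(tr$genes$clade[keep]), tr$genes$ca_class[keep],
                  tr$genes$clade[keep])
  res_cos <- class_rate_correlation(tpm, clade, k_cos)
  expect_gt(res_cos$r[res_cos$group == "beta-D"], 0.5)
  expect_lt(res_cos$p[res_cos$group == "beta-D"], 0.05)
  expect_lt(res_cos$r[res_cos$group == "beta-A"], 0)
  res_co2 <- class_rate_correlation(tpm, tr$genes$ca_class[keep], k_co2)
  expect_gt(res_co2$r[res_co2$group == "alpha"], 0.5)
})
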