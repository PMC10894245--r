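test_that("zero-effect subjects have identical latents only up to state noise", {
  m <- default_model()
  es <- null_effect_spec()
  es$condition_sd <- 0
  es$shifts$sd_subject <- 0
  rec <- sample_subject(m, es, seed = 3, spectra = FALSE)
  w <- tidyr::pivot_wider(rec$lambda, names_from = "condition",
                          values_from = "value")
  expect_equal(w$pre, w$bolus)
  expect_equal(w$pre, w$infusion)

  # with state noise the conditions differ, but with zero mean effect
  es2 <- null_effect_spec()
  rec2 <- sample_subject(m, es2, seed = 3, spectra = FALSE)
  w2 <- tidyr::pivot_wider(rec2$lambda, names_from = "condition",
                           values_from = "value")
  expect_false(isTRUE(all.equal(w2$pre, w2$infusion)))
})

test_that("subject records are reproducible per seed", {
  m <- default_model()
  g <- seq(8, 80, 8)
  r1 <- sample_subject(m, seed = 11, freqs = g)
  r2 <- sample_subject(m, seed = 11, freqs = g)
  expect_identical(r1$lambda, r2$lambda)
  expect_identical(r1$spectra$infusion$csd, r2$spectra$infusion$csd)
  expect_identical(r1$clinical, r2$clinical)
  expect_s3_class(r1$spectra$pre, "spectral_data")
  expect_identical(names(r1$spectra), c("pre", "bolus", "infusion"))
})

test_that("the planted forward-AMPA latent rises from pre to infusion in expectation", {
  m <- default_model()
  set.seed(55)
  z <- replicate(100, {
    rec <- sample_subject(m, seed = sample.int(1e6, 1), spectra = FALSE)
    w <- rec$lambda[rec$lambda$parameter == "ext_ampa_fwd", ]
    w$value[w$condition == "infusion"] - w$value[w$condition == "pre"]
  })
  expect_gt(mean(z), 0.2)
  expect_gt(t.test(z)$statistic, 5)
})

test_that("cohorts have the full design and a faithful manifest", {
  m <- default_model()
  co <- generate_cohort(n = 3, model = m, master_seed = 9, freqs = seq(8, 80, 8))
  expect_length(co$records, 3)
  specs <- unlist(lapply(co$records, function(r) r$spectra), recursive = FALSE)
  expect_length(specs, 9)
  expect_identical(sort(unique(co$manifest$subject)), 1:3)
  expect_identical(nrow(co$clinical), 3L)
  # manifest mirrors the per-record latents
  expect_identical(co$manifest, purrr::map_dfr(co$records, "lambda"))
  # latent-only cohorts support n = 27 cheaply
  col <- generate_cohort(n = 27, model = m, master_seed = 2, spectra = FALSE)
  expect_identical(nrow(col$manifest), 27L * 3L * sum(m$priors$prior_var > 0))
  expect_error(generate_cohort(n = 2, model = m, spectra = FALSE),
               "at least 3")
})

test_that("clinical couplings calibrate to their target correlations", {
  es <- effect_spec()
  es0 <- calibrate_clinical_coupling(es, 0, "ext_ampa_fwd", "change_24h")
  expect_equal(es0$couplings$r[es0$couplings$parameter == "ext_ampa_fwd" &
                                 es0$couplings$timepoint == "change_24h"], 0)
  expect_error(calibrate_clinical_coupling(es, 1), "residual")
  expect_error(calibrate_clinical_coupling(es, -1), "residual")
  expect_error(calibrate_clinical_coupling(es, 0.95, "kappa_frontal_gaba"),
               "infeasible")

  # Monte-Carlo: mean sample correlation between the realized planted shift
  # and the 24 h clinical change approaches the calibrated 0.43
  m <- default_model()
  set.seed(19)
  rs <- replicate(150, {
    co <- generate_cohort(27, m, master_seed = sample.int(1e6, 1),
                          spectra = FALSE)
    d <- co$manifest[co$manifest$parameter == "ext_ampa_fwd", ]
    z <- d$value[d$condition == "infusion"] - d$value[d$condition == "pre"]
    cor(z, co$clinical$change_24h)
  })
  expect_lt(abs(mean(rs) - 0.43), 0.05)
})

test_that("observation noise preserves Hermitian structure at the right scale", {
  s <- coarse_truth()
  set.seed(23)
  sn <- add_csd_noise(s, 0.05)
  expect_s3_class(sn, "spectral_data")  # constructor enforces Hermitian PSD diag
  rel <- abs(Re(sn$csd[1, 1, ]) - Re(s$csd[1, 1, ])) / Re(s$csd[1, 1, ])
  expect_lt(stats::median(rel), 0.2)
  expect_gt(stats::median(rel), 0.005)
})
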