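test_that("featurization counts, inverts and round-trips", {
  s <- coarse_truth()
  v <- featurize(s)
  expect_length(v, 6 * length(s$freq))
  expect_equal(as.numeric(v) - as.numeric(featurize(s)), rep(0, length(v)))

  s2 <- defeaturize(v, s$freq)
  expect_equal(s2$csd, s$csd, tolerance = 1e-12)

  v5 <- featurize(s, scale = 5)
  expect_equal(defeaturize(v5, s$freq)$csd, s$csd, tolerance = 1e-12)

  bad <- s; bad$csd[1, 1, 1] <- NaN
  class(bad) <- "spectral_data"
  expect_error(featurize(bad), "NaN")
})

test_that("the KL complexity term is exactly zero at posterior = prior", {
  set.seed(8)
  A <- crossprod(matrix(rnorm(25), 5))
  mu <- rnorm(5)
  expect_identical(kl_gaussian(mu, A, mu, A), 0)
  expect_gt(kl_gaussian(mu + 0.1, A, mu, A), 0)
})

test_that("free energy matches the conjugate closed form for a linear model", {
  # y = a * lambda + e, e ~ N(0, s2), prior lambda ~ N(0, v):
  # log evidence = log N(y; 0, s2 + a^2 v)
  a <- 1.7; s2 <- 0.3; v <- 2.0; y <- 0.9
  h <- log(1 / s2)
  priors <- structure(list(names = "x", mu0 = c(x = 0),
                           Sigma0 = matrix(v), h0 = NA, s_h = 16),
                      class = "prior_spec")
  post_var <- 1 / (a^2 / s2 + 1 / v)
  post_mu <- post_var * a * y / s2
  e <- y - a * post_mu
  Fv <- laplace_free_energy(e, matrix(a), post_mu, priors, h)
  log_ev <- dnorm(y, 0, sqrt(s2 + a^2 * v), log = TRUE)
  expect_equal(as.numeric(Fv), log_ev, tolerance = 1e-6)

  # an irrelevant extra parameter (zero Jacobian column, prior variance > 0)
  # does not increase the free energy
  priors2 <- structure(list(names = c("x", "z"), mu0 = c(x = 0, z = 0),
                            Sigma0 = diag(c(v, 0.5)), h0 = NA, s_h = 16),
                       class = "prior_spec")
  F2 <- laplace_free_energy(e, cbind(matrix(a), 0), c(post_mu, 0), priors2, h)
  expect_lt(as.numeric(F2) - as.numeric(Fv), 1e-3)

  # scaling the residual up strictly decreases the free energy
  Fbig <- laplace_free_energy(e + 0.5, matrix(a), post_mu, priors, h)
  expect_lt(as.numeric(Fbig), as.numeric(Fv))
})

test_that("variance explained has its defining anchors", {
  s <- coarse_truth()
  expect_equal(variance_explained(s, s), 100)
  # any prediction scores 100 (1 - SS_res / SS_tot) on mean-centered
  # features; a constant prediction at the feature mean would score 0
  v <- featurize(s)
  flat <- defeaturize(rep(mean(v), length(v)), s$freq)
  g <- as.numeric(featurize(flat))
  manual <- 100 * (1 - sum((g - v)^2) / sum((v - mean(v))^2))
  expect_equal(variance_explained(flat, s), manual, tolerance = 1e-10)
  expect_lt(abs(manual), 5)  # near zero: only the diagonal phases deviate
})

test_that("noise-free self-inversion recovers the generating parameters", {
  fit <- coarse_self_fit()
  expect_gte(fit$variance_explained, 99)
  expect_lt(max(abs(fit$mu)), 0.05)
  expect_true(fit$converged)
  # posterior covariance is positive semidefinite
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10 * max(ev)))
  # free-energy trace never decreases over accepted steps
  expect_false(is.unsorted(fit$trace))
})

test_that("inversion is deterministic given data and configuration", {
  s <- coarse_truth()
  set.seed(77)
  dat <- add_csd_noise(s, 0.05)
  ctl <- invert_control(max_iter = 8)
  f1 <- invert_csd(dat, default_model(), control = ctl)
  f2 <- invert_csd(dat, default_model(), control = ctl)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$free_energy, f2$free_energy)
  expect_false(is.unsorted(f1$trace))
})

test_that("a planted forward-AMPA increase is recovered across noise draws", {
  m <- default_model()
  truth <- predict_csd(m, tcm_lambda(m, ext_ampa_fwd = 0.3),
                       freqs = coarse_grid())
  base <- coarse_self_fit()$mu["ext_ampa_fwd"]
  hits <- 0
  for (sd_ in 1:5) {
    set.seed(sd_)
    fit <- invert_csd(add_csd_noise(truth, 0.05), m)
    if (fit$mu["ext_ampa_fwd"] > base + 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
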