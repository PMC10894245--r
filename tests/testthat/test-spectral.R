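test_that("analytic Jacobian matches finite differences and decoupled form", {
  m <- default_model()
  fp <- as.numeric(find_fixed_point(m))
  J <- tcm_jacobian(fp, m)
  num <- matrix(0, 64, 64)
  for (j in 1:64) {
    h <- 1e-6 * max(1, abs(fp[j]))
    xp <- fp; xp[j] <- xp[j] + h
    xm <- fp; xm[j] <- xm[j] - h
    num[, j] <- (state_derivative(xp, m) - state_derivative(xm, m)) / (2 * h)
  }
  expect_lt(max(abs(num - J)) / max(abs(J)), 1e-5)

  md <- decoupled_model()
  fpd <- as.numeric(find_fixed_point(md))
  Jd <- tcm_jacobian(fpd, md)
  cn <- md$constants
  th <- tcdcm:::tcm_theta(md)
  expect_equal(diag(Jd)[1:16], rep(-cn$g_L / cn$C, 16))
  expect_equal(diag(Jd)[17:32],
               unname(-th[paste0("kappa_", c(rep("frontal", 8),
                                             rep("parietal", 8)), "_ampa")]))
  # off-diagonal blocks vanish except the conductance-to-voltage leak terms
  Jd_offdiag <- Jd; Jd_offdiag[cbind(1:64, 1:64)] <- 0
  Jd_offdiag[1:16, 17:64] <- 0
  expect_equal(max(abs(Jd_offdiag)), 0)
})

test_that("the transfer function is proper, finite and linear in electrode gain", {
  m <- default_model()
  H <- transfer_function(m, freqs = 4:90)
  expect_true(all(is.finite(Mod(H))))
  Hfar <- transfer_function(m, freqs = 1e6)
  expect_lt(max(Mod(Hfar)), 1e-6 * max(Mod(H)))

  H2 <- transfer_function(m, tcm_lambda(m, L_frontal = log(2)), freqs = 4:90)
  expect_equal(Mod(H2[1, , ]), 2 * Mod(H[1, , ]), tolerance = 1e-8)
  expect_equal(Mod(H2[2, , ]), Mod(H[2, , ]), tolerance = 1e-8)
})

test_that("predicted cross-spectra are Hermitian positive semidefinite", {
  m <- default_model()
  set.seed(31)
  checked <- 0
  while (checked < 25) {
    lam <- stable_draw(m)
    if (is.null(lam)) next
    s <- predict_csd(m, lam, freqs = seq(4, 90, 4))
    expect_equal(s$csd[1, 2, ], Conj(s$csd[2, 1, ]))
    for (k in seq_along(s$freq)) {
      ev <- eigen(s$csd[, , k], only.values = TRUE)$values
      expect_true(all(Re(ev) >= -1e-10 * max(abs(s$csd[, , k]))))
    }
    checked <- checked + 1
  }
})

test_that("without a shared signal path the cross-spectrum is the common noise", {
  m <- default_model()
  m$edges <- m$edges[m$edges$from_node == m$edges$to_node, ]  # cut extrinsics
  s <- predict_csd(m, freqs = seq(4, 90, 2))
  lvl <- m$constants$innovation_scale
  th <- tcdcm:::tcm_theta(m)
  common <- lvl * th[["alpha_c"]] * s$freq^(-th[["beta_c"]])
  expect_equal(Re(s$csd[1, 2, ]), unname(common), tolerance = 1e-10)
  expect_equal(max(abs(Im(s$csd[1, 2, ]))), 0, tolerance = 1e-25)

  m$priors$value[m$priors$name == "alpha_c"] <- 0
  s0 <- predict_csd(m, freqs = seq(4, 90, 2))
  expect_equal(max(Mod(s0$csd[1, 2, ])), 0, tolerance = 1e-25)
})

test_that("innovation amplitude scales the signal spectrum linearly", {
  m <- default_model()
  s1 <- predict_csd(m, freqs = seq(4, 90, 2), noise = FALSE)
  lam <- tcm_lambda(m, alpha_u_frontal = log(3), alpha_u_parietal = log(3))
  s3 <- predict_csd(m, lam, freqs = seq(4, 90, 2), noise = FALSE)
  expect_equal(s3$csd, 3 * s1$csd, tolerance = 1e-8)
})

test_that("band integration of a flat unit spectrum returns band widths", {
  bt <- band_table()
  f <- 1:90
  flat <- rep(1, length(f))
  for (i in seq_len(nrow(bt))) {
    expect_equal(tcdcm:::band_integral(f, flat, bt$lo[i], bt$hi[i]),
                 bt$hi[i] - bt$lo[i])
  }
})

test_that("planted drug effects shift the spectral fingerprint as expected", {
  m <- default_model()
  lam0 <- tcm_lambda(m)
  same <- spectral_fingerprint_shift(m, lam0, lam0)
  expect_equal(same$shift, rep(0, nrow(same)))

  lamk <- tcm_lambda(m, ext_ampa_fwd = 0.3, kappa_frontal_gaba = 0.25)
  fp <- spectral_fingerprint_shift(m, lam0, lamk)
  gamma_frontal <- sum(fp$shift[fp$node == "frontal" &
                                  fp$band %in% c("low_gamma", "high_gamma")])
  expect_gt(gamma_frontal, 0)
})

test_that("a long low-noise simulation reproduces the analytic spectrum", {
  m <- default_model()
  sim <- simulate_tcm(m, duration = 60000, dt = 0.1, noise_scale = 1,
                      seed = 42)
  sw <- welch_csd(epoch_series(sim$obs, sim$rate), grid = 4:90)
  sp <- predict_csd(m, freqs = 4:90, noise = FALSE)
  f <- sp$freq
  bt <- band_table(); bt <- bt[bt$lo >= 4, ]
  for (i in seq_len(nrow(bt))) {
    sel <- f >= bt$lo[i] & f < bt$hi[i]
    for (ch in 1:2) {
      w <- mean(Re(sw$csd[ch, ch, sel]))
      p <- mean(Re(sp$csd[ch, ch, sel]))
      expect_lt(abs(w - p) / p, 0.2)
    }
  }
})
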