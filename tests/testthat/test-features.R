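test_that("epoching cuts exact 2200 ms segments and drops the remainder", {
  set.seed(5)
  x <- matrix(rnorm(5000 * 2), ncol = 2)  # 10 s at 500 Hz
  ep <- epoch_series(x, 500)
  expect_identical(dim(ep$data), c(4L, 2L, 1100L))
  expect_equal(ep$data[2, 1, ], x[1101:2200, 1])

  # 7-minute pre block: floor(420 / 2.2) epochs
  long <- matrix(rnorm(420 * 100), ncol = 1)
  expect_identical(dim(epoch_series(long, 100)$data)[1], 190L)

  expect_error(epoch_series(x[1:100, ], 500), "shorter")
})

test_that("epochs straddling a boundary go to the earlier condition iff half precede", {
  x <- matrix(0, 2500, 1)  # 5 s at 500 Hz: epochs at [0,2.2), [2.2,4.4)
  # boundary at 3.3 s = exactly the midpoint of epoch 2 -> earlier condition
  ep <- epoch_series(x, 500, boundaries = 3.3)
  expect_identical(ep$epochs$condition, c("pre", "pre"))
  # boundary just before the midpoint -> majority after -> later condition
  ep2 <- epoch_series(x, 500, boundaries = 3.29)
  expect_identical(ep2$epochs$condition, c("pre", "bolus"))
  # three blocks
  ep3 <- epoch_series(matrix(0, 5000, 1), 500, boundaries = c(2.2, 4.4))
  expect_identical(ep3$epochs$condition, c("pre", "bolus", "infusion", "infusion"))
})

test_that("Welch cross-spectra behave for white noise and identical channels", {
  set.seed(6)
  rate <- 500
  n <- 500 * 1100  # 500 epochs
  a <- rnorm(n); b <- rnorm(n)
  ep <- epoch_series(cbind(a, b), rate)
  s <- welch_csd(ep, grid = seq(4, 240, 4))
  coh <- Mod(s$csd[1, 2, ])^2 / (Re(s$csd[1, 1, ]) * Re(s$csd[2, 2, ]))
  expect_lt(max(coh), 0.1)
  # unit-variance white noise: flat one-sided density of 2 * dt
  expect_lt(max(abs(Re(s$csd[1, 1, ]) - 2 / rate)) / (2 / rate), 0.15)
  # Parseval: integrated density recovers the variance
  full <- welch_csd(ep, grid = seq(1, 249, 1))
  expect_equal(sum(Re(full$csd[1, 1, ])) * 1, var(a), tolerance = 0.05)

  sid <- welch_csd(epoch_series(cbind(a, a), rate), grid = seq(4, 240, 4))
  cohid <- Mod(sid$csd[1, 2, ])^2 / (Re(sid$csd[1, 1, ]) * Re(sid$csd[2, 2, ]))
  expect_equal(cohid, rep(1, length(cohid)), tolerance = 1e-9)

  expect_error(welch_csd(epoch_series(cbind(a, b)[1:(4 * 1100), ], rate)),
               "at least 8 epochs")
})

test_that("the band filter passes in-band and rejects far out-of-band tones", {
  rate <- 500
  t <- seq(0, 10, by = 1 / rate)
  keep <- seq(1000, length(t) - 1000)  # avoid filter edges
  in_band <- sin(2 * pi * 10 * t)
  f_in <- band_filter(in_band, "alpha", rate)
  expect_gt(max(abs(f_in[keep])) , 0.95)

  out_band <- sin(2 * pi * 50 * t)
  f_out <- band_filter(out_band, "alpha", rate)
  expect_lt(max(abs(f_out[keep])), 0.01)

  # zero phase: cross-correlation with the raw tone peaks at lag 0
  cc <- stats::ccf(f_in[keep], in_band[keep], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)

  expect_error(band_filter(in_band, c(200, 260), rate), "Nyquist")
})

test_that("the Hilbert envelope mean recovers oscillation amplitudes", {
  rate <- 500
  t <- seq(0, 4, by = 1 / rate)
  A <- 2.5
  expect_equal(hilbert_envelope_mean(A * sin(2 * pi * 10 * t)), A,
               tolerance = 0.01)
  am <- A * (1 + 0.5 * cos(2 * pi * 1 * t)) * sin(2 * pi * 20 * t)
  expect_equal(hilbert_envelope_mean(am), A, tolerance = 0.05)
  expect_equal(hilbert_envelope_mean(rep(0, 1000)), 0)
  expect_error(hilbert_envelope_mean(rnorm(100)), "256")
})

test_that("delimited-text series and trajectories round-trip", {
  x <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("frontal", "parietal")))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  y <- read_series_text(path)
  expect_equal(unname(y), unname(x), tolerance = 1e-12)

  sim <- simulate_tcm(default_model(), duration = 100, seed = 3,
                      keep_states = TRUE, thin = 10)
  td <- tidy(sim)
  expect_identical(names(td), c("time", "node", "population", "V"))
  expect_identical(nrow(td), 16L * nrow(sim$traj))
  expect_error(tidy(simulate_tcm(default_model(), duration = 50, seed = 3)),
               "keep_states")
})
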