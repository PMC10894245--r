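test_that("the default model has two nodes, eight populations, 64 states", {
  m <- default_model()
  expect_s3_class(m, "tcm_model")
  expect_identical(nrow(m$nodes), 2L)
  expect_identical(m$nodes$mni[[1]], c(-12L, 36L, 60L))
  expect_identical(m$nodes$mni[[2]], c(-24L, -66L, 66L))
  expect_identical(m$populations$label,
                   c("SP", "SI", "SS", "DP", "DI", "TP", "RT", "RL"))
  expect_identical(m$populations$excitatory,
                   c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_length(find_fixed_point(m), 64)

  # receptor time-constant ordering at prior means: AMPA < GABA-A < NMDA
  th <- tcdcm:::tcm_theta(m)
  for (nd in c("frontal", "parietal")) {
    taus <- 1 / th[paste0("kappa_", nd, c("_ampa", "_gaba", "_nmda"))]
    expect_true(taus[1] < taus[2] && taus[2] < taus[3])
  }
  expect_error(tcm_model(3), "two-node")
})

test_that("inhibitory populations project only through GABA-A", {
  e <- default_model()$edges
  pops <- default_model()$populations
  inh <- pops$label[!pops$excitatory]
  expect_true(all(e$receptor[e$from %in% inh] == "GABA"))
  expect_true(all(e$g0 >= 0))
  # forward extrinsics target granular populations, backward superficial
  ext <- e[e$from_node != e$to_node, ]
  expect_true(all(ext$to[ext$to_node == 1] %in% c("SS", "DP")))
  expect_true(all(ext$to[ext$to_node == 2] %in% c("SP", "SI")))
})

test_that("firing rate is zero at rest, saturates, and is strictly increasing", {
  for (r1 in c(0.2, 2 / 3, 1.5)) {
    for (r2 in c(-3, 0, 3)) {
      expect_equal(firing_rate(0, r1, r2), 0)
    }
  }
  sigma0 <- 1 / (1 + exp((2 / 3) * 3))
  expect_equal(firing_rate(1e6, 2 / 3, 3), 1 - sigma0, tolerance = 1e-12)
  grid <- seq(-100, 100, length.out = 1000)
  rates <- firing_rate(grid, 2 / 3, 3)
  expect_true(all(diff(rates) >= 0))
  # strictly increasing wherever the double-precision tails have not
  # underflown to ties
  mid <- abs(grid) <= 30
  expect_true(all(diff(rates[mid]) > 0))
  expect_error(firing_rate(0, rho1 = -1), "positive")
})

test_that("Mg block matches its closed form and is monotone in (0,1)", {
  expect_equal(mg_block(0, 0.06), 1 / 1.2, tolerance = 1e-12)
  expect_equal(mg_block(-70, 0.06), 1 / (1 + 0.2 * exp(4.2)), tolerance = 1e-12)
  expect_equal(mg_block(1e5, 0.06), 1, tolerance = 1e-10)
  grid <- seq(-120, 60, length.out = 1000)
  vals <- mg_block(grid, 0.06)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_error(mg_block(0, alpha = 0), "positive")
})

test_that("state derivative vanishes at equilibria and rejects bad input", {
  m <- default_model()
  fp <- find_fixed_point(m)
  expect_lt(max(abs(state_derivative(as.numeric(fp), m))), 1e-8)

  md <- decoupled_model()
  leak <- c(rep(md$constants$V_L, 16), rep(0, 48))
  expect_equal(state_derivative(leak, md), rep(0, 64))
  expect_identical(as.numeric(find_fixed_point(md)), leak)

  expect_error(state_derivative(c(NaN, leak[-1]), m), "finite")
})

test_that("one Euler step of the integrator matches the state derivative", {
  m <- default_model()
  fp <- as.numeric(find_fixed_point(m))
  x0 <- fp + 0.25  # displaced state: nontrivial derivative
  dt <- 1e-3
  sim <- simulate_tcm(m, duration = dt, dt = dt, noise_scale = 0, x0 = x0,
                      keep_states = TRUE, thin = 1)
  # at step one all delay-lagged rates equal the current rate, so the Euler
  # step is exactly x0 + dt * f(x0)
  x1 <- sim$final_state
  expect_equal((x1 - x0) / dt, state_derivative(x0, m), tolerance = 1e-8)
})

test_that("fixed point is reproducible, accurate, and locally attracting", {
  m <- default_model()
  fp <- find_fixed_point(m)
  expect_lt(attr(fp, "residual"), 1e-8)
  expect_identical(as.numeric(fp), as.numeric(find_fixed_point(m)))

  ev <- eigen(tcm_jacobian(as.numeric(fp), m), only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
  set.seed(4)
  x0 <- as.numeric(fp) + rnorm(64, 0, 0.05)
  sim <- simulate_tcm(m, duration = 1500, dt = 0.1, noise_scale = 0, x0 = x0)
  expect_lt(max(abs(sim$final_state - as.numeric(fp))),
            0.1 * max(abs(x0 - as.numeric(fp))))
})

test_that("fixed points exist for nearly all prior-plausible draws", {
  m <- default_model()
  set.seed(101)
  fails <- 0
  for (i in 1:100) {
    lam <- tryCatch(stable_draw(m), error = function(e) NULL)
    if (is.null(lam)) { fails <- fails + 1; next }
    fp <- find_fixed_point(m, lam)
    expect_lt(attr(fp, "residual"), 1e-8)
  }
  expect_lt(fails, 5)
})

test_that("simulation is deterministic per seed and respects physics", {
  m <- default_model()
  s1 <- simulate_tcm(m, duration = 500, seed = 7)
  s2 <- simulate_tcm(m, duration = 500, seed = 7)
  expect_identical(s1$obs, s2$obs)
  s3 <- simulate_tcm(m, duration = 500, seed = 8)
  expect_false(identical(s1$obs, s3$obs))

  # noiseless start at the fixed point stays there (each node constant)
  s0 <- simulate_tcm(m, duration = 200, noise_scale = 0)
  expect_lt(max(abs(sweep(s0$obs, 2, s0$obs[1, ]))), 1e-8)

  # conductances stay nonnegative over a long stochastic run
  s10 <- simulate_tcm(m, duration = 10000, seed = 12, keep_states = TRUE,
                      thin = 50)
  expect_true(all(s10$traj[, 17:64] >= 0))
  expect_error(simulate_tcm(m, duration = 100, dt = 1), "0.5 ms")
})
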