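#' Seven-band frequency table
#'
#' The band definitions used throughout the spectral analyses: delta 1-4,
#' theta 4-8, alpha 8-13, low beta 15-26, high beta 28-40, low gamma 42-53
#' and high gamma 55-67 Hz (gaps avoid MR slice-artifact harmonics).
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
band_table <- function() {
  tibble::tribble(
    ~band,        ~lo, ~hi,
    "delta",        1,   4,
    "theta",        4,   8,
    "alpha",        8,  13,
    "low_beta",    15,  26,
    "high_beta",   28,  40,
    "low_gamma",   42,  53,
    "high_gamma",  55,  67
  )
}

# rectangle integral of `values` sampled on `freq` over [lo, hi)
band_integral <- function(freq, values, lo, hi) {
  df <- if (length(freq) > 1) stats::median(diff(freq)) else 1
  sel <- freq >= lo & freq < hi
  sum(values[sel]) * df
}

# linearization bundle: fixed point + delay-resolved Jacobian blocks;
# errors if the full (zero-lag) Jacobian has any eigenvalue with
# nonnegative real part, since no stationary spectrum exists then.
tcm_linearize <- function(model, lambda = NULL, x0 = NULL) {
  asm <- tcm_assemble(model, lambda)
  fp <- find_fixed_point(model, lambda, x0 = x0)
  jb <- jacobian_assembled(fp, asm)
  A_full <- jb$A0 + jb$delayed$`1` + jb$delayed$`8`
  ev <- eigen(A_full, only.values = TRUE)$values
  worst <- ev[which.max(Re(ev))]
  if (Re(worst) >= 0) {
    stop("unstable linearization: eigenvalue ", format(worst, digits = 4),
         " has nonnegative real part", call. = FALSE)
  }
  list(asm = asm, fp = fp, jb = jb, eigenvalues = ev)
}

#' Transfer function from innovation sources to observed nodes
#'
#' Linearizes the model at its fixed point and evaluates
#' \eqn{H(\omega) = L J (i\omega I - A(\omega))^{-1} B} on a frequency grid,
#' where A carries the transmission delays as exact frequency-domain phase
#' factors and B routes each node's innovation stream into the AMPA
#' afferents of its spiny stellate and thalamic relay populations.
#'
#' @inheritParams state_derivative
#' @param freqs Frequency grid (Hz).
#' @return Complex array `2 x 2 x length(freqs)` (observed node x innovation
#'   source x frequency), with the fixed point as attribute `"fp"`.
#' @export
transfer_function <- function(model, lambda = NULL, freqs = 4:90) {
  lin <- tcm_linearize(model, lambda)
  H <- cpp_transfer(lin$jb$A0, lin$jb$delayed$`1`, lin$jb$delayed$`8`,
                    lin$asm$B, lin$asm$Cmat, as.numeric(freqs),
                    lin$jb$delays[["1"]], lin$jb$delays[["8"]])
  structure(H, fp = as.numeric(lin$fp), eigenvalues = lin$eigenvalues)
}

innovation_spectrum <- function(asm, freqs) {
  lvl <- asm$cn$innovation_scale
  sapply(1:2, function(n) lvl * asm$alpha_u[n] * freqs^(-asm$beta_u))
}

#' Predict the model's cross-spectral density
#'
#' The generative forward model for inversion: the linearized transfer
#' function filters parameterized pink-spectrum innovations,
#' \eqn{S(\omega) = H(\omega) G_u(\omega) H(\omega)^* } plus (optionally)
#' channel-specific and common observation-noise spectra. The result is
#' Hermitian positive semidefinite at every frequency.
#'
#' @inheritParams transfer_function
#' @param noise Include channel and common observation-noise spectra.
#' @param subject,condition Metadata passed to [spectral_data()].
#' @return A [spectral_data()] object.
#' @export
predict_csd <- function(model, lambda = NULL, freqs = 4:90, noise = TRUE,
                        subject = NA, condition = NA) {
  lin <- tcm_linearize(model, lambda)
  freqs <- as.numeric(freqs)
  H <- cpp_transfer(lin$jb$A0, lin$jb$delayed$`1`, lin$jb$delayed$`8`,
                    lin$asm$B, lin$asm$Cmat, freqs,
                    lin$jb$delays[["1"]], lin$jb$delays[["8"]])
  Gu <- innovation_spectrum(lin$asm, freqs)
  S <- array(NA_complex_, c(2, 2, length(freqs)))
  for (k in seq_along(freqs)) {
    Hk <- H[, , k]
    Sk <- Hk %*% diag(Gu[k, ]) %*% Conj(t(Hk))
    if (noise) {
      ns <- lin$asm$noise
      lvl <- lin$asm$cn$innovation_scale
      chan <- lvl * (ns[["alpha_s"]] * freqs[k]^(-ns[["beta_s"]]) +
                       ns[["alpha_w"]])
      comm <- lvl * ns[["alpha_c"]] * freqs[k]^(-ns[["beta_c"]])
      Sk <- Sk + diag(chan, 2) + matrix(comm, 2, 2)
    }
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  spectral_data(freqs, S, subject = subject, condition = condition)
}

#' Simulate the model in the time domain
#'
#' Euler-Maruyama integration of the full nonlinear model with transmission
#' delays, driven by per-node innovation streams whose spectra match the
#' model's parameterized innovation spectrum \eqn{G_u(f) = \alpha_u
#' f^{-\beta_u}} (realized by FFT-coloring white noise; frequencies below
#' 0.5 Hz are capped). With `noise_scale = 1` the observed series has,
#' in the linear regime, the one-sided Welch cross-spectral density
#' predicted by [predict_csd()] without observation noise;
#' `noise_scale` multiplies the innovation amplitude (its square scales
#' spectral power).
#'
#' @inheritParams state_derivative
#' @param duration Simulated time (ms); at least 1000 ms for spectral use.
#' @param dt Integration step (ms), at most 0.5.
#' @param noise_scale Multiplier on the innovation amplitude; 0 gives a
#'   deterministic trajectory.
#' @param seed Optional RNG seed: the same seed yields identical output.
#' @param x0 Initial state; defaults to the fixed point.
#' @param keep_states Keep a (thinned) copy of the full state trajectory.
#' @param thin Keep every `thin`-th sample of the state trajectory.
#' @return List of class `tcm_simulation` with elements `time` (ms), `obs`
#'   (samples x 2 observed series), `rate` (sampling rate, Hz), `final_state`
#'   and optionally `traj`.
#' @export
simulate_tcm <- function(model, lambda = NULL, duration = 2000, dt = 0.1,
                         noise_scale = 1, seed = NULL, x0 = NULL,
                         keep_states = FALSE, thin = 10L) {
  if (dt > 0.5) stop("integration step dt must be at most 0.5 ms", call. = FALSE)
  asm <- tcm_assemble(model, lambda)
  if (is.null(x0)) x0 <- as.numeric(find_fixed_point(model, lambda))
  n_steps <- round(duration / dt)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(0, 2, n_steps)
  if (noise_scale > 0) {
    lvl <- asm$cn$innovation_scale
    for (n in 1:2) {
      u[n, ] <- noise_scale * colored_noise(n_steps, dt,
                                            lvl * asm$alpha_u[n], asm$beta_u)
    }
  }
  pops <- model$populations$label
  noise_rows <- c(match("SS", pops), match("RL", pops),
                  8 + match("SS", pops), 8 + match("RL", pops))
  lag1 <- max(1L, round(asm$cn$delay_intrinsic / dt))
  lag8 <- max(1L, round(asm$cn$delay_extrinsic / dt))
  out <- cpp_integrate(asm$W$AMPA$`1`, asm$W$AMPA$`8`,
                       asm$W$NMDA$`1`, asm$W$NMDA$`8`,
                       asm$W$GABA$`1`, asm$W$GABA$`8`,
                       asm$kappa, asm$Cmat, x0, asm$cn,
                       asm$drive, dt, n_steps, u, as.integer(noise_rows),
                       lag1, lag8, as.integer(thin), keep_states)
  structure(list(
    time = dt * seq_len(n_steps), obs = t(out$obs), rate = 1000 / dt,
    final_state = as.numeric(out$state),
    traj = if (keep_states) t(out$traj) else NULL,
    dt = dt, thin = as.integer(thin), noise_scale = noise_scale
  ), class = "tcm_simulation")
}

# FFT-colored real noise: length-n sequence at step dt (ms) whose one-sided
# per-Hz spectral density is `level * f^-beta` when driven through
# unit-gain dynamics in ms time (the factor 500 converts the per-Hz level
# to the two-sided per-(cycles/ms) density of the drive).
colored_noise <- function(n, dt, level, beta, f_min = 0.5) {
  j <- 0:(n - 1)
  jj <- pmin(j, n - j)
  f_hz <- pmax(jj / (n * dt) * 1000, f_min)
  Q <- 500 * level * f_hz^(-beta)
  w <- stats::rnorm(n)
  Re(stats::fft(stats::fft(w) * sqrt(Q / dt), inverse = TRUE)) / n
}

#' Band-wise spectral shift between two parameter sets
#'
#' Integrates each node's auto-spectral amplitude over the seven canonical
#' bands for two parameter sets and returns the drug-minus-baseline change
#' per band and node; a qualitative surface for checking the direction of
#' planted pharmacological effects.
#'
#' @inheritParams transfer_function
#' @param lambda_pre,lambda_drug Latent vectors of the two states.
#' @return Tibble with columns `band`, `node`, `pre`, `drug`, `shift`.
#' @export
spectral_fingerprint_shift <- function(model, lambda_pre, lambda_drug,
                                       freqs = 1:90) {
  s_pre <- predict_csd(model, lambda_pre, freqs, noise = FALSE)
  s_drug <- predict_csd(model, lambda_drug, freqs, noise = FALSE)
  bt <- band_table()
  purrr::map_dfr(seq_len(nrow(bt)), function(b) {
    purrr::map_dfr(1:2, function(n) {
      p <- band_integral(freqs, abs(Re(s_pre$csd[n, n, ])), bt$lo[b], bt$hi[b])
      d <- band_integral(freqs, abs(Re(s_drug$csd[n, n, ])), bt$lo[b], bt$hi[b])
      tibble::tibble(band = bt$band[b], node = model$nodes$name[n],
                     pre = p, drug = d, shift = d - p)
    })
  })
}

#' Tidy a simulation into a long trajectory table
#'
#' One row per kept sample, node and population with the membrane potential;
#' requires the simulation to have been run with `keep_states = TRUE`.
#'
#' @param x A `tcm_simulation`.
#' @param ... Unused.
#' @return Tibble with `time` (ms), `node`, `population`, `V` (mV).
#' @export
tidy.tcm_simulation <- function(x, ...) {
  if (is.null(x$traj)) {
    stop("run simulate_tcm() with keep_states = TRUE to export a trajectory",
         call. = FALSE)
  }
  pops <- c("SP", "SI", "SS", "DP", "DI", "TP", "RT", "RL")
  kept <- nrow(x$traj)
  times <- x$time[seq(1, by = x$thin %||% 1L, length.out = kept)]
  purrr::map_dfr(1:2, function(n) {
    purrr::map_dfr(1:8, function(p) {
      tibble::tibble(
        time = times,
        node = c("frontal", "parietal")[n],
        population = pops[p],
        V = x$traj[, (n - 1) * 8 + p]
      )
    })
  })
}
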