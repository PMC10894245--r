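#' Prior specification for model inversion
#'
#' Collects the prior mean (zero) and diagonal prior covariance of the
#' log-scaling latents of a model's free parameters, plus a broad hyperprior
#' on the log noise precision. Entries with prior variance 0 are fixed and
#' excluded from optimization.
#'
#' @param model A `tcm_model`.
#' @param h0,s_h Mean and variance of the Gaussian hyperprior on the log
#'   noise precision; `h0 = NA` lets the inversion initialize it from the
#'   data (moment matching).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(model, h0 = NA, s_h = 16) {
  free <- model$priors[model$priors$prior_var > 0, ]
  structure(list(
    names = free$name,
    mu0 = stats::setNames(rep(0, nrow(free)), free$name),
    Sigma0 = diag(free$prior_var, nrow(free)),
    h0 = h0, s_h = s_h
  ), class = "prior_spec")
}

#' KL divergence between two multivariate Gaussians
#'
#' \eqn{KL(N(\mu,\Sigma) \| N(\mu_0,\Sigma_0))}; exactly zero when the two
#' distributions coincide. This is the complexity term of the variational
#' free energy.
#'
#' @param mu,Sigma Posterior mean and covariance.
#' @param mu0,Sigma0 Prior mean and covariance.
#' @export
kl_gaussian <- function(mu, Sigma, mu0, Sigma0) {
  if (identical(unname(mu), unname(mu0)) &&
      identical(unname(Sigma), unname(Sigma0))) {
    return(0)
  }
  p <- length(mu)
  P0 <- solve(Sigma0)
  d <- mu - mu0
  ld0 <- determinant(Sigma0, logarithm = TRUE)$modulus
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  as.numeric(0.5 * (sum(diag(P0 %*% Sigma)) + t(d) %*% P0 %*% d - p + ld0 - ld))
}

#' Laplace free energy of a residual/Jacobian pair
#'
#' Evaluates the variational free energy under the Laplace approximation:
#' the expected log likelihood under the Gaussian posterior,
#' \eqn{-\tfrac12 e^\top \Pi e - \tfrac12 \mathrm{tr}(J \Sigma J^\top \Pi)
#' + \tfrac12 \ln|\Pi| - \tfrac n2 \ln 2\pi}, minus the complexity
#' \eqn{KL(q \| p)}, with \eqn{\Pi = e^{h} I} and the posterior covariance
#' taken as \eqn{\Sigma = (e^{h} J^\top J + \Sigma_0^{-1})^{-1}} (the
#' Gauss-Newton curvature). For a linear forward map this equals the log
#' model evidence exactly at the analytic posterior. An optional Gaussian
#' hyperprior term on `h` can be included.
#'
#' @param e Residual vector (data minus prediction, in weighted feature
#'   space).
#' @param J Jacobian of the predicted features with respect to the latents
#'   (n x p).
#' @param mu Posterior mean of the latents at which `e` was evaluated.
#' @param priors A [prior_spec()].
#' @param h Log noise precision.
#' @param use_h_prior Include the `(h - h0)^2 / (2 s_h)` hyperprior term.
#' @return Scalar free energy with attributes `accuracy`, `complexity`,
#'   `Sigma`.
#' @export
laplace_free_energy <- function(e, J, mu, priors, h, use_h_prior = FALSE) {
  n <- length(e)
  P0 <- solve(priors$Sigma0)
  H <- exp(h) * crossprod(J) + P0
  H <- (H + t(H)) / 2
  # tiny relative ridge keeps the curvature invertible at extreme precisions
  Sigma <- solve(H + diag(1e-12 * mean(diag(H)), nrow(H)))
  acc <- -0.5 * exp(h) * (sum(e^2) + sum((J %*% Sigma) * J)) +
    0.5 * n * h - 0.5 * n * log(2 * pi)
  cx <- kl_gaussian(mu, Sigma, priors$mu0, priors$Sigma0)
  Fv <- acc - cx
  if (use_h_prior && is.finite(priors$h0)) {
    Fv <- Fv - (h - priors$h0)^2 / (2 * priors$s_h)
  }
  structure(Fv, accuracy = acc, complexity = cx, Sigma = Sigma)
}

# Feature weights: inverse absolute data amplitude per entry, floored at a
# small fraction of the entry's band-median amplitude (frequencies are
# assigned to the nearest of the seven canonical bands). This both balances
# the 1/f dominance of low frequencies in the residual and whitens
# observation noise whose size is proportional to each entry's magnitude;
# the band-median floor keeps near-zero entries (e.g. the imaginary parts
# of the auto-spectra) from dominating.
band_weights <- function(y, freq_of_entry) {
  bt <- band_table()
  centers <- (bt$lo + bt$hi) / 2
  band_of <- vapply(freq_of_entry, function(f) which.min(abs(centers - f)),
                    integer(1))
  med <- numeric(length(y))
  fallback <- stats::median(abs(y[abs(y) > 0]))
  for (b in unique(band_of)) {
    sel <- band_of == b
    m <- stats::median(abs(y[sel]))
    med[sel] <- if (m > 0) m else fallback
  }
  1 / (abs(y) + 0.05 * med)
}

#' Percent variance explained by a fitted (or supplied) spectrum
#'
#' \eqn{100 (1 - \|g - y\|^2 / \|y - \bar y\|^2)} on the unweighted feature
#' vectors of the predicted and observed cross-spectral densities (total sum
#' of squares about the mean feature).
#'
#' @param object An `inversion_result`, or a `spectral_data` prediction.
#' @param data The observed [spectral_data()].
#' @return Percent variance explained (at most 100; negative if the fit is
#'   worse than the mean).
#' @export
variance_explained <- function(object, data) {
  pred <- if (inherits(object, "inversion_result")) object$fitted else object
  stopifnot(inherits(pred, "spectral_data"), inherits(data, "spectral_data"))
  if (!isTRUE(all.equal(pred$freq, data$freq))) {
    stop("frequency grids of prediction and data do not match", call. = FALSE)
  }
  y <- as.numeric(featurize(data))
  g <- as.numeric(featurize(pred))
  tot <- sum((y - mean(y))^2)
  if (tot == 0) stop("zero-variance data features", call. = FALSE)
  100 * (1 - sum((g - y)^2) / tot)
}

#' Control settings for [invert_csd()]
#'
#' @param max_iter Iteration cap.
#' @param tol Free-energy improvement (nats) under which an iteration counts
#'   as converged.
#' @param patience Consecutive sub-`tol` iterations required to stop.
#' @param fd_step Central finite-difference step on the latents (log units).
#' @param lm0 Initial Levenberg-Marquardt damping.
#' @param max_retry Step-halving retries per iteration before giving up.
#' @param restart_threshold If the converged fit explains less variance
#'   than this (percent), one cautious restart with 16-fold damping is run
#'   and the higher-free-energy result kept; `-Inf` disables.
#' @export
invert_control <- function(max_iter = 128, tol = 1e-2, patience = 4,
                           fd_step = 1e-3, lm0 = 0.5, max_retry = 8,
                           restart_threshold = 90) {
  list(max_iter = max_iter, tol = tol, patience = patience,
       fd_step = fd_step, lm0 = lm0, max_retry = max_retry,
       restart_threshold = restart_threshold)
}

#' Fit the thalamocortical model to a cross-spectral density
#'
#' Variational-Laplace inversion: Gauss-Newton/Levenberg-Marquardt ascent on
#' the free energy (accuracy minus complexity) over the log-scaling latents,
#' with the log noise precision updated between parameter steps. Steps are
#' accepted only if they increase the free energy, so the returned trace is
#' non-decreasing; proposals whose linearization is unstable are rejected
#' outright. The procedure is deterministic given data and configuration.
#'
#' @param data A [spectral_data()] object.
#' @param model A `tcm_model`.
#' @param priors A [prior_spec()]; defaults to the model's priors.
#' @param control A [invert_control()] list.
#' @param quiet Suppress per-iteration progress.
#' @return An object of class `inversion_result`: posterior mean `mu` and
#'   covariance `Sigma` over the latents, free-energy `trace`, fitted
#'   spectrum `fitted`, `variance_explained`, `converged`, `iterations`,
#'   feature `weights`, and a config `hash`.
#' @export
invert_csd <- function(data, model, priors = prior_spec(model),
                       control = invert_control(), quiet = TRUE) {
  fit <- invert_csd_once(data, model, priors, control, quiet)
  thr <- control$restart_threshold %||% 90
  if (is.finite(thr) && fit$variance_explained < thr) {
    ctl2 <- control
    ctl2$lm0 <- (control$lm0 %||% 0.5) * 16
    ctl2$restart_threshold <- -Inf
    fit2 <- tryCatch(invert_csd_once(data, model, priors, ctl2, quiet),
                     error = function(e) NULL)
    if (!is.null(fit2) && fit2$free_energy > fit$free_energy) fit <- fit2
  }
  fit
}

invert_csd_once <- function(data, model, priors = prior_spec(model),
                            control = invert_control(), quiet = TRUE) {
  stopifnot(inherits(data, "spectral_data"))
  freqs <- data$freq
  y_raw <- as.numeric(featurize(data))
  wts <- band_weights(y_raw, attr(featurize(data), "freq"))
  yw <- wts * y_raw
  nms <- priors$names
  p <- length(nms)
  n <- length(yw)
  P0 <- solve(priors$Sigma0)

  fp_cache <- NULL
  forward <- function(lam, check = FALSE) {
    lam <- stats::setNames(as.numeric(lam), nms)
    asm <- tcm_assemble(model, lam)
    fp <- find_fixed_point(asm, x0 = fp_cache)
    jb <- jacobian_assembled(fp, asm)
    if (check) {
      ev <- eigen(jb$A0 + jb$delayed$`1` + jb$delayed$`8`,
                  only.values = TRUE)$values
      if (max(Re(ev)) >= 0) stop("unstable", call. = FALSE)
    }
    H <- cpp_transfer(jb$A0, jb$delayed$`1`, jb$delayed$`8`,
                      asm$B, asm$Cmat, freqs,
                      jb$delays[["1"]], jb$delays[["8"]])
    Gu <- innovation_spectrum(asm, freqs)
    S <- array(NA_complex_, c(2, 2, length(freqs)))
    ns <- asm$noise; lvl <- asm$cn$innovation_scale
    chan <- lvl * (ns[["alpha_s"]] * freqs^(-ns[["beta_s"]]) + ns[["alpha_w"]])
    comm <- lvl * ns[["alpha_c"]] * freqs^(-ns[["beta_c"]])
    for (k in seq_along(freqs)) {
      Hk <- H[, , k]
      Sk <- Hk %*% diag(Gu[k, ]) %*% Conj(t(Hk)) +
        diag(chan[k], 2) + matrix(comm[k], 2, 2)
      S[, , k] <- (Sk + Conj(t(Sk))) / 2
    }
    sd_obj <- spectral_data(freqs, S)
    list(fw = wts * as.numeric(featurize(sd_obj)), pred = sd_obj, fp = fp)
  }

  mu <- priors$mu0
  g <- forward(mu, check = TRUE)
  fp_cache <- as.numeric(g$fp)
  e <- yw - g$fw
  h <- log(n / max(sum(e^2), 1e-8 * sum(yw^2)))
  if (!is.finite(priors$h0)) priors$h0 <- h

  fd_jacobian <- function(mu) {
    J <- matrix(0, n, p)
    for (j in seq_len(p)) {
      d <- control$fd_step
      lp <- mu; lp[j] <- lp[j] + d
      lm <- mu; lm[j] <- lm[j] - d
      fp1 <- tryCatch(forward(lp)$fw, error = function(err) NULL)
      fm1 <- tryCatch(forward(lm)$fw, error = function(err) NULL)
      if (is.null(fp1) || is.null(fm1)) {
        J[, j] <- 0
      } else {
        J[, j] <- (fp1 - fm1) / (2 * d)
      }
    }
    J
  }

  update_h <- function(e, J, mu, h) {
    Fc <- laplace_free_energy(e, J, mu, priors, h, use_h_prior = TRUE)
    Sigma <- attr(Fc, "Sigma")
    eh <- n / max(sum(e^2) + sum((J %*% Sigma) * J), 1e-12)
    hn <- max(min(log(eh), priors$h0 + 8), priors$h0 - 8)
    if (!is.finite(hn)) return(h)
    Fn <- laplace_free_energy(e, J, mu, priors, hn, use_h_prior = TRUE)
    if (is.finite(as.numeric(Fn)) && as.numeric(Fn) > as.numeric(Fc)) hn else h
  }

  trace <- numeric(0)
  lm_damp <- control$lm0
  stall <- 0
  converged <- FALSE
  iters <- 0
  F_best <- -Inf
  for (it in seq_len(control$max_iter)) {
    iters <- it
    J <- fd_jacobian(mu)
    h <- update_h(e, J, mu, h)
    Fc <- laplace_free_energy(e, J, mu, priors, h, use_h_prior = TRUE)
    # acceptance is gated on the best free energy recorded so far, so the
    # trace of accepted steps is non-decreasing by construction even though
    # the Jacobian (and with it the curvature entering F) is refreshed
    # between iterations
    F_gate <- max(as.numeric(Fc), F_best)
    Hgn <- exp(h) * crossprod(J) + P0
    grad <- exp(h) * crossprod(J, e) - P0 %*% (mu - priors$mu0)
    accepted <- FALSE
    for (try_i in seq_len(control$max_retry)) {
      M <- Hgn + lm_damp * diag(diag(Hgn), p)
      dmu <- as.numeric(solve(M, grad))
      mu_new <- mu + dmu
      g_new <- tryCatch(forward(mu_new, check = TRUE),
                        error = function(err) NULL)
      if (!is.null(g_new)) {
        e_new <- yw - g_new$fw
        Fn <- laplace_free_energy(e_new, J, mu_new, priors, h,
                                  use_h_prior = TRUE)
        if (as.numeric(Fn) > F_gate) {
          dF <- as.numeric(Fn) - F_gate
          F_best <- as.numeric(Fn)
          mu <- stats::setNames(mu_new, nms)
          g <- g_new; e <- e_new
          fp_cache <- as.numeric(g$fp)
          lm_damp <- max(lm_damp / 2, 1e-8)
          trace <- c(trace, as.numeric(Fn))
          accepted <- TRUE
          stall <- if (dF < control$tol) stall + 1 else 0
          if (!quiet) message(sprintf("iter %3d  F = %.4f  dF = %.5f", it,
                                      as.numeric(Fn), dF))
          break
        }
      }
      lm_damp <- lm_damp * 4
    }
    if (!accepted) {
      if (it == 1) {
        # distinguish "already at the optimum" (expected quadratic-model
        # gain below tolerance) from a genuinely failed start
        exp_gain <- 0.5 * sum(grad * solve(Hgn, grad))
        if (exp_gain >= control$tol) {
          stop("inversion failed: no acceptable step from the prior mean ",
               "(expected free-energy gain ", format(exp_gain, digits = 3),
               ", damping reached ", format(lm_damp, digits = 3), ")",
               call. = FALSE)
        }
        trace <- as.numeric(Fc)
        F_best <- as.numeric(Fc)
      }
      stall <- stall + 1
    }
    if (stall >= control$patience) { converged <- TRUE; break }
  }

  J <- fd_jacobian(mu)
  Ff <- laplace_free_energy(e, J, mu, priors, h, use_h_prior = TRUE)
  Sigma <- attr(Ff, "Sigma")
  fitted <- forward(mu)$pred
  fitted$subject <- data$subject; fitted$condition <- data$condition
  ve <- variance_explained(fitted, data)

  structure(list(
    mu = stats::setNames(as.numeric(mu), nms),
    Sigma = Sigma,
    trace = trace,
    free_energy = as.numeric(Ff),
    h = h,
    fitted = fitted,
    data = data,
    variance_explained = ve,
    converged = converged,
    iterations = iters,
    weights = wts,
    priors = priors,
    hash = rlang::hash(list(control, priors$names, freqs))
  ), class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("<inversion_result> ", length(x$mu), " latents, ",
      x$iterations, " iterations, F = ", round(x$free_energy, 2),
      ", variance explained = ", round(x$variance_explained, 1), "%",
      if (x$converged) " (converged)" else " (iteration cap)", "\n", sep = "")
  invisible(x)
}

#' Tidy an inversion result into one row per latent
#'
#' @param x An `inversion_result`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `estimate` (posterior mean latent),
#'   `std.error` (posterior SD), `scaling` (`exp(estimate)`).
#' @export
tidy.inversion_result <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$mu),
    estimate = as.numeric(x$mu),
    std.error = sqrt(pmax(diag(x$Sigma), 0)),
    scaling = exp(as.numeric(x$mu))
  )
}

#' One-row summary of an inversion
#'
#' @param x An `inversion_result`.
#' @param ... Unused.
#' @export
glance.inversion_result <- function(x, ...) {
  tibble::tibble(
    free_energy = x$free_energy,
    variance_explained = x$variance_explained,
    iterations = x$iterations,
    converged = x$converged,
    log_precision = x$h
  )
}
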