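#' Planted pharmacological effect specification
#'
#' Defines the condition effects a synthetic cohort carries: additive shifts
#' (log-scaling units) on named latents for the bolus and infusion
#' conditions, between-subject SD of each shift, the SD of baseline
#' between-subject parameter variability, and the linear clinical-coupling
#' model that ties realized parameter shifts to MADRS change scores.
#'
#' The defaults plant the drug effects on: forward AMPA gain (up, roughly
#' linearly over bolus then infusion), frontal GABA-A rate constant (up,
#' i.e. a shorter time constant, with most of the change already present in
#' the bolus), parietal NMDA rate constant (down: longer time constant) and
#' frontal SI->SP inhibitory gain (down). Clinical couplings are calibrated
#' so the expected correlation between the realized infusion-minus-pre shift
#' and the signed MADRS change at 24 h is 0.43 for forward AMPA and 0.38
#' for the frontal GABA-A rate constant (equivalently -0.38 for its time
#' constant); at 7 days only the GABA-A coupling is kept substantial.
#'
#' Besides the planted shifts, every free latent receives independent
#' condition-level state noise (SD `condition_sd`, all three conditions):
#' the within-subject physiological variability against which the
#' repeated-measures analysis operates.
#'
#' @param shifts Tibble with columns `parameter`, `bolus`, `infusion`,
#'   `sd_subject`.
#' @param baseline_sd SD of baseline between-subject variability applied to
#'   every free latent.
#' @param condition_sd SD of condition-level state noise on every free
#'   latent.
#' @param clinical_base Named mean signed MADRS changes, `c(change_24h = ,
#'   change_7d = )` (negative = improvement).
#' @param clinical_sd Total SD of each clinical change score.
#' @param couplings Tibble with `parameter`, `timepoint`
#'   (`"change_24h"`/`"change_7d"`), `r` (target correlation with the
#'   realized shift).
#' @param madrs_baseline Mean and SD of baseline MADRS severity.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(shifts = NULL, baseline_sd = 0.1,
                        condition_sd = 0.05,
                        clinical_base = c(change_24h = -12, change_7d = -8),
                        clinical_sd = 6,
                        couplings = NULL,
                        madrs_baseline = c(mean = 32, sd = 4)) {
  if (is.null(shifts)) {
    shifts <- tibble::tribble(
      ~parameter,            ~bolus, ~infusion, ~sd_subject,
      "ext_ampa_fwd",          0.15,      0.30,        0.15,
      "kappa_frontal_gaba",    0.20,      0.25,        0.15,
      "kappa_parietal_nmda",  -0.10,     -0.15,        0.15,
      "int_frontal_si_sp",    -0.10,     -0.15,        0.15
    )
  }
  if (is.null(couplings)) {
    couplings <- tibble::tribble(
      ~parameter,           ~timepoint,    ~r,
      "ext_ampa_fwd",       "change_24h",  0.43,
      "kappa_frontal_gaba", "change_24h",  0.38,
      "ext_ampa_fwd",       "change_7d",   0.15,
      "kappa_frontal_gaba", "change_7d",   0.35
    )
  }
  stopifnot(all(shifts$sd_subject >= 0), clinical_sd > 0, baseline_sd >= 0,
            condition_sd >= 0)
  for (tp in unique(couplings$timepoint)) {
    rr <- couplings$r[couplings$timepoint == tp]
    if (sum(rr^2) >= 1) {
      stop("infeasible clinical couplings at ", tp,
           ": sum of squared correlations must be < 1", call. = FALSE)
    }
  }
  structure(list(shifts = shifts, baseline_sd = baseline_sd,
                 condition_sd = condition_sd,
                 clinical_base = clinical_base, clinical_sd = clinical_sd,
                 couplings = couplings, madrs_baseline = madrs_baseline),
            class = "effect_spec")
}

#' Zero-effect specification (null cohorts)
#'
#' @inheritParams effect_spec
#' @export
null_effect_spec <- function(baseline_sd = 0.1) {
  es <- effect_spec(baseline_sd = baseline_sd)
  es$shifts$bolus <- 0
  es$shifts$infusion <- 0
  es$shifts$sd_subject <- 0.15
  es$couplings$r <- 0
  es
}

#' Calibrate one clinical coupling to a target correlation
#'
#' Sets the coupling of `parameter` at `timepoint` so the expected
#' correlation between the subject-level realized infusion-minus-pre shift
#' and the clinical change score equals `target_r`; the residual SD is
#' implied by keeping the total clinical SD fixed, so the calibration is
#' exact in expectation. Correlations of magnitude 1 (zero residual) are
#' rejected, as are combinations whose squared correlations exceed 1.
#'
#' @param effects An [effect_spec()].
#' @param target_r Target Pearson correlation, `|target_r| < 1`.
#' @param parameter Which planted parameter's coupling to set.
#' @param timepoint `"change_24h"` or `"change_7d"`.
#' @return The modified `effect_spec`.
#' @export
calibrate_clinical_coupling <- function(effects, target_r,
                                        parameter = "ext_ampa_fwd",
                                        timepoint = "change_24h") {
  stopifnot(inherits(effects, "effect_spec"))
  if (abs(target_r) >= 1) {
    stop("|target_r| must be < 1 (a perfect correlation needs zero residual)",
         call. = FALSE)
  }
  cp <- effects$couplings
  sel <- cp$parameter == parameter & cp$timepoint == timepoint
  if (!any(sel)) {
    cp <- dplyr::bind_rows(cp, tibble::tibble(parameter = parameter,
                                              timepoint = timepoint,
                                              r = target_r))
  } else {
    cp$r[sel] <- target_r
  }
  rr <- cp$r[cp$timepoint == timepoint]
  if (sum(rr^2) >= 1) {
    stop("infeasible coupling set: sum of squared correlations at ",
         timepoint, " reaches ", round(sum(rr^2), 3), call. = FALSE)
  }
  effects$couplings <- cp
  effects
}

# realized clinical scores from a subject's realized infusion-minus-pre
# latent changes: the coupling b_p = r_p * S / sd(z_p) plus residual sd
# S * sqrt(1 - sum r^2) keeps the total SD at S and the expected sample
# correlations at their targets; sd(z_p) includes both the subject-level
# shift noise and the condition-level state noise of the two conditions
clinical_scores <- function(effects, shift_realized) {
  S <- effects$clinical_sd
  out <- list(madrs_baseline = stats::rnorm(1, effects$madrs_baseline[["mean"]],
                                            effects$madrs_baseline[["sd"]]))
  for (tp in c("change_24h", "change_7d")) {
    cp <- effects$couplings[effects$couplings$timepoint == tp, ]
    val <- effects$clinical_base[[tp]]
    r2 <- 0
    for (i in seq_len(nrow(cp))) {
      prm <- cp$parameter[i]
      sds <- effects$shifts$sd_subject[effects$shifts$parameter == prm]
      if (!length(sds) || cp$r[i] == 0) next
      sdz <- sqrt(sds^2 + 2 * effects$condition_sd^2)
      if (sdz <= 0) next
      z <- shift_realized[[prm]]
      mz <- effects$shifts$infusion[effects$shifts$parameter == prm]
      val <- val + cp$r[i] * S / sdz * (z - mz)
      r2 <- r2 + cp$r[i]^2
    }
    val <- val + stats::rnorm(1, 0, S * sqrt(max(1 - r2, 0)))
    out[[tp]] <- val
  }
  out
}

#' Draw one synthetic subject
#'
#' Baseline latents are drawn around the priors
#' (\eqn{\lambda \sim N(0, \mathrm{baseline\_sd}^2)} on every free
#' parameter); each condition adds its planted shift plus subject-level
#' shift noise; spectra are generated by the linearized forward model with
#' Hermitian-preserving complex Gaussian observation noise (SD a fixed
#' fraction of the frequency-wise entry magnitude); clinical change scores
#' are a linear-Gaussian function of the subject's realized shifts. If a
#' drawn parameter set is dynamically unstable the subject is redrawn (up
#' to `max_resample` times, counted in the record). Deterministic per seed.
#'
#' @param model A `tcm_model`.
#' @param effects An [effect_spec()].
#' @param seed Integer seed for this subject.
#' @param freqs Frequency grid for the generated spectra (Hz).
#' @param noise_frac Observation-noise SD as a fraction of each CSD entry's
#'   magnitude.
#' @param subject Subject identifier.
#' @param spectra Generate spectra (set `FALSE` for a fast latent-only
#'   record, e.g. statistical calibration runs).
#' @param max_resample Redraw budget for unstable parameter draws.
#' @return An object of class `cohort_record`.
#' @export
sample_subject <- function(model, effects = effect_spec(), seed = 1,
                           freqs = 4:90, noise_frac = 0.05, subject = 1L,
                           spectra = TRUE, max_resample = 10) {
  stopifnot(inherits(effects, "effect_spec"))
  set.seed(seed)
  free <- model$priors$name[model$priors$prior_var > 0]
  conditions <- c("pre", "bolus", "infusion")
  for (attempt in 0:max_resample) {
    base <- stats::setNames(stats::rnorm(length(free), 0, effects$baseline_sd),
                            free)
    lam <- list()
    ok <- TRUE
    for (cond in conditions) {
      l <- base + stats::rnorm(length(free), 0, effects$condition_sd)
      if (cond != "pre") {
        for (i in seq_len(nrow(effects$shifts))) {
          prm <- effects$shifts$parameter[i]
          if (!prm %in% free) next
          sh <- effects$shifts[[cond]][i] +
            stats::rnorm(1, 0, effects$shifts$sd_subject[i])
          l[prm] <- l[prm] + sh
        }
      }
      lam[[cond]] <- l
      if (spectra) {
        ok <- tryCatch({ tcm_linearize(model, l); TRUE },
                       error = function(e) FALSE)
        if (!ok) break
      }
    }
    if (ok) break
  }
  prms <- intersect(effects$shifts$parameter, free)
  shift_real <- as.list(lam$infusion[prms] - lam$pre[prms])
  if (!ok) {
    stop("could not draw a stable subject after ", max_resample,
         " resamples (seed ", seed, ")", call. = FALSE)
  }
  spec_list <- NULL
  if (spectra) {
    spec_list <- lapply(conditions, function(cond) {
      s <- predict_csd(model, lam[[cond]], freqs, subject = subject,
                       condition = cond)
      add_csd_noise(s, noise_frac)
    })
    names(spec_list) <- conditions
  }
  clin <- clinical_scores(effects, shift_real)
  structure(list(
    subject = subject,
    lambda = purrr::map_dfr(conditions, function(cond) {
      tibble::tibble(subject = subject, condition = cond,
                     parameter = free, value = as.numeric(lam[[cond]]))
    }),
    spectra = spec_list,
    clinical = tibble::tibble(subject = subject,
                              madrs_baseline = clin$madrs_baseline,
                              change_24h = clin$change_24h,
                              change_7d = clin$change_7d),
    resamples = attempt, seed = seed
  ), class = "cohort_record")
}

#' Add Hermitian-preserving observation noise to a CSD
#'
#' Complex Gaussian noise with SD `frac` times the magnitude of each entry,
#' symmetrized so the perturbed matrix stays Hermitian with real diagonal
#' (clipped below at a tiny positive floor).
#'
#' @param x A [spectral_data()] object.
#' @param frac Noise SD as a fraction of each entry's magnitude.
#' @return A `spectral_data` object.
#' @export
add_csd_noise <- function(x, frac = 0.05) {
  S <- x$csd
  for (k in seq_along(x$freq)) {
    G <- matrix(complex(real = stats::rnorm(4), imaginary = stats::rnorm(4)),
                2, 2) * frac * abs(S[, , k])
    Sk <- S[, , k] + (G + Conj(t(G))) / 2
    diag(Sk) <- pmax(Re(diag(Sk)), 1e-12 * max(abs(Sk))) + 0i
    S[, , k] <- Sk
  }
  spectral_data(x$freq, S, subject = x$subject, condition = x$condition)
}

#' Generate a synthetic cohort
#'
#' Draws `n` independent subjects via [sample_subject()], with per-subject
#' seeds derived from the master seed by the fixed splitting rule
#' `seed_i = master_seed + 7919 * i`. The returned object carries the
#' manifest of true latent values for later recovery scoring, and the
#' clinical table.
#'
#' @inheritParams sample_subject
#' @param n Number of subjects (default the study's 27 included
#'   participants).
#' @param master_seed Master seed.
#' @return An object of class `tcm_cohort`: list with `records`, `manifest`
#'   (subject x condition x parameter true latents), `clinical`, `effects`.
#' @export
generate_cohort <- function(n = 27, model = tcm_model(),
                            effects = effect_spec(), master_seed = 1,
                            freqs = 4:90, noise_frac = 0.05,
                            spectra = TRUE) {
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  records <- lapply(seq_len(n), function(i) {
    sample_subject(model, effects, seed = master_seed + 7919L * i,
                   freqs = freqs, noise_frac = noise_frac,
                   subject = i, spectra = spectra)
  })
  structure(list(
    records = records,
    manifest = purrr::map_dfr(records, "lambda"),
    clinical = purrr::map_dfr(records, "clinical"),
    effects = effects, master_seed = master_seed, freqs = freqs
  ), class = "tcm_cohort")
}

#' @export
print.tcm_cohort <- function(x, ...) {
  cat("<tcm_cohort> ", length(x$records), " subjects x 3 conditions",
      if (!is.null(x$records[[1]]$spectra)) paste0(
        " (", 3 * length(x$records), " spectra on ",
        length(x$freqs), " frequencies)") else " (latents only)",
      "\n", sep = "")
  invisible(x)
}

#' Tidy a cohort into its true-latent manifest
#'
#' @param x A `tcm_cohort`.
#' @param ... Unused.
#' @export
tidy.tcm_cohort <- function(x, ...) x$manifest

#' Fit every subject and condition of a cohort
#'
#' Runs [invert_csd()] independently (from identical priors) on each of the
#' 3n spectra of a cohort and collects posterior means in long format.
#'
#' @param cohort A `tcm_cohort` with spectra.
#' @param model A `tcm_model`.
#' @param control An [invert_control()].
#' @param quiet Print one progress line per fit.
#' @return List of class `cohort_fits`: `estimates` (tibble subject x
#'   condition x parameter x estimate), `fits` (tibble of per-fit
#'   diagnostics), `clinical` (carried through).
#' @export
fit_cohort <- function(cohort, model = tcm_model(),
                       control = invert_control(), quiet = TRUE) {
  stopifnot(inherits(cohort, "tcm_cohort"))
  if (is.null(cohort$records[[1]]$spectra)) {
    stop("cohort was generated without spectra", call. = FALSE)
  }
  rows <- list(); diags <- list()
  for (rec in cohort$records) {
    for (cond in names(rec$spectra)) {
      fit <- invert_csd(rec$spectra[[cond]], model, control = control)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = rec$subject, condition = cond,
        parameter = names(fit$mu), estimate = as.numeric(fit$mu)
      )
      diags[[length(diags) + 1]] <- dplyr::mutate(
        glance(fit), subject = rec$subject, condition = cond,
        .before = 1
      )
      if (!quiet) {
        message(sprintf("subject %s %-8s VE %5.1f%%  F %.1f  (%d it)",
                        rec$subject, cond, fit$variance_explained,
                        fit$free_energy, fit$iterations))
      }
    }
  }
  structure(list(estimates = dplyr::bind_rows(rows),
                 fits = dplyr::bind_rows(diags),
                 clinical = cohort$clinical),
            class = "cohort_fits")
}
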