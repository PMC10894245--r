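# Shared fixtures, built once per test run.

the <- new.env()

default_model <- function() {
  if (is.null(the$model)) the$model <- tcm_model()
  the$model
}

# model with every synaptic coupling and the tonic drive removed: the
# populations decouple into pure leak + conductance-decay dynamics
decoupled_model <- function() {
  m <- tcm_model()
  m$edges$g0[] <- 0
  m$priors$value[m$priors$name == "drive"] <- 0
  m
}

# coarse grid for unit-test inversions (cheap but representative)
coarse_grid <- function() seq(4, 90, by = 3)

# noise-free prediction at prior means on the coarse grid, cached
coarse_truth <- function() {
  if (is.null(the$coarse_truth)) {
    the$coarse_truth <- predict_csd(default_model(), freqs = coarse_grid())
  }
  the$coarse_truth
}

# one cheap noise-free self-inversion, cached and reused by several tests
coarse_self_fit <- function() {
  if (is.null(the$coarse_self_fit)) {
    the$coarse_self_fit <- invert_csd(coarse_truth(), default_model())
  }
  the$coarse_self_fit
}

# random stable prior draw (NULL if the draw is unstable)
stable_draw <- function(model) {
  free <- model$priors[model$priors$prior_var > 0, ]
  lam <- tcm_lambda(model)
  lam[] <- rnorm(length(lam), 0, sqrt(free$prior_var[match(names(lam),
                                                           free$name)]))
  ok <- tryCatch({ tcdcm:::tcm_linearize(model, lam); TRUE },
                 error = function(e) FALSE)
  if (ok) lam else NULL
}

# brute-force one-way repeated-measures ANOVA by explicit sums of squares
# (independent oracle for rm_anova)
rm_anova_bruteforce <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(x[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(x[i, ]) - grand)^2
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  ms_cond <- ss_cond / (k - 1)
  ms_err <- ss_err / ((k - 1) * (n - 1))
  ms_cond / ms_err
}

# direct covariance-formula Pearson correlation (independent oracle)
pearson_bruteforce <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
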