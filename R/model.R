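#' Construct the default two-node thalamocortical conductance model
#'
#' Builds the prior specification of an eight-population conductance neural
#' mass model replicated over two hierarchically connected cortical nodes
#' (a frontal node in medial prefrontal cortex, MNI -12 36 60, and a parietal
#' node in superior parietal lobule, MNI -24 -66 66). Each node contains
#' superficial pyramidal (SP), superficial interneuron (SI), spiny stellate
#' (SS), deep pyramidal (DP), deep interneuron (DI), thalamic-projection
#' pyramidal (TP), reticular (RT) and relay (RL) populations, every
#' population carrying AMPA, NMDA and GABA-A conductances, giving
#' 2 nodes x 8 populations x 4 state variables = 64 dynamical states.
#'
#' Laminar wiring follows the canonical microcircuit extended with a
#' thalamic loop (TP->RL, TP->RT, RT->RL, RL->SS, RL->RT); inhibitory
#' populations project only through GABA-A, excitatory populations through
#' AMPA plus a fixed-ratio NMDA component. Extrinsic forward connections
#' (parietal -> frontal) target granular populations (SS, DP); backward
#' connections (frontal -> parietal) target superficial populations (SP, SI);
#' both are AMPA- and NMDA-mediated with separate gains.
#'
#' Every scalar parameter is carried as a prior mean together with a
#' log-scaling latent \eqn{\lambda} (the quantity actually estimated), so the
#' effective value is \eqn{\theta = \bar\theta e^\lambda}; entries with prior
#' variance 0 are fixed. Evaluating at \eqn{\lambda = 0} reproduces the prior
#' means exactly.
#'
#' @param n_nodes Number of cortical nodes; only the two-node model is
#'   supported.
#' @return An object of class `tcm_model`: a list with tibbles `nodes`,
#'   `populations`, `edges`, `priors` and a list `constants`.
#' @examples
#' m <- tcm_model()
#' m$priors
#' @export
tcm_model <- function(n_nodes = 2) {
  if (!identical(as.integer(n_nodes), 2L)) {
    stop("only the two-node (frontal/parietal) model is supported", call. = FALSE)
  }

  nodes <- tibble::tibble(
    node = 1:2,
    name = c("frontal", "parietal"),
    mni  = list(c(-12L, 36L, 60L), c(-24L, -66L, 66L))
  )

  populations <- tibble::tibble(
    pop        = 1:8,
    label      = c("SP", "SI", "SS", "DP", "DI", "TP", "RT", "RL"),
    excitatory = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )

  constants <- list(
    V_L = -70, V_AMPA = 60, V_GABA = -90, V_NMDA = 10,
    mg_alpha = 0.06,          # 1/mV, NMDA Mg-block slope
    rho1 = 2 / 3, rho2 = 3,   # firing sigmoid slope (1/mV) and threshold (mV,
                              # above rest: baseline sits on the rising limb)
    C = 10, g_L = 1,          # capacitance and leak: membrane tau = 10 ms
    g_scale = 1 / 16,         # firing-to-conductance conversion of afferent drive
    nmda_ratio = 0.25,        # NMDA companion weight on excitatory edges
    delay_intrinsic = 1,      # ms
    delay_thalamic = 8,       # ms, cortex<->thalamus each way
    delay_extrinsic = 8,      # ms, cortico-cortical
    innovation_scale = 1e-12, # (drive units)^2/Hz behind unit alpha_u
    J = c(SP = 0.8, SI = 0, SS = 0, DP = 0.2, DI = 0, TP = 0.1, RT = 0, RL = 0)
  )

  # Intrinsic edges, replicated per node. `param` names the log-scaling
  # latent that multiplies the base weight g0 (sign -1: divides, used for
  # the SP self-gain which scales down SP's own inhibitory recurrence).
  intr <- tibble::tribble(
    ~from, ~to,  ~receptor, ~g0, ~delay, ~param,      ~sign,
    "SS",  "SP", "E",       1.0, 1,      NA,          1,
    "SP",  "SI", "E",       1.0, 1,      NA,          1,
    "SS",  "SI", "E",       1.0, 1,      NA,          1,
    "SP",  "DP", "E",       1.0, 1,      NA,          1,
    "DP",  "DI", "E",       1.0, 1,      NA,          1,
    "DP",  "TP", "E",       1.0, 1,      NA,          1,
    "TP",  "RL", "E",       0.8, 8,      "tp_rl",     1,
    "TP",  "RT", "E",       0.8, 8,      NA,          1,
    "RL",  "SS", "E",       0.8, 8,      "rl_ss",     1,
    "RL",  "RT", "E",       0.8, 1,      NA,          1,
    "SP",  "SP", "GABA",    2.0, 1,      "sp_sp",     -1,
    "SI",  "SP", "GABA",    2.0, 1,      "si_sp",     1,
    "DI",  "DP", "GABA",    2.0, 1,      NA,          1,
    "RT",  "RL", "GABA",    2.0, 1,      NA,          1
  )
  per_node <- dplyr::bind_rows(lapply(1:2, function(n) {
    e <- intr
    e$from_node <- n
    e$to_node <- n
    e$param <- ifelse(is.na(e$param), NA_character_,
                      paste0("int_", nodes$name[n], "_", e$param))
    e
  }))

  extr <- tibble::tribble(
    ~from, ~to,  ~receptor, ~g0, ~from_node, ~to_node, ~dir,
    "SP",  "SS", "E",       1.0, 2L,         1L,       "fwd",
    "SP",  "DP", "E",       0.8, 2L,         1L,       "fwd",
    "DP",  "SP", "E",       0.8, 1L,         2L,       "bwd",
    "DP",  "SI", "E",       0.8, 1L,         2L,       "bwd"
  )
  extr$delay <- constants$delay_extrinsic
  extr$param <- paste0("ext_", extr$dir)
  extr$sign <- 1
  extr$dir <- NULL

  edges <- dplyr::bind_rows(per_node, extr)

  # Expand excitatory edges into explicit AMPA + NMDA rows. Extrinsic edges
  # carry independent AMPA/NMDA gains; intrinsic ones share a gain latent.
  expand_edge <- function(e) {
    if (e$receptor == "GABA") return(e)
    a <- e; a$receptor <- "AMPA"
    n <- e; n$receptor <- "NMDA"; n$g0 <- e$g0 * constants$nmda_ratio
    if (!is.na(e$param) && grepl("^ext_", e$param)) {
      a$param <- sub("^ext_", "ext_ampa_", e$param)
      n$param <- sub("^ext_", "ext_nmda_", e$param)
    }
    dplyr::bind_rows(a, n)
  }
  edges <- dplyr::bind_rows(lapply(seq_len(nrow(edges)), function(i) expand_edge(edges[i, ])))

  prior_row <- function(name, value, var, family, node = NA_character_) {
    tibble::tibble(name = name, value = value, prior_var = var,
                   family = family, node = node)
  }
  priors <- dplyr::bind_rows(
    prior_row("ext_ampa_fwd", 1, 1 / 8, "extrinsic"),
    prior_row("ext_ampa_bwd", 1, 1 / 8, "extrinsic"),
    prior_row("ext_nmda_fwd", 1, 1 / 8, "extrinsic"),
    prior_row("ext_nmda_bwd", 1, 1 / 8, "extrinsic"),
    dplyr::bind_rows(lapply(nodes$name, function(nm) dplyr::bind_rows(
      prior_row(paste0("int_", nm, "_sp_sp"), 1, 1 / 16, "intrinsic", nm),
      prior_row(paste0("int_", nm, "_si_sp"), 1, 1 / 16, "intrinsic", nm),
      prior_row(paste0("int_", nm, "_rl_ss"), 1, 1 / 16, "intrinsic", nm),
      prior_row(paste0("int_", nm, "_tp_rl"), 1, 1 / 16, "intrinsic", nm)
    ))),
    dplyr::bind_rows(lapply(nodes$name, function(nm) dplyr::bind_rows(
      prior_row(paste0("kappa_", nm, "_ampa"), 1 / 4,  1 / 16, "kinetics", nm),
      prior_row(paste0("kappa_", nm, "_gaba"), 1 / 16, 1 / 16, "kinetics", nm),
      prior_row(paste0("kappa_", nm, "_nmda"), 1 / 100, 1 / 16, "kinetics", nm)
    ))),
    prior_row("L_frontal", 1, 1 / 8, "observation", "frontal"),
    prior_row("L_parietal", 1, 1 / 8, "observation", "parietal"),
    prior_row("alpha_u_frontal", 1, 1 / 8, "noise", "frontal"),
    prior_row("alpha_u_parietal", 1, 1 / 8, "noise", "parietal"),
    prior_row("beta_u", 1, 1 / 16, "noise"),
    prior_row("alpha_s", 0.01, 0, "noise"),
    prior_row("beta_s", 1, 0, "noise"),
    prior_row("alpha_w", 0.002, 0, "noise"),
    prior_row("alpha_c", 0.002, 0, "noise"),
    prior_row("beta_c", 1, 0, "noise"),
    prior_row("drive", 0.003, 0, "input")
  )

  structure(
    list(nodes = nodes, populations = populations, edges = edges,
         priors = priors, constants = constants),
    class = "tcm_model"
  )
}

#' @export
print.tcm_model <- function(x, ...) {
  cat("<tcm_model> ", nrow(x$nodes), " nodes x ", nrow(x$populations),
      " populations (", 4 * nrow(x$nodes) * nrow(x$populations),
      " states), ", nrow(x$edges), " receptor-resolved edges\n", sep = "")
  cat("free parameters: ", sum(x$priors$prior_var > 0), " of ",
      nrow(x$priors), "\n", sep = "")
  invisible(x)
}

#' Log-scaling latent vector template
#'
#' Returns a named zero vector over the model's free parameters (those with
#' prior variance > 0). Entries set via `...` override the zeros.
#'
#' @param model A `tcm_model`.
#' @param ... Named latent values, e.g. `ext_ampa_fwd = 0.3`.
#' @return Named numeric vector of log-scaling latents.
#' @export
tcm_lambda <- function(model, ...) {
  free <- model$priors$name[model$priors$prior_var > 0]
  lam <- stats::setNames(numeric(length(free)), free)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), free)
    if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    lam[names(dots)] <- unlist(dots)
  }
  lam
}

# Effective parameter values theta = prior mean * exp(lambda); fixed entries
# (prior_var == 0) stay at their prior means regardless of lambda.
tcm_theta <- function(model, lambda = NULL) {
  th <- stats::setNames(model$priors$value, model$priors$name)
  if (!is.null(lambda) && length(lambda)) {
    nm <- intersect(names(lambda), names(th))
    free <- model$priors$name[model$priors$prior_var > 0]
    nm <- intersect(nm, free)
    th[nm] <- th[nm] * exp(lambda[nm])
  }
  th
}

# State indexing: x = [V(16), gAMPA(16), gNMDA(16), gGABA(16)],
# within-block index i = (node-1)*8 + pop.
state_index <- function(node, pop, block = c("V", "gA", "gN", "gG")) {
  block <- match.arg(block)
  offset <- c(V = 0L, gA = 16L, gN = 32L, gG = 48L)[block]
  offset + (node - 1L) * 8L + pop
}

# Assembles the numeric machinery for one lambda: per-receptor, per-delay
# 16x16 weight matrices, rate-constant vectors, drive, observation and
# noise parameters.
tcm_assemble <- function(model, lambda = NULL) {
  th <- tcm_theta(model, lambda)
  cn <- model$constants
  pops <- model$populations$label
  idx <- function(node, pop) (node - 1L) * 8L + match(pop, pops)

  W <- list(
    AMPA = list(`1` = matrix(0, 16, 16), `8` = matrix(0, 16, 16)),
    NMDA = list(`1` = matrix(0, 16, 16), `8` = matrix(0, 16, 16)),
    GABA = list(`1` = matrix(0, 16, 16), `8` = matrix(0, 16, 16))
  )
  e <- model$edges
  for (k in seq_len(nrow(e))) {
    w <- e$g0[k]
    if (!is.na(e$param[k])) w <- w * th[[e$param[k]]]^e$sign[k]
    d <- as.character(e$delay[k])
    i <- idx(e$to_node[k], e$to[k])
    j <- idx(e$from_node[k], e$from[k])
    W[[e$receptor[k]]][[d]][i, j] <- W[[e$receptor[k]]][[d]][i, j] + w
  }

  nodevec <- rep(1:2, each = 8)
  kappa <- cbind(
    AMPA = th[paste0("kappa_", model$nodes$name, "_ampa")][nodevec],
    NMDA = th[paste0("kappa_", model$nodes$name, "_nmda")][nodevec],
    GABA = th[paste0("kappa_", model$nodes$name, "_gaba")][nodevec]
  )
  rownames(kappa) <- NULL

  Cmat <- matrix(0, 2, 64)
  for (n in 1:2) {
    Ln <- th[[paste0("L_", model$nodes$name[n])]]
    Cmat[n, state_index(n, 1:8, "V")] <- Ln * cn$J
  }

  # innovation input columns: AMPA afferent of SS and RL per node
  B <- matrix(0, 64, 2)
  for (n in 1:2) {
    B[state_index(n, match("SS", pops), "gA"), n] <- kappa[idx(n, "SS"), "AMPA"]
    B[state_index(n, match("RL", pops), "gA"), n] <- kappa[idx(n, "RL"), "AMPA"]
  }

  structure(list(
    th = th, W = W, kappa = kappa, Cmat = Cmat, B = B,
    drive = th[["drive"]],
    alpha_u = th[c("alpha_u_frontal", "alpha_u_parietal")],
    beta_u = th[["beta_u"]],
    noise = th[c("alpha_s", "beta_s", "alpha_w", "alpha_c", "beta_c")],
    cn = cn
  ), class = "tcm_assembled")
}

#' Normalized population firing rate
#'
#' Sigmoid activation of depolarization relative to rest, with the resting
#' value subtracted so that zero depolarization maps to zero rate:
#' \eqn{\sigma(V) = 1/(1+e^{-\rho_1 (V-\rho_2)}) - \sigma_0} with
#' \eqn{\sigma_0 = 1/(1+e^{\rho_1 \rho_2})}. Strictly increasing; range
#' \eqn{(-\sigma_0, 1-\sigma_0)}.
#'
#' @param v Depolarization relative to the leak reversal (mV).
#' @param rho1 Sigmoid slope (1/mV), must be positive.
#' @param rho2 Threshold (mV).
#' @return Normalized rate, same shape as `v`.
#' @export
firing_rate <- function(v, rho1 = 2 / 3, rho2 = 0) {
  if (rho1 <= 0) stop("sigmoid slope rho1 must be positive", call. = FALSE)
  1 / (1 + exp(-rho1 * (v - rho2))) - 1 / (1 + exp(rho1 * rho2))
}

firing_rate_grad <- function(v, rho1 = 2 / 3, rho2 = 0) {
  s <- 1 / (1 + exp(-rho1 * (v - rho2)))
  rho1 * s * (1 - s)
}

#' NMDA magnesium-block nonlinearity
#'
#' Voltage-dependent relief of the NMDA channel's magnesium occlusion,
#' \eqn{m(V) = 1/(1 + 0.2 e^{-\alpha V})}: a sigmoid of the absolute membrane
#' potential, monotone increasing, bounded in (0, 1).
#'
#' @param v Membrane potential (mV).
#' @param alpha Slope of the voltage dependence (1/mV), must be positive.
#' @return Open fraction in (0, 1), same shape as `v`.
#' @export
mg_block <- function(v, alpha = 0.06) {
  if (alpha <= 0) stop("Mg-block slope alpha must be positive", call. = FALSE)
  1 / (1 + 0.2 * exp(-alpha * v))
}

mg_block_grad <- function(v, alpha = 0.06) {
  m <- mg_block(v, alpha)
  alpha * m * (1 - m)
}

# Receptor-wise afferent drive (before rate constants): g_scale-weighted,
# firing-driven input plus tonic drive and optional per-state extra input,
# clamped at zero so conductances cannot be driven negative.
tcm_afferents <- function(asm, rate, drive_extra = NULL) {
  W <- asm$W
  affA <- asm$cn$g_scale * as.numeric(W$AMPA$`1` %*% rate + W$AMPA$`8` %*% rate) + asm$drive
  affN <- asm$cn$g_scale * as.numeric(W$NMDA$`1` %*% rate + W$NMDA$`8` %*% rate)
  affG <- asm$cn$g_scale * as.numeric(W$GABA$`1` %*% rate + W$GABA$`8` %*% rate)
  if (!is.null(drive_extra)) affA <- affA + drive_extra
  list(A = pmax(affA, 0), N = pmax(affN, 0), G = pmax(affG, 0),
       rawA = affA, rawN = affN, rawG = affG)
}

#' Time derivative of the model state
#'
#' Evaluates the conductance-based equations of motion: for each population
#' \eqn{C \dot V = g_L (V_L - V) + g_A (V_A - V) + g_N m(V) (V_N - V) +
#' g_G (V_G - V)} and for each receptor \eqn{\dot g_r = \kappa_r (a_r - g_r)}
#' where the afferent drive \eqn{a_r} is the weighted presynaptic firing of
#' populations connected through receptor class r (plus tonic drive on AMPA),
#' clamped at zero. Delays are not applied here (all presynaptic terms use
#' the current state); they enter the linearized spectral response as
#' frequency-domain phase factors.
#'
#' @param state Numeric state vector of length 64.
#' @param model A `tcm_model`.
#' @param lambda Named log-scaling latents (default: prior means).
#' @param drive Extra exogenous input added to the AMPA afferent: scalar, or
#'   length-64 vector aligned with the state (only conductance rows sensible).
#' @return Numeric vector of length 64 with the time derivative (per ms).
#' @export
state_derivative <- function(state, model, lambda = NULL, drive = 0) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  asm <- if (inherits(model, "tcm_assembled")) model else tcm_assemble(model, lambda)
  deriv_assembled(state, asm, drive)
}

deriv_assembled <- function(state, asm, drive = 0) {
  cn <- asm$cn
  V <- state[1:16]; gA <- state[17:32]; gN <- state[33:48]; gG <- state[49:64]
  rate <- firing_rate(V - cn$V_L, cn$rho1, cn$rho2)
  de <- if (length(drive) == 64) drive[17:32] else rep(drive, length.out = 16)
  aff <- tcm_afferents(asm, rate, de)
  m <- mg_block(V, cn$mg_alpha)
  dV <- (cn$g_L * (cn$V_L - V) + gA * (cn$V_AMPA - V) +
           gN * m * (cn$V_NMDA - V) + gG * (cn$V_GABA - V)) / cn$C
  c(dV,
    asm$kappa[, "AMPA"] * (aff$A - gA),
    asm$kappa[, "NMDA"] * (aff$N - gN),
    asm$kappa[, "GABA"] * (aff$G - gG))
}

# Analytic Jacobian of deriv_assembled, split into an undelayed part and
# delay groups (the dg/dV coupling blocks inherit their edge delays; in the
# frequency domain each group picks up the phase factor exp(-i w d)).
jacobian_assembled <- function(state, asm) {
  cn <- asm$cn
  V <- state[1:16]; gA <- state[17:32]; gN <- state[33:48]; gG <- state[49:64]
  m <- mg_block(V, cn$mg_alpha)
  mp <- mg_block_grad(V, cn$mg_alpha)
  sp <- firing_rate_grad(V - cn$V_L, cn$rho1, cn$rho2)
  rate <- firing_rate(V - cn$V_L, cn$rho1, cn$rho2)
  aff <- tcm_afferents(asm, rate)

  A0 <- matrix(0, 64, 64)
  iV <- 1:16; iA <- 17:32; iN <- 33:48; iG <- 49:64
  dVdV <- -(cn$g_L + gA + gN * m + gG) / cn$C + gN * mp * (cn$V_NMDA - V) / cn$C
  A0[cbind(iV, iV)] <- dVdV
  A0[cbind(iV, iA)] <- (cn$V_AMPA - V) / cn$C
  A0[cbind(iV, iN)] <- m * (cn$V_NMDA - V) / cn$C
  A0[cbind(iV, iG)] <- (cn$V_GABA - V) / cn$C
  A0[cbind(iA, iA)] <- -asm$kappa[, "AMPA"]
  A0[cbind(iN, iN)] <- -asm$kappa[, "NMDA"]
  A0[cbind(iG, iG)] <- -asm$kappa[, "GABA"]

  # clamp: zero sensitivity where the raw afferent is negative
  actA <- as.numeric(aff$rawA > 0); actN <- as.numeric(aff$rawN > 0)
  actG <- as.numeric(aff$rawG > 0)
  delayed <- lapply(c(`1` = "1", `8` = "8"), function(d) {
    Ad <- matrix(0, 64, 64)
    Ad[iA, iV] <- (asm$kappa[, "AMPA"] * actA) * asm$W$AMPA[[d]] *
      rep(sp, each = 16) * cn$g_scale
    Ad[iN, iV] <- (asm$kappa[, "NMDA"] * actN) * asm$W$NMDA[[d]] *
      rep(sp, each = 16) * cn$g_scale
    Ad[iG, iV] <- (asm$kappa[, "GABA"] * actG) * asm$W$GABA[[d]] *
      rep(sp, each = 16) * cn$g_scale
    Ad
  })
  list(A0 = A0, delayed = delayed,
       delays = c(`1` = 1, `8` = 8))
}

#' Jacobian of the state equations
#'
#' Analytic derivative of [state_derivative()] with respect to the state,
#' evaluated at `state` (typically a fixed point). Returns the full 64 x 64
#' matrix with all delayed coupling blocks included at zero lag; this is the
#' matrix whose eigenvalues determine local stability and that matches a
#' finite-difference derivative of [state_derivative()].
#'
#' @inheritParams state_derivative
#' @param state State vector, typically from [find_fixed_point()].
#' @return A 64 x 64 numeric matrix.
#' @export
tcm_jacobian <- function(state, model, lambda = NULL) {
  asm <- if (inherits(model, "tcm_assembled")) model else tcm_assemble(model, lambda)
  jb <- jacobian_assembled(state, asm)
  jb$A0 + jb$delayed$`1` + jb$delayed$`8`
}

#' Find the model's fixed point
#'
#' Damped Newton iteration from the leak equilibrium (all potentials at the
#' leak reversal, all conductances zero), using the analytic Jacobian, with a
#' fallback through a long noiseless integration if Newton stalls. The
#' returned state satisfies \eqn{\|\dot x\|_\infty < 10^{-8}}.
#'
#' @inheritParams state_derivative
#' @param x0 Optional warm-start state (length 64).
#' @param tol Convergence tolerance on the derivative max-norm.
#' @param max_iter Newton iteration budget.
#' @return Fixed-point state vector (length 64) with attribute `"residual"`.
#' @export
find_fixed_point <- function(model, lambda = NULL, x0 = NULL,
                             tol = 1e-10, max_iter = 100) {
  asm <- if (inherits(model, "tcm_assembled")) model else tcm_assemble(model, lambda)
  cn <- asm$cn
  x <- if (is.null(x0)) c(rep(cn$V_L, 16), rep(0, 48)) else x0
  f <- deriv_assembled(x, asm)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    jb <- jacobian_assembled(x, asm)
    J <- jb$A0 + jb$delayed$`1` + jb$delayed$`8`
    step <- tryCatch(-solve(J, f), error = function(e) NULL)
    if (is.null(step)) step <- -solve(J + diag(1e-6, 64), f)
    alpha <- 1
    repeat {
      xn <- x + alpha * step
      fn <- tryCatch(deriv_assembled(xn, asm), error = function(e) NULL)
      if (!is.null(fn) && max(abs(fn)) < max(abs(f))) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { xn <- x; fn <- f; break }
    }
    if (identical(xn, x)) break
    x <- xn; f <- fn
  }
  if (max(abs(f)) >= 1e-8) {
    # fallback: relax by noiseless integration, then retry Newton once
    x <- relax_to_equilibrium(asm, x)
    f <- deriv_assembled(x, asm)
    for (it in seq_len(max_iter)) {
      if (max(abs(f)) < tol) break
      jb <- jacobian_assembled(x, asm)
      J <- jb$A0 + jb$delayed$`1` + jb$delayed$`8`
      step <- -solve(J + diag(1e-9, 64), f)
      xn <- x + step
      fn <- deriv_assembled(xn, asm)
      if (max(abs(fn)) >= max(abs(f))) break
      x <- xn; f <- fn
    }
  }
  if (max(abs(f)) >= 1e-8) {
    stop("fixed point not found (residual ", format(max(abs(f)), digits = 3),
         ") for the supplied parameter set", call. = FALSE)
  }
  structure(x, residual = max(abs(f)))
}

relax_to_equilibrium <- function(asm, x, duration = 2000, dt = 0.05) {
  n <- ceiling(duration / dt)
  lag1 <- max(1L, round(asm$cn$delay_intrinsic / dt))
  lag8 <- max(1L, round(asm$cn$delay_extrinsic / dt))
  out <- cpp_integrate(asm$W$AMPA$`1`, asm$W$AMPA$`8`,
                       asm$W$NMDA$`1`, asm$W$NMDA$`8`,
                       asm$W$GABA$`1`, asm$W$GABA$`8`,
                       asm$kappa, asm$Cmat, x, asm$cn,
                       asm$drive, dt, n, matrix(0, 2, n),
                       c(3L, 8L, 11L, 16L), lag1, lag8, 1L, FALSE)
  as.numeric(out$state)
}
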