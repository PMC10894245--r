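#' One-way repeated-measures ANOVA across the three conditions
#'
#' Within-subject ANOVA of a subjects x conditions matrix, fitted with
#' `stats::aov` on the two-way (condition + subject) layout so the error
#' term is the condition-by-subject interaction:
#' \eqn{F = MS_{cond} / MS_{cond \times subj}}. The univariate degrees of
#' freedom are \eqn{(k-1, (k-1)(n-1))}; the multivariate-convention pair
#' \eqn{(k-1, n-k+1)} and its p-value are reported alongside, as some
#' published tables print that convention.
#'
#' @param x Numeric matrix, subjects x conditions (complete cases), at
#'   least 3 subjects.
#' @return One-row tibble: `F`, `df1`, `df2`, `p` (univariate),
#'   `df2_mv`, `p_mv`.
#' @export
rm_anova <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("missing or non-finite cells in the design",
                               call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  d <- data.frame(
    value = as.vector(x),
    cond = factor(rep(seq_len(k), each = n)),
    subj = factor(rep(seq_len(n), k))
  )
  fit <- stats::aov(value ~ cond + subj, data = d)
  tab <- summary(fit)[[1]]
  ms_cond <- tab["cond", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  Fv <- if (ms_err > 0) ms_cond / ms_err else 0
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  df2_mv <- n - k + 1
  if (ms_cond <= .Machine$double.eps * max(abs(x), 1)^2) Fv <- 0
  tibble::tibble(
    F = Fv, df1 = df1, df2 = df2,
    p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
    df2_mv = df2_mv,
    p_mv = stats::pf(Fv, df1, df2_mv, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values \eqn{\tilde p_{(i)} = \min_{j \ge i} (m p_{(j)} / j)}
#' capped at 1 and returned in input order (delegates to
#' `stats::p.adjust(..., "BH")`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length `n >= 4` with nonzero
#'   variance.
#' @return One-row tibble: `r`, `p` (two-sided, `n - 2` df), `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("need at least 4 paired observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Parameter families analysed at the group level
#'
#' The three families, each FDR-corrected internally: extrinsics (AMPA and
#' NMDA, forward and backward; 4 members), intrinsics (per node: SP
#' self-gain, SI->SP, RL->SS, TP->RL; 8 members) and time constants (per
#' node: AMPA, GABA-A, NMDA; 6 members). Time constants are reported on the
#' \eqn{\log \tau} scale, i.e. the negated rate-constant latent
#' (`transform = -1`).
#'
#' @return Tibble with `family`, `parameter` (reported name), `source`
#'   (fitted latent name), `transform` (+1/-1 multiplier).
#' @export
parameter_families <- function() {
  nodes <- c("frontal", "parietal")
  dplyr::bind_rows(
    tibble::tibble(
      family = "extrinsics",
      parameter = c("AMPA forward", "AMPA backward", "NMDA forward",
                    "NMDA backward"),
      source = c("ext_ampa_fwd", "ext_ampa_bwd", "ext_nmda_fwd",
                 "ext_nmda_bwd"),
      transform = 1
    ),
    purrr::map_dfr(nodes, function(nd) tibble::tibble(
      family = "intrinsics",
      parameter = paste(tools::toTitleCase(nd),
                        c("SP to SP", "SI to SP", "RL to SS", "TP to RL")),
      source = paste0("int_", nd, "_", c("sp_sp", "si_sp", "rl_ss", "tp_rl")),
      transform = 1
    )),
    purrr::map_dfr(nodes, function(nd) tibble::tibble(
      family = "time_constants",
      parameter = paste(tools::toTitleCase(nd), c("AMPA", "GABA", "NMDA")),
      source = paste0("kappa_", nd, "_", c("ampa", "gaba", "nmda")),
      transform = -1
    ))
  )
}

#' Group-level analysis of fitted parameters
#'
#' For each family member: extracts the posterior-mean latent per subject
#' and condition (time constants negated to the \eqn{\log\tau} scale), runs
#' the repeated-measures ANOVA over pre/bolus/infusion, and applies BH-FDR
#' within each family. Members significant before correction are carried to
#' Pearson correlations of their infusion-minus-pre change against the
#' clinical change scores at 24 h and 7 days, and those correlation
#' p-values are FDR-corrected as one set.
#'
#' @param fits A `cohort_fits` object, or a tibble with columns `subject`,
#'   `condition`, `parameter`, `estimate`.
#' @param clinical Tibble with `subject`, `change_24h`, `change_7d`; taken
#'   from `fits` when it is a `cohort_fits`.
#' @param families Family table as from [parameter_families()].
#' @param alpha Uncorrected threshold selecting members for correlation.
#' @return An object of class `stat_report` with tibbles `anova` and
#'   `correlations`.
#' @export
run_group_analysis <- function(fits, clinical = NULL,
                               families = parameter_families(),
                               alpha = 0.05) {
  if (inherits(fits, "cohort_fits")) {
    if (is.null(clinical)) clinical <- fits$clinical
    fits <- fits$estimates
  }
  conds <- c("pre", "bolus", "infusion")
  subjects <- sort(unique(fits$subject))
  get_matrix <- function(source, transform) {
    w <- fits[fits$parameter == source, ]
    m <- matrix(NA_real_, length(subjects), 3,
                dimnames = list(subjects, conds))
    for (cond in conds) {
      wc <- w[w$condition == cond, ]
      m[as.character(wc$subject), cond] <- wc$estimate * transform
    }
    if (any(!is.finite(m))) {
      stop("incomplete design: missing subject x condition cells for ",
           source, call. = FALSE)
    }
    m
  }
  an <- purrr::map_dfr(seq_len(nrow(families)), function(i) {
    m <- get_matrix(families$source[i], families$transform[i])
    dplyr::mutate(rm_anova(m),
                  family = families$family[i],
                  parameter = families$parameter[i],
                  source = families$source[i],
                  transform = families$transform[i],
                  change = mean(m[, "infusion"] - m[, "pre"]),
                  .before = 1)
  })
  an <- an |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_fdr = bh_fdr(.data$p)) |>
    dplyr::ungroup()

  cors <- tibble::tibble()
  if (!is.null(clinical) && length(subjects) >= 4) {
    sig <- an[an$p < alpha, ]
    rows <- list()
    for (i in seq_len(nrow(sig))) {
      m <- get_matrix(sig$source[i], sig$transform[i])
      delta <- m[, "infusion"] - m[, "pre"]
      cl <- clinical[match(subjects, clinical$subject), ]
      for (tp in c("change_24h", "change_7d")) {
        if (stats::sd(delta) == 0 || stats::sd(cl[[tp]]) == 0) next
        rows[[length(rows) + 1]] <- dplyr::mutate(
          pearson_correlation(delta, cl[[tp]]),
          parameter = sig$parameter[i], family = sig$family[i],
          timepoint = sub("change_", "", tp), .before = 1)
      }
    }
    if (length(rows)) {
      cors <- dplyr::bind_rows(rows)
      cors$p_fdr <- bh_fdr(cors$p)
    }
  }
  structure(list(anova = an, correlations = cors,
                 n = length(subjects), alpha = alpha),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("Thalamocortical model parameter changes (n = ", x$n, ")\n\n", sep = "")
  an <- x$anova
  for (fam in unique(an$family)) {
    cat(toupper(substring(fam, 1, 1)), substring(fam, 2), "\n", sep = "")
    w <- an[an$family == fam, ]
    for (i in seq_len(nrow(w))) {
      cat(sprintf("  %-18s F(%d,%d) = %6.2f   p = %-8.3g p(FDR) = %-8.3g%s\n",
                  w$parameter[i], w$df1[i], w$df2[i], w$F[i], w$p[i],
                  w$p_fdr[i], ifelse(w$p_fdr[i] < 0.05, " *", "")))
    }
  }
  if (nrow(x$correlations)) {
    cat("\nCorrelations with MADRS change\n")
    w <- x$correlations
    for (i in seq_len(nrow(w))) {
      cat(sprintf("  %-18s (%s)  r = %+.2f  p = %-8.3g p(FDR) = %-8.3g n = %d\n",
                  w$parameter[i], w$timepoint[i], w$r[i], w$p[i], w$p_fdr[i],
                  w$n[i]))
    }
  }
  invisible(x)
}

#' Tidy a stat report (the ANOVA table)
#'
#' @param x A `stat_report`.
#' @param ... Unused.
#' @export
tidy.stat_report <- function(x, ...) {
  dplyr::select(x$anova, "family", "parameter", "F", "df1", "df2", "p",
                "p_fdr", "p_mv", "change")
}

#' One-row summary of a stat report
#'
#' @param x A `stat_report`.
#' @param ... Unused.
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_parameters = nrow(x$anova),
    n_significant_uncorrected = sum(x$anova$p < x$alpha),
    n_significant_fdr = sum(x$anova$p_fdr < x$alpha),
    n_correlations = nrow(x$correlations)
  )
}

#' Write a stat report to CSV files
#'
#' @param x A `stat_report`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_stat_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "anova.csv")
  p2 <- file.path(dir, "correlations.csv")
  utils::write.csv(tidy(x), p1, row.names = FALSE)
  utils::write.csv(x$correlations, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
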