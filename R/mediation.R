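# Saturated linear path models testing whether factor-score mediators
# transmit the effect of alcohol exposure (AA/day) on growth and cognition,
# with smoking handled as an exogenous correlate (sensitivity switch to
# include it as a regression covariate), Sobel z-tests and bias-corrected
# bootstrap confidence intervals.

#' Describe a mediation model
#'
#' @param exposure,mediator,outcome column names in the data.
#' @param covariate optional smoking covariate column.
#' @param smoking_as_covariate if TRUE the covariate enters both regression
#'   equations; default FALSE models the exposure-smoking association as an
#'   exogenous covariance (it then does not alter the OLS path estimates).
#' @param standardize z-score all variables before fitting (default TRUE, so
#'   coefficients are standardized).
#' @return a `mediation_design` list.
#' @export
mediation_design <- function(exposure, mediator, outcome,
                             covariate = NULL,
                             smoking_as_covariate = FALSE,
                             standardize = TRUE) {
  structure(list(exposure = exposure, mediator = mediator,
                 outcome = outcome, covariate = covariate,
                 smoking_as_covariate = smoking_as_covariate,
                 standardize = standardize), class = "mediation_design")
}

mediation_frame <- function(design, data) {
  cols <- c(design$exposure, design$mediator, design$outcome,
            if (design$smoking_as_covariate) design$covariate)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (any(vapply(d, stats::sd, numeric(1)) < .Machine$double.eps)) {
    stop("zero variance in a mediation variable")
  }
  if (design$standardize) d[] <- lapply(d, function(x) as.numeric(scale(x)))
  d
}

#' Fit a single-mediator path model
#'
#' Product-of-coefficients mediation: `a` from `mediator ~ exposure`, `b`
#' and `c'` from `outcome ~ exposure + mediator` (plus the smoking covariate
#' in both equations under the sensitivity switch). The indirect effect is
#' `a * b`, tested with the Sobel z (delta-method SE); the total effect
#' equals `c' + a * b` exactly for least squares on the same sample.
#'
#' @param design a [mediation_design()].
#' @param data data.frame with the model columns.
#' @return a `mediation_result` list: `a`, `b`, `c_prime`, `indirect`,
#'   `total`, `z`, `p`, component SEs and p-values, `n`.
#' @export
fit_mediation <- function(design, data) {
  d <- mediation_frame(design, data)
  if (nrow(d) < 10) stop("fewer than 10 complete cases")
  cov_term <- if (design$smoking_as_covariate) {
    paste("+", design$covariate)
  } else ""
  f_m <- stats::as.formula(paste(design$mediator, "~", design$exposure,
                                 cov_term))
  f_y <- stats::as.formula(paste(design$outcome, "~", design$exposure,
                                 "+", design$mediator, cov_term))
  m_fit <- stats::lm(f_m, d)
  y_fit <- stats::lm(f_y, d)
  sa <- summary(m_fit)$coefficients[design$exposure, ]
  sb <- summary(y_fit)$coefficients[design$mediator, ]
  sc <- summary(y_fit)$coefficients[design$exposure, ]
  a <- sa[["Estimate"]]; b <- sb[["Estimate"]]; cp <- sc[["Estimate"]]
  indirect <- a * b
  se_ind <- sqrt(b^2 * sa[["Std. Error"]]^2 + a^2 * sb[["Std. Error"]]^2)
  if (se_ind < .Machine$double.eps) {
    z <- NA_real_; p <- 1
  } else {
    z <- indirect / se_ind
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(a = a, b = b, c_prime = cp,
                 se_a = sa[["Std. Error"]], se_b = sb[["Std. Error"]],
                 se_c_prime = sc[["Std. Error"]],
                 p_a = sa[["Pr(>|t|)"]], p_b = sb[["Pr(>|t|)"]],
                 p_c_prime = sc[["Pr(>|t|)"]],
                 indirect = indirect, total = cp + indirect,
                 se_indirect = se_ind, z = z, p = p, n = nrow(d),
                 design = design), class = "mediation_result")
}

#' Bias-corrected bootstrap CI for the indirect effect
#'
#' Case-resampling bootstrap of the full two-equation model; the
#' bias-corrected (BC, not accelerated) percentile interval shifts the
#' percentile bounds by `z0 = qnorm(P(boot < point estimate))`. Degenerate
#' resamples (constant columns) are skipped and counted. Classification:
#' "partial" iff both the direct and indirect effects are significant,
#' "full" iff only the indirect is, else "no_mediation".
#'
#' @param design a [mediation_design()].
#' @param data data.frame.
#' @param n_boot resamples (reference analysis: 10000; >= 1000 required).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list with `ci`, `boot` (indirect draws), `n_skipped`, `point`,
#'   `classification`.
#' @export
bootstrap_indirect_ci <- function(design, data, n_boot = 10000,
                                  level = 0.95, seed = 1L) {
  stopifnot(n_boot >= 1000)
  fit <- fit_mediation(design, data)
  d <- mediation_frame(design, data)
  n <- nrow(d)
  skipped <- 0L
  boot <- withr::with_seed(substream_seed(seed, 7), {
    vapply(seq_len(n_boot), function(b) {
      db <- d[sample.int(n, replace = TRUE), , drop = FALSE]
      res <- tryCatch(fit_mediation(design, db), error = function(e) NULL)
      if (is.null(res)) {
        skipped <<- skipped + 1L
        return(NA_real_)
      }
      res$indirect
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  z0 <- stats::qnorm(pmin(pmax(mean(boot < fit$indirect), 1 / n_boot),
                          1 - 1 / n_boot))
  alpha <- (1 - level) / 2
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha, 1 - alpha)))
  ci <- unname(stats::quantile(boot, probs, type = 7))
  sig_ind <- ci[1] > 0 || ci[2] < 0
  sig_dir <- fit$p_c_prime < 0.05
  list(ci = ci, boot = boot, n_skipped = skipped, point = fit$indirect,
       classification = if (sig_ind && sig_dir) "partial"
                        else if (sig_ind) "full" else "no_mediation")
}

#' Run a battery of mediation models
#'
#' For each outcome: three single-factor models (one per mediating factor)
#' plus one joint model with all three mediators entered together (their
#' residual correlations left free, which for least squares means each
#' mediator keeps its own exposure equation while the outcome equation
#' includes all mediators). Signs follow the delta-CT convention: a higher
#' factor score means lower expression of its miRNAs.
#'
#' @param data data.frame containing exposure, covariate, outcomes and
#'   factor-score columns.
#' @param factor_cols names of the mediator (factor score) columns.
#' @param outcome_cols names of the outcome columns.
#' @param exposure,covariate column names.
#' @param smoking_as_covariate see [mediation_design()].
#' @return data.frame, one row per outcome x mediator x model type with
#'   paths, indirect effects and p-values.
#' @export
run_mediation_battery <- function(data, factor_cols, outcome_cols,
                                  exposure = "aa_per_day",
                                  covariate = "cigarettes_per_day",
                                  smoking_as_covariate = FALSE) {
  rows <- list()
  for (y in outcome_cols) {
    for (f in factor_cols) {
      des <- mediation_design(exposure, f, y, covariate,
                              smoking_as_covariate)
      r <- fit_mediation(des, data)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = y, mediator = f, model = "single",
        a = r$a, b = r$b, c_prime = r$c_prime, indirect = r$indirect,
        total = r$total, z = r$z, p_indirect = r$p,
        p_direct = r$p_c_prime, n = r$n)
    }
    # joint model: outcome on exposure + all mediators
    cols <- c(exposure, factor_cols, y,
              if (smoking_as_covariate) covariate)
    d <- data[stats::complete.cases(data[, cols]), cols]
    d[] <- lapply(d, function(x) as.numeric(scale(x)))
    cov_term <- if (smoking_as_covariate) paste("+", covariate) else ""
    y_fit <- stats::lm(stats::as.formula(paste(
      y, "~", exposure, "+", paste(factor_cols, collapse = " + "),
      cov_term)), d)
    ys <- summary(y_fit)$coefficients
    for (f in factor_cols) {
      a_fit <- stats::lm(stats::as.formula(paste(f, "~", exposure,
                                                 cov_term)), d)
      as_ <- summary(a_fit)$coefficients[exposure, ]
      a <- as_[["Estimate"]]; b <- ys[f, "Estimate"]
      se_ind <- sqrt(b^2 * as_[["Std. Error"]]^2 +
                       a^2 * ys[f, "Std. Error"]^2)
      z <- if (se_ind > 0) a * b / se_ind else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        outcome = y, mediator = f, model = "joint",
        a = a, b = b, c_prime = ys[exposure, "Estimate"],
        indirect = a * b, total = NA_real_, z = z,
        p_indirect = if (is.na(z)) 1 else 2 * stats::pnorm(-abs(z)),
        p_direct = ys[exposure, "Pr(>|t|)"], n = nrow(d))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
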