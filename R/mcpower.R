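# Monte Carlo simulation harness for the CFA and mediation power studies:
# per-parameter coverage of 95 % confidence intervals, power at p < 0.05,
# percentage bias, and the convergence rate.

#' Percentage bias of an estimator
#'
#' `100 * (mean(estimates) - truth) / truth`.
#'
#' @param truth population value (non-zero).
#' @param estimates vector of estimates.
#' @return percentage bias.
#' @export
percent_bias <- function(truth, estimates) {
  if (truth == 0) stop("relative bias undefined for truth 0")
  100 * (mean(estimates) - truth) / truth
}

#' Monte Carlo power study for a CFA model
#'
#' Generates multivariate-normal data from a population correlated-factor
#' model (default: loadings 0.50, factor correlations 0.50, residual
#' variances 0.75, factor variances 1 — so items have unit variance), fits
#' each replicate with [fit_ml()], and aggregates per-parameter power
#' (|est/SE| > 1.96), coverage (est +/- 1.96 SE contains truth) and
#' percentage bias over the converged replicates. Non-convergence is
#' optimizer failure or a Heywood residual variance below -1e-6.
#'
#' @param spec a [cfa_spec()] (>= 3 items per factor); default is the
#'   18-item 3-factor allocation 8/5/5.
#' @param loading,factor_cov,residual_var population values.
#' @param n sample size per replicate (reference study: 59).
#' @param n_reps replicates (reference study: 10000; scaled-down runs use
#'   1000).
#' @param seed RNG seed.
#' @return a `power_result` list with per-parameter `power`, `coverage`,
#'   `percent_bias`, plus `n_reps`, `n_converged`, `seed`.
#' @export
simulate_cfa_power <- function(spec = default_power_cfa_spec(),
                               loading = 0.50, factor_cov = 0.50,
                               residual_var = 0.75, n = 59,
                               n_reps = 10000, seed = 1L) {
  stopifnot(all(lengths(spec$factors) >= 3))
  pat <- cfa_pattern(spec)
  p <- nrow(pat); k <- ncol(pat)
  Lambda <- pat * loading
  Phi <- matrix(factor_cov, k, k); diag(Phi) <- 1
  Sigma_pop <- Lambda %*% Phi %*% t(Lambda) + diag(residual_var, p)
  dimnames(Sigma_pop) <- list(spec$items, spec$items)

  nl <- sum(pat)
  nphi <- if (k > 1 && !spec$bifactor) k * (k - 1) / 2 else 0
  truth <- c(rep(loading, nl), rep(factor_cov, nphi),
             rep(residual_var, p))
  par_names <- c(paste0("loading_", spec$items),
                 if (nphi) paste0("phi_", seq_len(nphi)),
                 paste0("resvar_", spec$items))

  est <- se <- matrix(NA_real_, n_reps, length(truth))
  converged <- logical(n_reps)
  withr::with_seed(substream_seed(seed, 8), {
    for (r in seq_len(n_reps)) {
      dat <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma_pop)
      colnames(dat) <- spec$items
      fit <- tryCatch(fit_ml(spec, dat), error = function(e) NULL)
      if (is.null(fit) || !fit$converged || fit$heywood ||
          !fit$phi_proper) next
      th <- fit$theta[seq_len(length(truth))]
      # resolve factor sign indeterminacy: flip any factor whose loading
      # sum is negative, carrying its factor correlations along
      lam_col <- col(pat)[pat == 1L]
      for (kk in seq_len(k)) {
        if (sum(th[seq_len(nl)][lam_col == kk]) >= 0) next
        th[seq_len(nl)][lam_col == kk] <-
          -th[seq_len(nl)][lam_col == kk]
        if (nphi) {
          ut <- which(upper.tri(diag(k)), arr.ind = TRUE)
          hit <- xor(ut[, 1] == kk, ut[, 2] == kk)
          th[nl + which(hit)] <- -th[nl + which(hit)]
        }
      }
      converged[r] <- TRUE
      est[r, ] <- th
      se[r, ] <- fit$se[seq_len(length(truth))]
    }
  })
  ok <- converged & rowSums(is.na(se)) == 0
  zcrit <- stats::qnorm(0.975)
  est_ok <- est[ok, , drop = FALSE]
  se_ok <- se[ok, , drop = FALSE]
  tr <- matrix(truth, nrow(est_ok), length(truth), byrow = TRUE)
  power <- colMeans(abs(est_ok / se_ok) > zcrit)
  coverage <- colMeans(est_ok - zcrit * se_ok <= tr &
                         est_ok + zcrit * se_ok >= tr)
  bias <- vapply(seq_along(truth), function(j) {
    if (truth[j] == 0) return(NA_real_)
    percent_bias(truth[j], est_ok[, j])
  }, numeric(1))
  structure(list(
    n_reps = n_reps, n_converged = sum(ok),
    power = stats::setNames(power, par_names),
    coverage = stats::setNames(coverage, par_names),
    percent_bias = stats::setNames(bias, par_names),
    truth = stats::setNames(truth, par_names),
    groups = rep(c("loading", "factor_cov", "residual_var"),
                 c(nl, nphi, p)),
    seed = seed), class = "power_result")
}

#' Default 18-item 3-factor specification for the power study
#'
#' The item allocation (8/5/5) mirrors the factor sizes of the 2-week
#' measurement model.
#'
#' @param sizes items per factor.
#' @return a [cfa_spec()].
#' @export
default_power_cfa_spec <- function(sizes = c(8, 5, 5)) {
  items <- sprintf("item%02d", seq_len(sum(sizes)))
  cfa_spec(split(items, rep(paste0("F", seq_along(sizes)), sizes)))
}

#' Monte Carlo power study for the mediation model
#'
#' Simulates the standardized trivariate system `M = a X + e_m`,
#' `Y = c' X + b M + e_y` (all variables unit variance), fits the mediation
#' model per replicate, and aggregates power, coverage and percentage bias
#' for the direct path, the component paths, and the indirect effect
#' (delta-method SE).
#'
#' @param a,b,c_prime standardized population paths (reference study: 0.40).
#' @param n sample size (reference study: 58).
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @return a `power_result` list.
#' @export
simulate_mediation_power <- function(a = 0.4, b = 0.4, c_prime = 0.4,
                                     n = 58, n_reps = 10000, seed = 1L) {
  vm <- 1 - a^2
  vy <- 1 - c_prime^2 - b^2 - 2 * a * b * c_prime
  stopifnot(vm > 0, vy > 0)
  truth <- c(a = a, b = b, c_prime = c_prime, indirect = a * b)
  # the population is already standardized (unit variances), so replicates
  # are fitted raw: re-scaling each sample would distort the SEs
  des <- mediation_design("x", "m", "y", standardize = FALSE)
  est <- se <- matrix(NA_real_, n_reps, 4,
                      dimnames = list(NULL, names(truth)))
  withr::with_seed(substream_seed(seed, 9), {
    for (r in seq_len(n_reps)) {
      x <- stats::rnorm(n)
      m <- a * x + stats::rnorm(n, 0, sqrt(vm))
      y <- c_prime * x + b * m + stats::rnorm(n, 0, sqrt(vy))
      fit <- fit_mediation(des, data.frame(x = x, m = m, y = y))
      est[r, ] <- c(fit$a, fit$b, fit$c_prime, fit$indirect)
      se[r, ] <- c(fit$se_a, fit$se_b, fit$se_c_prime, fit$se_indirect)
    }
  })
  zcrit <- stats::qnorm(0.975)
  power <- colMeans(abs(est / se) > zcrit)
  coverage <- vapply(seq_along(truth), function(j) {
    mean(est[, j] - zcrit * se[, j] <= truth[j] &
           est[, j] + zcrit * se[, j] >= truth[j])
  }, numeric(1))
  bias <- vapply(seq_along(truth), function(j) {
    if (truth[j] == 0) return(NA_real_)
    percent_bias(truth[j], est[, j])
  }, numeric(1))
  structure(list(
    n_reps = n_reps, n_converged = n_reps,
    power = power,
    coverage = stats::setNames(coverage, names(truth)),
    percent_bias = stats::setNames(bias, names(truth)),
    truth = truth, seed = seed), class = "power_result")
}
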