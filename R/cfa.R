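# Confirmatory factor analysis engine: maximum-likelihood estimation of
# unidimensional, correlated-k-factor and bifactor measurement models for
# the miRNA factor structures, with fit indices, information criteria,
# nested chi-square difference tests, the Bartlett small-sample correction,
# and omega / maximal-reliability-H coefficients.
#
# Identification: factor variances fixed to 1 (all loadings free); bifactor
# models constrain the general factor orthogonal to the specific factors and
# the specific factors mutually orthogonal. Mean structure is excluded
# (covariance-only fitting); free parameters are the loadings, the factor
# correlations (correlated models), the residual variances and any declared
# residual covariances.

#' Specify a confirmatory factor model
#'
#' @param factors named list mapping factor name -> character vector of item
#'   ids; every item belongs to exactly one specific factor.
#' @param bifactor if TRUE, adds a general factor loading on all items;
#'   all factors are then mutually orthogonal.
#' @param residual_pairs optional list of 2-vectors of item ids whose
#'   residuals covary.
#' @return a `cfa_spec` object.
#' @export
cfa_spec <- function(factors, bifactor = FALSE, residual_pairs = NULL) {
  items <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(items)) {
    stop("every item must be assigned to exactly one specific factor")
  }
  for (pr in residual_pairs) {
    stopifnot(length(pr) == 2, all(pr %in% items), pr[1] != pr[2])
  }
  structure(list(factors = factors, items = items,
                 k = length(factors) + as.integer(bifactor),
                 bifactor = bifactor,
                 residual_pairs = residual_pairs), class = "cfa_spec")
}

#' Read/write a CFA specification as YAML
#'
#' @param path YAML file with fields `factors`, optional `bifactor` and
#'   `residual_pairs`.
#' @return a [cfa_spec()].
#' @export
read_cfa_spec <- function(path) {
  y <- yaml::read_yaml(path)
  cfa_spec(lapply(y$factors, unlist), bifactor = isTRUE(y$bifactor),
           residual_pairs = lapply(y$residual_pairs, unlist))
}

#' @rdname read_cfa_spec
#' @param spec a `cfa_spec`; @param path output file.
#' @export
write_cfa_spec <- function(spec, path) {
  yaml::write_yaml(list(factors = spec$factors, bifactor = spec$bifactor,
                        residual_pairs = spec$residual_pairs), path)
  invisible(path)
}

# loading pattern: p x k 0/1 matrix of free loadings
cfa_pattern <- function(spec) {
  p <- length(spec$items)
  kspec <- length(spec$factors)
  pat <- matrix(0L, p, kspec + as.integer(spec$bifactor),
                dimnames = list(spec$items, c(names(spec$factors),
                                              if (spec$bifactor) "general")))
  for (f in seq_len(kspec)) {
    pat[match(spec$factors[[f]], spec$items), f] <- 1L
  }
  if (spec$bifactor) pat[, kspec + 1L] <- 1L
  pat
}

# unpack theta -> Lambda, Phi, Psi(matrix with residual covariances)
cfa_unpack <- function(theta, spec, pat) {
  p <- nrow(pat); k <- ncol(pat)
  nl <- sum(pat)
  Lambda <- matrix(0, p, k, dimnames = dimnames(pat))
  Lambda[pat == 1L] <- theta[seq_len(nl)]
  pos <- nl
  Phi <- diag(k)
  if (!spec$bifactor && k > 1) {
    nphi <- k * (k - 1) / 2
    Phi[upper.tri(Phi)] <- theta[pos + seq_len(nphi)]
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    pos <- pos + nphi
  }
  psi <- theta[pos + seq_len(p)]
  pos <- pos + p
  Theta <- diag(psi, p)
  dimnames(Theta) <- list(rownames(pat), rownames(pat))
  for (i in seq_along(spec$residual_pairs)) {
    pr <- match(spec$residual_pairs[[i]], rownames(pat))
    Theta[pr[1], pr[2]] <- Theta[pr[2], pr[1]] <- theta[pos + i]
  }
  list(Lambda = Lambda, Phi = Phi, Theta = Theta, psi = psi)
}

cfa_n_free <- function(spec, pat) {
  sum(pat) +
    (if (!spec$bifactor && ncol(pat) > 1) ncol(pat) * (ncol(pat) - 1) / 2
     else 0) +
    nrow(pat) + length(spec$residual_pairs)
}

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p and its
# analytic gradient; non-PD Sigma handled by a ridge so the optimizer can
# retreat smoothly.
cfa_objective <- function(S, spec, pat, logdetS) {
  p <- nrow(S)
  fn <- function(theta) {
    par <- cfa_unpack(theta, spec, pat)
    Sigma <- par$Lambda %*% par$Phi %*% t(par$Lambda) + par$Theta
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
      ridge <- abs(min(ev)) + 1e-4
      ch <- tryCatch(chol(Sigma + ridge * diag(p)),
                     error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      pen <- 1e3 * ridge
    } else pen <- 0
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    logdet + sum(Sinv * S) - logdetS - p + pen
  }
  gr <- function(theta) {
    par <- cfa_unpack(theta, spec, pat)
    Sigma <- par$Lambda %*% par$Phi %*% t(par$Lambda) + par$Theta
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
      ch <- chol(Sigma + (abs(min(ev)) + 1e-4) * diag(p))
    }
    Sinv <- chol2inv(ch)
    A <- Sinv - Sinv %*% S %*% Sinv      # dF/dSigma (x2 off-diagonal)
    gL <- 2 * (A %*% par$Lambda %*% par$Phi)
    g <- gL[pat == 1L]
    if (!spec$bifactor && ncol(pat) > 1) {
      gPhi <- t(par$Lambda) %*% A %*% par$Lambda
      g <- c(g, 2 * gPhi[upper.tri(gPhi)])
    }
    g <- c(g, diag(A))
    for (pr in spec$residual_pairs) {
      i <- match(pr, rownames(pat))
      g <- c(g, 2 * A[i[1], i[2]])
    }
    g
  }
  list(fn = fn, gr = gr)
}

# derivative matrices dSigma/dtheta_a, in theta order
cfa_dsigma <- function(par, spec, pat) {
  p <- nrow(pat); k <- ncol(pat)
  LP <- par$Lambda %*% par$Phi
  out <- list()
  idx <- which(pat == 1L, arr.ind = TRUE)
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]; m <- idx[q, 2]
    D <- matrix(0, p, p)
    D[i, ] <- LP[, m]
    D <- D + t(D)
    out[[length(out) + 1]] <- D
  }
  if (!spec$bifactor && k > 1) {
    ut <- which(upper.tri(diag(k)), arr.ind = TRUE)
    for (q in seq_len(nrow(ut))) {
      lm_ <- par$Lambda[, ut[q, 1]]; ln_ <- par$Lambda[, ut[q, 2]]
      out[[length(out) + 1]] <- outer(lm_, ln_) + outer(ln_, lm_)
    }
  }
  for (i in seq_len(p)) {
    D <- matrix(0, p, p); D[i, i] <- 1
    out[[length(out) + 1]] <- D
  }
  for (pr in spec$residual_pairs) {
    i <- match(pr, rownames(pat))
    D <- matrix(0, p, p); D[i[1], i[2]] <- D[i[2], i[1]] <- 1
    out[[length(out) + 1]] <- D
  }
  out
}

cfa_start <- function(S, spec, pat, inflate = 1) {
  p <- nrow(S)
  v <- diag(S)
  # principal-axis flavored starts: first eigenvector scaled per item
  e1 <- eigen(stats::cov2cor(S), symmetric = TRUE)$vectors[, 1]
  lam0 <- abs(e1) * sqrt(v) * 0.8
  lam_mat <- matrix(rep(lam0, ncol(pat)), nrow = p)
  theta <- lam_mat[pat == 1L]
  if (spec$bifactor) {
    # split variance between general and specific starts
    theta <- theta / sqrt(2)
  }
  if (!spec$bifactor && ncol(pat) > 1) {
    theta <- c(theta, rep(0.3, ncol(pat) * (ncol(pat) - 1) / 2))
  }
  theta <- c(theta, pmax(v * 0.5 * inflate, 0.05))
  theta <- c(theta, rep(0, length(spec$residual_pairs)))
  theta
}

#' Fit a CFA model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p` by
#' quasi-Newton (BFGS) with the analytic gradient, starting from
#' principal-axis-style values, with up to 5 ridge restarts when the search
#' hits a non-positive-definite model covariance. `chi2 = (n - 1) * F_min`;
#' standard errors come from the inverse expected (Fisher) information of
#' the covariance structure, evaluated analytically at the solution. The
#' independence model is fitted internally as the baseline for CFI/TLI.
#'
#' @param spec a [cfa_spec()].
#' @param data matrix or data.frame, subjects x items (complete cases).
#' @return a `cfa_fit` list: loadings, standardized loadings, residual
#'   variances/covariances, factor covariance matrix, `chi2`, `df`,
#'   `p_value`, fit indices, information criteria, `converged`, `n_obs`,
#'   `heywood` flag.
#' @export
fit_ml <- function(spec, data) {
  data <- as.matrix(data[, spec$items, drop = FALSE])
  if (anyNA(data)) stop("complete data required")
  n <- nrow(data)
  p <- ncol(data)
  S <- stats::cov(data)
  logdetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  pat <- cfa_pattern(spec)
  obj <- cfa_objective(S, spec, pat, logdetS)

  best <- NULL
  for (attempt in 0:5) {
    theta0 <- cfa_start(S, spec, pat, inflate = 1 + attempt)
    opt <- tryCatch(
      stats::optim(theta0, obj$fn, obj$gr, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (!is.null(best) && best$convergence == 0 &&
        is.finite(best$value) && best$value < 1e9) break
  }
  if (is.null(best)) {
    stop("CFA optimization failed on all restarts")
  }
  theta <- best$par
  par <- cfa_unpack(theta, spec, pat)
  Sigma <- par$Lambda %*% par$Phi %*% t(par$Lambda) + par$Theta
  Fmin <- obj$fn(theta)
  chi2 <- (n - 1) * Fmin
  q <- cfa_n_free(spec, pat)
  df <- p * (p + 1) / 2 - q
  heywood <- any(par$psi < -1e-6)
  # with unit factor variances the factor covariance must be a proper
  # correlation matrix; improper solutions are flagged, not hidden
  phi_proper <- all(abs(par$Phi[upper.tri(par$Phi)]) <= 1) &&
    min(eigen(par$Phi, symmetric = TRUE, only.values = TRUE)$values) > 0
  converged <- best$convergence == 0 && is.finite(Fmin) && Fmin < 1e9

  # expected (Fisher) information of the covariance structure:
  # I[a,b] = (n-1)/2 tr(Sigma^-1 dSigma_a Sigma^-1 dSigma_b)
  se <- rep(NA_real_, length(theta))
  H <- tryCatch({
    Sinv <- solve(Sigma)
    dS <- cfa_dsigma(par, spec, pat)
    B <- lapply(dS, function(D) Sinv %*% D)
    q_all <- length(B)
    I <- matrix(0, q_all, q_all)
    for (a in seq_len(q_all)) {
      for (b2 in a:q_all) {
        I[a, b2] <- I[b2, a] <- sum(B[[a]] * t(B[[b2]]))
      }
    }
    0.5 * (n - 1) * I
  }, error = function(e) NULL)
  if (!is.null(H)) {
    covt <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(covt)) {
      dg <- diag(covt)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }

  # baseline (independence) model for CFI/TLI
  chi2_b <- (n - 1) * (sum(log(diag(S))) - logdetS)
  df_b <- p * (p - 1) / 2

  std_load <- sweep(par$Lambda, 1, sqrt(diag(Sigma)), "/")
  idx <- fit_indices(chi2, df, chi2_b, df_b, n, S = S, Sigma = Sigma)

  # ML loglik of the fitted covariance structure (saturated means)
  S_ml <- S * (n - 1) / n
  Sinv <- solve(Sigma)
  ll <- -0.5 * n * (p * log(2 * pi) +
                      as.numeric(determinant(Sigma, TRUE)$modulus) +
                      sum(Sinv * S_ml))
  ic <- information_criteria(ll, q, n)

  names(se) <- NULL
  structure(list(
    spec = spec, loadings = par$Lambda, std_loadings = std_load,
    residual_variances = stats::setNames(par$psi, spec$items),
    residual_covariances = if (length(spec$residual_pairs)) {
      vapply(spec$residual_pairs,
             function(pr) par$Theta[pr[1], pr[2]], numeric(1))
    } else numeric(0),
    factor_covariance = par$Phi,
    theta = theta, se = se, pattern = pat,
    chi2 = chi2, df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
              else NA_real_,
    CFI = idx$CFI, TLI = idx$TLI, RMSEA = idx$RMSEA,
    RMSEA_CI = idx$RMSEA_CI, SRMR = idx$SRMR,
    chi2_baseline = chi2_b, df_baseline = df_b,
    loglik = ll, n_free = q,
    AIC = ic$AIC, BIC = ic$BIC, SABIC = ic$SABIC,
    Sigma = Sigma, S = S,
    converged = converged, heywood = heywood, phi_proper = phi_proper,
    n_obs = n),
    class = "cfa_fit")
}

#' Descriptive fit indices
#'
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`;
#' `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`;
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))` with a 90 % CI from
#' inversion of the noncentral chi-square; SRMR from the standardized
#' residual matrix when `S` and `Sigma` are supplied. With `df = 0`,
#' RMSEA = 0 and CFI = 1 by convention.
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param chi2_baseline,df_baseline independence-model values.
#' @param n sample size.
#' @param S,Sigma optional sample and model-implied covariance for SRMR.
#' @param ci_level RMSEA CI level (default 0.90).
#' @return list with `CFI`, `TLI`, `RMSEA`, `RMSEA_CI`, `SRMR`.
#' @export
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n,
                        S = NULL, Sigma = NULL, ci_level = 0.90) {
  stopifnot(df >= 0)
  if (df == 0) {
    cfi <- 1; tli <- 1; rmsea <- 0; ci <- c(0, 0)
  } else {
    num <- max(chi2 - df, 0)
    den <- max(chi2_baseline - df_baseline, chi2 - df, 0)
    cfi <- if (den > 0) 1 - num / den else 1
    rb <- chi2_baseline / df_baseline
    tli <- if (rb > 1) (rb - chi2 / df) / (rb - 1) else 1
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    a <- (1 - ci_level) / 2
    ncp_root <- function(target) {
      f <- function(l) stats::pchisq(chi2, df, ncp = l) - target
      if (f(0) < 0) return(NA_real_)
      up <- max(chi2 * 2, 10)
      while (f(up) > 0 && up < 1e7) up <- up * 2
      if (f(up) > 0) return(NA_real_)
      stats::uniroot(f, c(0, up), tol = 1e-8)$root
    }
    lo <- ncp_root(1 - a)
    hi <- ncp_root(a)
    ci <- c(if (is.na(lo)) 0 else sqrt(lo / (df * (n - 1))),
            if (is.na(hi)) 0 else sqrt(hi / (df * (n - 1))))
  }
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    sdv <- sqrt(diag(S))
    res <- (S - Sigma) / outer(sdv, sdv)
    srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  }
  list(CFI = cfi, TLI = tli, RMSEA = rmsea, RMSEA_CI = ci, SRMR = srmr)
}

#' Information criteria
#'
#' `AIC = -2LL + 2q`; `BIC = -2LL + q ln(n)`;
#' `SABIC = -2LL + q ln((n + 2) / 24)`.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters q.
#' @param n_obs sample size.
#' @return list with `AIC`, `BIC`, `SABIC`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  m2ll <- -2 * loglik
  list(AIC = m2ll + 2 * n_params,
       BIC = m2ll + n_params * log(n_obs),
       SABIC = m2ll + n_params * log((n_obs + 2) / 24))
}

#' Chi-square difference test for nested models
#'
#' @param fit_nested,fit_general `cfa_fit` objects (or lists with `chi2`,
#'   `df`); the nested model has more degrees of freedom.
#' @return list with `delta_chi2`, `delta_df`, `p`.
#' @export
chi2_difference <- function(fit_nested, fit_general) {
  stopifnot(fit_nested$df > fit_general$df)
  d2 <- fit_nested$chi2 - fit_general$chi2
  ddf <- fit_nested$df - fit_general$df
  if (d2 < 0) {
    warning("negative chi-square difference; p reported as 1")
    return(list(delta_chi2 = d2, delta_df = ddf, p = 1))
  }
  list(delta_chi2 = d2, delta_df = ddf,
       p = stats::pchisq(d2, ddf, lower.tail = FALSE))
}

#' Bartlett small-sample correction
#'
#' Multiplies the ML chi-square by `1 - (4k + 2p + 5) / (6n)` with k latent
#' variables, p observed variables and n the sample size plus one.
#'
#' @param chi2 uncorrected chi-square.
#' @param k number of latent variables.
#' @param p number of observed variables.
#' @param n_plus_one the sample size + 1.
#' @return list with `factor`, `chi2_corrected`.
#' @export
bartlett_correction <- function(chi2, k, p, n_plus_one) {
  f <- 1 - (4 * k + 2 * p + 5) / (6 * n_plus_one)
  if (f <= 0) stop("Bartlett corrective factor non-positive: n too small")
  list(factor = f, chi2_corrected = chi2 * f)
}

#' Apply the Bartlett correction to a fitted model
#'
#' Recomputes the omnibus p-value and, on request, CFI/TLI/RMSEA from the
#' corrected chi-square (baseline chi-square corrected with k = 0).
#'
#' @param fit a `cfa_fit`.
#' @param recompute_indices recompute CFI/TLI/RMSEA from corrected chi2.
#' @return list with `factor`, `chi2_corrected`, `p_corrected`, and
#'   optionally corrected indices.
#' @export
bartlett_corrected_fit <- function(fit, recompute_indices = TRUE) {
  bc <- bartlett_correction(fit$chi2, k = fit$spec$k,
                            p = length(fit$spec$items),
                            n_plus_one = fit$n_obs + 1)
  out <- c(bc, list(
    p_corrected = if (fit$df > 0) {
      stats::pchisq(bc$chi2_corrected, fit$df, lower.tail = FALSE)
    } else NA_real_))
  if (recompute_indices) {
    idx <- fit_indices(bc$chi2_corrected, fit$df, fit$chi2_baseline,
                       fit$df_baseline, fit$n_obs,
                       S = fit$S, Sigma = fit$Sigma)
    out$CFI <- idx$CFI; out$TLI <- idx$TLI
    out$RMSEA <- idx$RMSEA; out$RMSEA_CI <- idx$RMSEA_CI
  }
  out
}

#' Omega total reliability
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum Var(eps) +
#' 2 sum residual covariances)` — the collinearity-adjusted composite
#' reliability of a factor.
#'
#' @param loadings factor loadings of the items.
#' @param residual_variances residual variances of the items.
#' @param residual_covariances covariances among the items' residuals
#'   (default none).
#' @return omega in `[0, 1]` for non-negative loadings.
#' @export
omega_total <- function(loadings, residual_variances,
                        residual_covariances = numeric(0)) {
  num <- sum(loadings)^2
  den <- num + sum(residual_variances) + 2 * sum(residual_covariances)
  if (den <= 0) stop("non-positive denominator in omega")
  num / den
}

#' Maximal reliability H
#'
#' `H = sum(l^2 / (1 - l^2)) / (1 + sum(l^2 / (1 - l^2)))` over the
#' standardized loadings; invariant to loading sign, never less than the
#' reliability of the best item.
#'
#' @param std_loadings standardized loadings, all `|l| < 1`.
#' @return H in `[0, 1)`.
#' @export
maximal_reliability_H <- function(std_loadings) {
  if (any(abs(std_loadings) >= 1)) {
    stop("standardized loadings must satisfy |l| < 1")
  }
  s <- sum(std_loadings^2 / (1 - std_loadings^2))
  s / (1 + s)
}

#' Per-subject factor mean scores
#'
#' The score of a factor is the unweighted mean delta-CT of its items
#' (lower score = higher expression of the factor's miRNAs).
#'
#' @param delta_ct matrix (miRNA x sample).
#' @param spec a [cfa_spec()].
#' @return matrix samples x factors.
#' @export
factor_mean_scores <- function(delta_ct, spec) {
  missing <- setdiff(spec$items, rownames(delta_ct))
  if (length(missing)) {
    stop("items absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  out <- vapply(spec$factors, function(items) {
    colMeans(delta_ct[items, , drop = FALSE])
  }, numeric(ncol(delta_ct)))
  rownames(out) <- colnames(delta_ct)
  out
}

#' Model-comparison table
#'
#' Summarizes fitted models the way nested measurement-model comparisons are
#' reported: chi-square, df, p, delta-chi-square against the named reference,
#' and information criteria.
#'
#' @param fits named list of `cfa_fit` objects, ordered most- to
#'   least-restrictive.
#' @return data.frame, one row per model.
#' @export
model_comparison_table <- function(fits) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    row <- data.frame(model = names(fits)[i], chi2 = f$chi2, df = f$df,
                      p = f$p_value, delta_chi2 = NA_real_,
                      delta_df = NA_integer_, delta_p = NA_real_,
                      AIC = f$AIC, BIC = f$BIC, SABIC = f$SABIC)
    if (i > 1 && fits[[i - 1]]$df > f$df) {
      dd <- chi2_difference(fits[[i - 1]], f)
      row$delta_chi2 <- dd$delta_chi2
      row$delta_df <- dd$delta_df
      row$delta_p <- dd$p
    }
    row
  })
  do.call(rbind, rows)
}
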