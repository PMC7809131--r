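# ML CFA engine: oracle equivalence, df bookkeeping, indices, Bartlett,
# reliability coefficients, factor scores.

test_that("chi-square matches a brute-force oracle on small models", {
  for (s in 1:3) {
    withr::with_seed(600 + s, {
      lam <- stats::runif(4, 0.4, 0.9)
      X <- MASS::mvrnorm(80, rep(0, 4),
                         outer(lam, lam) + diag(stats::runif(4, 0.4, 1)))
    })
    colnames(X) <- letters[1:4]
    spec <- cfa_spec(list(F1 = letters[1:4]))
    fit <- fit_ml(spec, X)
    oracle <- brute_force_cfa_chi2(stats::cov(X), nrow(X))
    expect_lt(abs(fit$chi2 - oracle), 1e-4)
  }
})

test_that("saturated and near-saturated df bookkeeping is exact", {
  withr::with_seed(61, {
    X3 <- MASS::mvrnorm(150, rep(0, 3),
                        outer(c(.6, .7, .5), c(.6, .7, .5)) + diag(.5, 3))
  })
  colnames(X3) <- letters[1:3]
  f3 <- fit_ml(cfa_spec(list(F1 = letters[1:3])), X3)
  expect_equal(f3$df, 0)
  expect_lt(abs(f3$chi2), 1e-6)
  # saturated model reproduces S exactly
  expect_equal(f3$Sigma, f3$S, tolerance = 1e-6)
  expect_equal(f3$RMSEA, 0)
  expect_equal(f3$CFI, 1)

  withr::with_seed(62, {
    X4 <- MASS::mvrnorm(150, rep(0, 4), diag(4) + 0.4)
  })
  colnames(X4) <- letters[1:4]
  f4 <- fit_ml(cfa_spec(list(F1 = letters[1:4])), X4)
  expect_equal(f4$df, 2)        # 10 moments - 8 free parameters
})

test_that("a 3-factor population is recovered at large n", {
  spec <- default_power_cfa_spec()
  pat <- matrix(0, 18, 3)
  for (f in 1:3) pat[match(spec$factors[[f]], spec$items), f] <- 1
  Phi <- matrix(0.5, 3, 3); diag(Phi) <- 1
  Sigma <- (pat * 0.5) %*% Phi %*% t(pat * 0.5) + diag(0.75, 18)
  withr::with_seed(63, {
    X <- MASS::mvrnorm(5000, rep(0, 18), Sigma)
  })
  colnames(X) <- spec$items
  fit <- fit_ml(spec, X)
  expect_true(fit$converged)
  lam <- fit$loadings[fit$pattern == 1]
  expect_lt(max(abs(abs(lam) - 0.5)), 0.05)
  expect_lt(mean(abs(abs(lam) - 0.5)), 0.02)
  phi <- fit$factor_covariance[upper.tri(fit$factor_covariance)]
  expect_lt(max(abs(abs(phi) - 0.5)), 0.05)
  expect_lt(max(abs(fit$residual_variances - 0.75)), 0.05)
  expect_equal(fit$df, 18 * 19 / 2 - 39)
})

test_that("bifactor and residual-covariance specifications count free
           parameters correctly", {
  items <- sprintf("i%d", 1:6)
  bi <- cfa_spec(list(A = items[1:3], B = items[4:6]), bifactor = TRUE)
  # 6 specific + 6 general loadings + 6 residuals = 18; moments = 21
  withr::with_seed(64, {
    X <- MASS::mvrnorm(300, rep(0, 6), diag(6) + 0.45)
  })
  colnames(X) <- items
  fbi <- fit_ml(bi, X)
  expect_equal(fbi$df, 21 - 18)
  expect_equal(unname(fbi$factor_covariance),
               unname(diag(3)))   # orthogonal by constraint

  rc <- cfa_spec(list(A = items[1:3], B = items[4:6]),
                 residual_pairs = list(c("i1", "i4")))
  frc <- fit_ml(rc, X)
  # 12 loadings+residuals... 6 loadings + 1 phi + 6 resvar + 1 rescov = 14
  expect_equal(frc$df, 21 - 14)
  expect_error(cfa_spec(list(A = items[1:3], B = items[c(3, 4)])),
               "exactly one")
})

test_that("fit indices follow their definitions", {
  idx <- fit_indices(115, 115, 500, 135, 56)
  expect_equal(idx$RMSEA, 0)
  expect_equal(idx$CFI, 1)
  # hand evaluation: chi2 160, df 115, n 56
  idx2 <- fit_indices(160, 115, 800, 135, 56)
  expect_equal(idx2$RMSEA, sqrt(45 / (115 * 55)), tolerance = 1e-12)
  expect_equal(round(idx2$RMSEA, 4), 0.0843)
  expect_true(idx2$CFI <= 1 && idx2$TLI <= 1)
  expect_true(idx2$RMSEA_CI[1] <= idx2$RMSEA &&
                idx2$RMSEA <= idx2$RMSEA_CI[2] + 1e-12)
})

test_that("information criteria match hand arithmetic", {
  ic0 <- information_criteria(-50, 0, 56)
  expect_equal(ic0$AIC, 100)
  expect_equal(ic0$BIC, 100)
  expect_equal(ic0$SABIC, 100)
  ic <- information_criteria(-50, 10, 56)
  expect_equal(ic$AIC, 120)
  expect_equal(round(ic$BIC, 2), 140.25)
  expect_equal(round(ic$SABIC, 2), 108.82)
})

test_that("nested chi-square differences reproduce the printed deltas", {
  d1 <- chi2_difference(list(chi2 = 179.058, df = 118),
                        list(chi2 = 149.170, df = 115))
  expect_equal(d1$delta_chi2, 29.888)
  expect_equal(d1$delta_df, 3)
  expect_lt(d1$p, 0.001)
  d2 <- chi2_difference(list(chi2 = 332.276, df = 206),
                        list(chi2 = 274.617, df = 203))
  expect_equal(d2$delta_chi2, 57.659)
  same <- chi2_difference(list(chi2 = 100, df = 10),
                          list(chi2 = 100, df = 8))
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p, 1)
  expect_warning(neg <- chi2_difference(list(chi2 = 90, df = 10),
                                        list(chi2 = 100, df = 8)),
                 "negative")
  expect_equal(neg$p, 1)
})

test_that("Bartlett correction follows the corrective-factor formula", {
  b1 <- bartlett_correction(274.617, k = 3, p = 22, n_plus_one = 68)
  expect_equal(b1$factor, 1 - 61 / 408, tolerance = 1e-12)
  expect_equal(round(b1$chi2_corrected, 2), 233.56)
  b2 <- bartlett_correction(100, k = 3, p = 18, n_plus_one = 57)
  expect_equal(b2$factor, 1 - 53 / 342, tolerance = 1e-12)
  # large-n limit
  b3 <- bartlett_correction(100, 3, 22, 1e9)
  expect_equal(b3$chi2_corrected, 100, tolerance = 1e-5)
  expect_error(bartlett_correction(100, 3, 22, 10), "non-positive")

  # corrected chi2 < chi2, corrected p > uncorrected p
  withr::with_seed(65, {
    X <- MASS::mvrnorm(60, rep(0, 6), diag(6) + 0.4)
  })
  colnames(X) <- sprintf("i%d", 1:6)
  fit <- fit_ml(cfa_spec(list(A = sprintf("i%d", 1:6))), X)
  bc <- bartlett_corrected_fit(fit)
  expect_lt(bc$factor, 1)
  expect_lt(bc$chi2_corrected, fit$chi2)
  expect_gte(bc$p_corrected, fit$p_value)
})

test_that("omega and maximal reliability H satisfy their identities", {
  expect_equal(omega_total(rep(0.5, 4), rep(0.75, 4)), 4 / 7,
               tolerance = 1e-12)
  expect_equal(omega_total(rep(0, 4), rep(0.75, 4)), 0)
  # positive residual covariance strictly decreases omega
  expect_lt(omega_total(rep(0.5, 4), rep(0.75, 4), 0.2),
            omega_total(rep(0.5, 4), rep(0.75, 4)))

  expect_equal(maximal_reliability_H(0.6), 0.36, tolerance = 1e-12)
  expect_equal(maximal_reliability_H(rep(0, 3)), 0)
  expect_equal(maximal_reliability_H(c(0.5, -0.5)),
               maximal_reliability_H(c(0.5, 0.5)))
  expect_error(maximal_reliability_H(c(0.5, 1)), "< 1")
  # H is never below the best item's reliability
  for (s in 1:20) {
    l <- withr::with_seed(700 + s, stats::runif(5, -0.95, 0.95))
    expect_gte(maximal_reliability_H(l) + 1e-12, max(l^2))
  }
})

test_that("factor mean scores are item averages on the delta-CT scale", {
  dct <- rbind(a = c(1, 2), b = c(3, 4), c = c(10, 20))
  colnames(dct) <- c("s1", "s2")
  spec <- cfa_spec(list(F1 = c("a", "b"), F2 = "c"))
  sc <- factor_mean_scores(dct, spec)
  expect_equal(unname(sc[, "F1"]), c(2, 3))
  expect_equal(unname(sc[, "F2"]), c(10, 20))
  # linearity: adding a constant to items shifts the score by it
  sc2 <- factor_mean_scores(dct + 5, spec)
  expect_equal(sc2, sc + 5)
  expect_error(factor_mean_scores(dct[1:2, ], spec), "absent")
})

test_that("YAML model specifications round-trip", {
  spec <- cfa_spec(list(F1 = c("a", "b", "c"), F2 = c("d", "e")),
                   residual_pairs = list(c("a", "d")))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cfa_spec(spec, path)
  back <- read_cfa_spec(path)
  expect_equal(back$factors, spec$factors)
  expect_equal(back$residual_pairs, list(c("a", "d")))
  expect_equal(back$k, 2)
})
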