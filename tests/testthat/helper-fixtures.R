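# Shared fixtures, built in code at test time.

# small default cohort + panel, reused across files
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(seed = 101)
      coh <- generate_cohort(cfg)
      panel <- generate_ct_panel(coh, cfg)
      cache <<- list(cfg = cfg, cohort = coh, panel = panel,
                     qc = qc_normalize_panel(panel))
    }
    cache
  }
})

# orthonormalize: return a vector with exact zero sample correlation to
# each column of X and exact unit SD (for constructing data with exact
# standardized regression slopes)
ortho_unit <- function(z, X) {
  r <- stats::residuals(stats::lm(z ~ X))
  as.numeric(scale(r))
}

# construct (x, m, y) whose standardized OLS paths are exactly (a, b, cp)
exact_path_data <- function(a, b, cp, n = 60, seed = 1) {
  withr::with_seed(seed, {
    x <- as.numeric(scale(stats::rnorm(n)))
    em <- ortho_unit(stats::rnorm(n), x)
    m <- a * x + sqrt(1 - a^2) * em
    ey <- ortho_unit(stats::rnorm(n), cbind(x, m))
    resv <- 1 - cp^2 - b^2 - 2 * a * b * cp
    stopifnot(resv > 0)
    y <- cp * x + b * m + sqrt(resv) * ey
    data.frame(x = x, m = m, y = y)
  })
}

# independent ML discrepancy (written against the definition, not the
# package internals) for the brute-force CFA oracle
ml_discrepancy <- function(lambda, psi, S) {
  p <- length(lambda)
  Sigma <- outer(lambda, lambda) + diag(psi, p)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(1e10)
  log(det(Sigma)) + sum(diag(solve(Sigma) %*% S)) - log(det(S)) - p
}

# derivative-free brute-force minimum of the 1-factor ML discrepancy
brute_force_cfa_chi2 <- function(S, n) {
  p <- nrow(S)
  obj <- function(th) ml_discrepancy(th[1:p], th[(p + 1):(2 * p)], S)
  best <- Inf
  for (s in 1:4) {
    start <- c(rep(0.2 * s, p), diag(S) * (0.3 + 0.2 * s))
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  (n - 1) * best
}
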