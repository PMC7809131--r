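# Covariate-adjusted group comparison per miRNA: ANCOVA-adjusted means,
# Cohen's d / Hedges' g with confidence intervals, the d >= 0.40 screen,
# interpretive effect-size conversions, and sex-stratified bootstrap
# classification.

#' ANCOVA-adjusted group means
#'
#' Fits `delta_ct ~ group + covariate` and returns model-predicted group
#' means at the covariate grand mean, together with the F statistic and
#' p-value for the group term. With zero covariate variance, falls back to
#' unadjusted means with a warning.
#'
#' @param delta_ct response per sample.
#' @param group "control"/"exposed" per sample.
#' @param covariate numeric covariate (cigarettes/day).
#' @return list with `adjusted_mean_control`, `adjusted_mean_exposed`, `F`,
#'   `p`.
#' @export
ancova_adjusted_means <- function(delta_ct, group, covariate) {
  group <- factor(group, levels = c("control", "exposed"))
  stopifnot(min(table(group)) >= 3)
  if (stats::var(covariate) < .Machine$double.eps) {
    warning("zero covariate variance; returning unadjusted means")
    fit <- stats::lm(delta_ct ~ group)
    sm <- summary(fit)$coefficients
    mu <- tapply(delta_ct, group, mean)
    return(list(adjusted_mean_control = unname(mu["control"]),
                adjusted_mean_exposed = unname(mu["exposed"]),
                F = sm["groupexposed", "t value"]^2,
                p = sm["groupexposed", "Pr(>|t|)"]))
  }
  fit <- stats::lm(delta_ct ~ group + covariate)
  grand <- mean(covariate)
  pred <- stats::predict(fit, newdata = data.frame(
    group = factor(c("control", "exposed"),
                   levels = levels(group)),
    covariate = grand))
  sm <- summary(fit)$coefficients
  list(adjusted_mean_control = unname(pred[1]),
       adjusted_mean_exposed = unname(pred[2]),
       F = unname(sm["groupexposed", "t value"]^2),
       p = unname(sm["groupexposed", "Pr(>|t|)"]))
}

#' Cohen's d and Hedges' g from group summaries
#'
#' `d = (mean_control - mean_exposed) / pooled SD` (positive d = lower
#' delta-CT, i.e. upregulated, in the exposed group when means are delta-CT
#' values); `g = J * d` with the small-sample correction
#' `J = 1 - 3 / (4(n_c + n_e - 2) - 1)`. The 95 % CI uses the normal
#' approximation `d +/- 1.96 * SE`,
#' `SE = sqrt((n_c + n_e)/(n_c n_e) + d^2 / (2(n_c + n_e)))`.
#'
#' @param mean_c,mean_e group means (numerator may use ANCOVA-adjusted means).
#' @param sd_c,sd_e group standard deviations (raw within-group).
#' @param n_c,n_e group sizes.
#' @return list with `d`, `g`, `ci_low`, `ci_high`, `se`, `pooled_sd`.
#' @export
cohens_d <- function(mean_c, mean_e, sd_c, sd_e, n_c, n_e) {
  stopifnot(n_c >= 2, n_e >= 2, sd_c > 0, sd_e > 0)
  pooled <- sqrt(((n_c - 1) * sd_c^2 + (n_e - 1) * sd_e^2) /
                   (n_c + n_e - 2))
  d <- (mean_c - mean_e) / pooled
  j <- 1 - 3 / (4 * (n_c + n_e - 2) - 1)
  se <- sqrt((n_c + n_e) / (n_c * n_e) + d^2 / (2 * (n_c + n_e)))
  list(d = d, g = j * d,
       ci_low = d - stats::qnorm(0.975) * se,
       ci_high = d + stats::qnorm(0.975) * se,
       se = se, pooled_sd = pooled)
}

#' Per-miRNA effect-size table
#'
#' Runs the ANCOVA-adjusted comparison for every miRNA of a normalized
#' matrix: adjusted means enter the numerator of d, the pooled raw
#' within-group SD its denominator.
#'
#' @param delta_ct matrix (miRNA x sample).
#' @param group,covariate per-sample labels/covariate.
#' @return data.frame, one row per miRNA (`EffectRecord` fields).
#' @export
effect_table <- function(delta_ct, group, covariate) {
  group <- factor(group, levels = c("control", "exposed"))
  out <- lapply(rownames(delta_ct), function(m) {
    y <- delta_ct[m, ]
    adj <- ancova_adjusted_means(y, group, covariate)
    es <- cohens_d(adj$adjusted_mean_control, adj$adjusted_mean_exposed,
                   stats::sd(y[group == "control"]),
                   stats::sd(y[group == "exposed"]),
                   sum(group == "control"), sum(group == "exposed"))
    data.frame(mimat_id = m,
               adjusted_mean_control = adj$adjusted_mean_control,
               adjusted_mean_exposed = adj$adjusted_mean_exposed,
               pooled_sd = es$pooled_sd, d = es$d, g = es$g,
               ci_low = es$ci_low, ci_high = es$ci_high,
               F = adj$F, p = adj$p,
               direction = ifelse(es$d >= 0, "up_in_PAE", "down_in_PAE"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen miRNAs by effect size
#'
#' Keeps records with `|d| >= cutoff`; flags the "significant" subset whose
#' 95 % CI excludes zero, and reports the fraction upregulated in the
#' exposed group.
#'
#' @param records data.frame from [effect_table()].
#' @param cutoff absolute-d cutoff (default 0.40).
#' @return list with `screened` (data.frame incl. `significant` flag),
#'   `n_screened`, `frac_up_in_pae`.
#' @export
screen_by_effect <- function(records, cutoff = 0.40) {
  keep <- records[abs(records$d) >= cutoff, , drop = FALSE]
  keep$significant <- keep$ci_low > 0 | keep$ci_high < 0
  list(screened = keep, n_screened = nrow(keep),
       frac_up_in_pae = if (nrow(keep)) mean(keep$d > 0) else NA_real_)
}

#' Interpretive effect-size conversions
#'
#' Translates a standardized mean difference into Cohen's U3 (proportion of
#' the exposed group above the control mean), the equivalent logistic odds
#' ratio `exp(d * pi / sqrt(3))`, and the binomial effect size display rate
#' difference `d / sqrt(d^2 + 4)`.
#'
#' @param d standardized mean difference.
#' @return list with `U3` (proportion), `OR`, `BESD` (rate difference).
#' @export
effect_interpretations <- function(d) {
  list(U3 = stats::pnorm(d),
       OR = exp(d * pi / sqrt(3)),
       BESD = d / sqrt(d^2 + 4))
}

# fast ANCOVA p-value for the group term (least-squares via QR)
ancova_group_p <- function(y, g01, covariate) {
  X <- cbind(1, g01, covariate)
  fit <- stats::lm.fit(X, y)
  rdf <- length(y) - fit$rank
  if (rdf <= 0 || fit$rank < 3) return(NA_real_)
  s2 <- sum(fit$residuals^2) / rdf
  XtX_inv <- chol2inv(fit$qr$qr[1:3, 1:3, drop = FALSE])
  se <- sqrt(s2 * XtX_inv[2, 2])
  2 * stats::pt(-abs(fit$coefficients[2] / se), rdf)
}

#' Sex-stratified bootstrap classification
#'
#' For each miRNA, resamples subjects with replacement (within exposure
#' group, preserving the design) for the combined sample and for each sex
#' separately, runs the smoking-adjusted ANCOVA on every resample, and
#' records the fraction of iterations with p < 0.05. A miRNA is classified
#' sex-specific iff that sex's proportion exceeds 0.5 and exceeds the
#' combined proportion.
#'
#' @param delta_ct matrix (miRNA x sample).
#' @param group,sex,covariate per-sample labels/covariate.
#' @param n_iter bootstrap iterations (reference analysis: 2000).
#' @param seed RNG seed.
#' @return data.frame with per-miRNA proportions and `classification`.
#' @export
sex_stratified_bootstrap <- function(delta_ct, group, sex, covariate,
                                     n_iter = 2000, seed = 1L) {
  g01 <- as.integer(group == "exposed")
  strata <- list(combined = seq_along(group),
                 male = which(sex == "M"),
                 female = which(sex == "F"))
  small <- vapply(strata[-1], function(idx) {
    min(table(factor(group[idx], levels = c("control", "exposed")))) < 4
  }, logical(1))
  props <- withr::with_seed(substream_seed(seed, 5), {
    lapply(strata, function(idx) {
      ctrl <- idx[g01[idx] == 0]
      expo <- idx[g01[idx] == 1]
      draws <- replicate(n_iter, c(sample(ctrl, replace = TRUE),
                                   sample(expo, replace = TRUE)),
                         simplify = FALSE)
      sig <- matrix(FALSE, nrow(delta_ct), n_iter)
      for (b in seq_len(n_iter)) {
        s <- draws[[b]]
        for (m in seq_len(nrow(delta_ct))) {
          p <- ancova_group_p(delta_ct[m, s], g01[s], covariate[s])
          sig[m, b] <- isTRUE(p < 0.05)
        }
      }
      rowMeans(sig)
    })
  })
  cls <- classify_sex_specific(props$combined, props$male, props$female)
  if (any(small)) cls[] <- "indeterminate"
  data.frame(mimat_id = rownames(delta_ct) %||% seq_len(nrow(delta_ct)),
             prop_sig_combined = props$combined,
             prop_sig_male = props$male,
             prop_sig_female = props$female,
             classification = cls,
             stringsAsFactors = FALSE)
}

#' Classify sex specificity from bootstrap proportions
#'
#' Rule: a sex is "specific" iff its proportion of significant iterations
#' exceeds 0.5 and exceeds the combined-sample proportion.
#'
#' @param combined,male,female proportions in `[0, 1]` (vectorized).
#' @return character vector: "none", "male_specific", "female_specific" or
#'   "both".
#' @export
classify_sex_specific <- function(combined, male, female) {
  m_spec <- male > 0.5 & male > combined
  f_spec <- female > 0.5 & female > combined
  ifelse(m_spec & f_spec, "both",
         ifelse(m_spec, "male_specific",
                ifelse(f_spec, "female_specific", "none")))
}
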