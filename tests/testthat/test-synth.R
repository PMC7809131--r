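# Synthetic cohort and CT-panel generator.

test_that("cohort has the configured design and is seed-reproducible", {
  fx <- fixture_cohort()
  subj <- fx$cohort$subjects
  expect_equal(sum(subj$timepoint == "T2wk"), 68)
  expect_equal(sum(subj$timepoint == "T6.5mo"), 68)
  expect_equal(sum(subj$group == "exposed" & subj$timepoint == "T2wk"), 37)
  expect_equal(sum(subj$group == "control" & subj$timepoint == "T2wk"), 31)
  # controls near zero alcohol, exposed strictly positive
  expect_true(all(subj$aa_per_day[subj$group == "exposed"] > 0.09))
  expect_true(all(subj$aa_per_day[subj$group == "control"] < 0.05))

  again <- generate_cohort(fx$cfg)
  expect_identical(fx$cohort, again)
  panel2 <- generate_ct_panel(again, fx$cfg)
  expect_identical(fx$panel$ct, panel2$ct)
})

test_that("invalid configurations are rejected", {
  bad_phi <- matrix(1, 3, 3)  # singular
  expect_error(cohort_config(factor_covariances = bad_phi),
               "positive definite")
  expect_error(cohort_config(n_control = 1), "n_control")
  expect_error(cohort_config(nondetect_rate = 1.5))
})

test_that("null configuration produces no spurious group differences", {
  p_out <- replicate(100, NULL, simplify = FALSE)
  k <- 0
  for (s in 1:100) {
    cfg <- cohort_config(
      n_responsive = 2, exposure_effect_d = c(0, 0),
      factor_loadings = c(0.5, 0.5), factor_assignment = c(1, 2),
      outcome_path_coefficients = list(a = 0, b = 0, c_prime = 0),
      seed = 1000 + s)
    subj <- generate_cohort(cfg)$subjects
    subj <- subj[subj$timepoint == "T2wk", ]
    ps <- vapply(c("weight_z", "length_z", "hc_z", "ftii_novelty"),
                 function(v) {
                   stats::t.test(subj[[v]] ~ subj$group)$p.value
                 }, numeric(1))
    if (all(ps > 0.001)) k <- k + 1
  }
  expect_gte(k / 100, 0.99)
})

test_that("OLS recovers the structural paths on average", {
  a_hat <- b_hat <- numeric(400)
  for (s in seq_along(a_hat)) {
    cfg <- cohort_config(
      n_control = 29, n_exposed = 29,
      outcome_path_coefficients = list(a = 0.4, b = 0.4, c_prime = 0.4),
      seed = 2000 + s)
    coh <- generate_cohort(cfg)
    d <- coh$subjects[coh$subjects$timepoint == "T2wk", ]
    d$f1 <- coh$truth$factor_scores$T2wk[, 1]
    d[] <- lapply(d, function(x) if (is.numeric(x)) as.numeric(scale(x))
                  else x)
    a_hat[s] <- stats::coef(stats::lm(f1 ~ aa_per_day, d))[2]
    b_hat[s] <- stats::coef(stats::lm(weight_z ~ aa_per_day + f1, d))[3]
  }
  expect_lt(abs(mean(a_hat) - 0.4), 0.02)
  expect_lt(abs(mean(b_hat) - 0.4), 0.02)
})

test_that("CT panel geometry and non-detect encoding are as configured", {
  fx <- fixture_cohort()
  expect_equal(nrow(fx$panel$ct), 752)
  expect_equal(ncol(fx$panel$ct), 136)
  # ct present iff detected
  expect_identical(is.na(fx$panel$ct), !fx$panel$detected)

  cfg0 <- cohort_config(nondetect_rate = 0, seed = 7)
  coh0 <- generate_cohort(cfg0)
  p0 <- generate_ct_panel(coh0, cfg0, ceiling_ct = Inf)
  expect_false(anyNA(p0$ct[1:148, ]))
  # non-expressed assays detect sporadically (per-assay probability
  # under 0.2; realized per-group rates stay well below the filter bar)
  det_ne <- p0$detected[149:752, ]
  grp <- p0$samples$group
  expect_lt(mean(det_ne[, grp == "control"]), 0.1)
  expect_lt(mean(det_ne[, grp == "exposed"]), 0.1)
  expect_lt(max(rowMeans(det_ne)), 0.3)
  # and the expressed filter removes every one of them
  kept <- filter_expressed(p0$detected, p0$samples$group,
                           p0$samples$timepoint)
  expect_true(all(match(kept, rownames(p0$ct)) <= 148))
})

test_that("single-miRNA effect calibration hits the configured d", {
  d_emp <- numeric(150)
  for (s in seq_along(d_emp)) {
    cfg <- cohort_config(n_responsive = 1, exposure_effect_d = 0.68,
                         factor_loadings = 0.5, factor_assignment = 1,
                         nondetect_rate = 0, seed = 3000 + s)
    coh <- generate_cohort(cfg)
    panel <- generate_ct_panel(coh, cfg, ceiling_ct = Inf)
    qc <- qc_normalize_panel(panel)
    tp1 <- qc$samples$timepoint == "T2wk"
    y <- qc$delta_ct[coh$truth$responsive_ids, tp1]
    g <- qc$samples$group[tp1]
    nc <- sum(g == "control"); ne <- sum(g == "exposed")
    ps <- sqrt(((nc - 1) * stats::var(y[g == "control"]) +
                  (ne - 1) * stats::var(y[g == "exposed"])) / (nc + ne - 2))
    d_emp[s] <- (mean(y[g == "control"]) - mean(y[g == "exposed"])) / ps
  }
  expect_lt(abs(mean(d_emp) - 0.68), 0.05)
})

test_that("effect calibration converges for the full panel at large n", {
  cfg <- cohort_config(n_control = 2000, n_exposed = 2000,
                       nondetect_rate = 0, seed = 11)
  coh <- generate_cohort(cfg)
  panel <- generate_ct_panel(coh, cfg, ceiling_ct = Inf)
  qc <- qc_normalize_panel(panel)
  tp1 <- qc$samples$timepoint == "T2wk"
  g <- qc$samples$group[tp1]
  dct <- qc$delta_ct[coh$truth$responsive_ids, tp1]
  nc <- sum(g == "control"); ne <- sum(g == "exposed")
  d_emp <- apply(dct, 1, function(y) {
    ps <- sqrt(((nc - 1) * stats::var(y[g == "control"]) +
                  (ne - 1) * stats::var(y[g == "exposed"])) / (nc + ne - 2))
    (mean(y[g == "control"]) - mean(y[g == "exposed"])) / ps
  })
  dev <- d_emp - coh$truth$exposure_effect_d
  expect_lt(abs(mean(dev)), 0.03)
  expect_lt(max(abs(dev)), 0.12)
})

test_that("hemolysis metrics flag exactly the configured fraction", {
  fx <- fixture_cohort()
  h0 <- generate_hemolysis_metrics(fx$cohort$subjects, 0, seed = 5)
  q0 <- assess_hemolysis(h0$a414, h0$ct_mir23a, h0$ct_mir451a)
  expect_equal(sum(q0$status == "fail"), 0)

  subj124 <- fx$cohort$subjects[1:124, ]
  h3 <- generate_hemolysis_metrics(subj124, 3 / 124, seed = 5)
  q3 <- assess_hemolysis(h3$a414, h3$ct_mir23a, h3$ct_mir451a)
  expect_equal(sum(q3$status == "fail"), 3)
  flagged <- q3$status == "fail"
  expect_true(all(h3$ct_mir23a[flagged] - h3$ct_mir451a[flagged] > 7))
  expect_true(all(h3$a414[flagged] > 0.3))
})

test_that("cohort artifacts round-trip through the written files", {
  fx <- fixture_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort_artifacts(fx$cohort, fx$panel, fx$cfg, dir)
  expect_true(all(file.exists(paths)))
  ct_in <- utils::read.delim(paths["ct"], check.names = FALSE)
  expect_equal(nrow(ct_in), 752)
  expect_equal(ct_in$mimat_id, rownames(fx$panel$ct))
  loci <- load_loci_gff3(paths["gff3"])
  expect_setequal(unique(loci$mimat_id), fx$cohort$truth$expressed_ids)
})
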