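# Synthetic cohort / CT-panel generator.
#
# Emulates the statistical structure the downstream analyses assume: two
# exposure groups measured at two ages on a 752-assay qPCR panel of which
# ~148 miRNAs are reliably expressed, a latent 3-factor structure driving a
# responsive subset, alcohol-exposure effects of moderate standardized size,
# smoking as a correlated covariate, and growth/cognition outcomes linked to
# the latent factors. Ground truth is exported for recovery tests.

#' Configuration for a synthetic cohort
#'
#' Defaults reproduce the reference study design: 31 control and 37 exposed
#' infants, two timepoints, 752 assays with 148 expressed miRNAs of which 18
#' respond to exposure with standardized effects spanning 0.40-0.88 (most
#' upregulated in the exposed group), a 3-factor latent structure with
#' loadings 0.50 and factor correlations 0.50, and structural paths
#' exposure -> factor (a), factor -> outcome (b), exposure -> outcome (c').
#'
#' @param n_control,n_exposed group sizes (infants per group).
#' @param n_mirnas_total assays on the panel.
#' @param n_expressed miRNAs with reliable expression.
#' @param n_responsive exposure-responsive miRNAs (first `n_responsive` of the
#'   expressed set).
#' @param factor_loadings latent-factor loading per responsive miRNA, on the
#'   CT scale (positive = higher factor score lowers CT, i.e. upregulation).
#' @param factor_assignment integer factor index per responsive miRNA.
#' @param factor_covariances symmetric positive-definite correlation matrix of
#'   the latent factors.
#' @param exposure_effect_d target Cohen's d per responsive miRNA on the
#'   normalized (delta-CT) scale; positive = upregulated in the exposed group.
#' @param smoking_exposure_corr increment in smoking prevalence for exposed
#'   mothers, in `[0, 0.5]`; makes covariate adjustment non-trivial.
#' @param nondetect_rate random-dropout probability per expressed assay, in
#'   addition to detection-limit censoring at the assay ceiling.
#' @param outcome_path_coefficients list with elements `a`, `b`, `c_prime`:
#'   standardized structural paths used to generate outcomes.
#' @param seed master seed; each generation block derives its own stream.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_control = 31L,
                          n_exposed = 37L,
                          n_mirnas_total = 752L,
                          n_expressed = 148L,
                          n_responsive = 18L,
                          factor_loadings = rep(0.5, n_responsive),
                          factor_assignment = rep(1:3, c(
                            n_responsive - 2 * (n_responsive %/% 3.6),
                            n_responsive %/% 3.6, n_responsive %/% 3.6)),
                          factor_covariances = matrix(0.5, 3, 3) + diag(0.5, 3),
                          exposure_effect_d = round(seq(0.40, 0.88,
                            length.out = n_responsive), 2) *
                            rep(c(1, -1), c(ceiling(0.8 * n_responsive),
                                            floor(0.2 * n_responsive))),
                          smoking_exposure_corr = 0.2,
                          nondetect_rate = 0.02,
                          outcome_path_coefficients = list(
                            a = 0.4, b = 0.4, c_prime = 0.4),
                          seed = 1L) {
  stopifnot(n_control >= 2, n_exposed >= 2,
            n_expressed <= n_mirnas_total,
            n_responsive <= n_expressed,
            length(factor_loadings) == n_responsive,
            length(factor_assignment) == n_responsive,
            length(exposure_effect_d) == n_responsive,
            smoking_exposure_corr >= -1, smoking_exposure_corr <= 1,
            nondetect_rate >= 0, nondetect_rate <= 1)
  k <- nrow(factor_covariances)
  stopifnot(ncol(factor_covariances) == k,
            max(factor_assignment) <= k,
            isTRUE(all.equal(factor_covariances, t(factor_covariances))))
  if (min(eigen(factor_covariances, symmetric = TRUE,
                only.values = TRUE)$values) <= 1e-10) {
    stop("factor covariance matrix must be positive definite")
  }
  structure(list(
    n_control = as.integer(n_control), n_exposed = as.integer(n_exposed),
    n_mirnas_total = as.integer(n_mirnas_total),
    n_expressed = as.integer(n_expressed),
    n_responsive = as.integer(n_responsive),
    factor_loadings = factor_loadings,
    factor_assignment = as.integer(factor_assignment),
    factor_covariances = factor_covariances,
    exposure_effect_d = exposure_effect_d,
    smoking_exposure_corr = smoking_exposure_corr,
    nondetect_rate = nondetect_rate,
    outcome_path_coefficients = outcome_path_coefficients,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws subjects for both timepoints under a linear structural model:
#' latent factors `F_j = a * X + eta_j` (X = standardized alcohol dose,
#' `eta ~ MVN(0, (1 - a^2) * Phi)` so factors are marginally standardized) and
#' outcomes `Y = c' * X + b * F_1 + e`, scaled into WHO-z / percent units.
#' Smoking is zero-inflated Poisson with higher prevalence among exposed
#' mothers. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `subjects` (one row per infant x timepoint) and `truth`
#'   (latent factor scores, true loadings and paths, responsive miRNA ids).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_control + config$n_exposed
  paths <- config$outcome_path_coefficients
  a <- paths$a; b <- paths$b; cp <- paths$c_prime
  k <- nrow(config$factor_covariances)

  subj <- withr::with_seed(substream_seed(config$seed, 1), {
    group <- rep(c("control", "exposed"),
                 c(config$n_control, config$n_exposed))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    aa <- ifelse(group == "exposed",
                 0.1 + stats::rgamma(n, shape = 1.8, rate = 3),
                 abs(stats::rnorm(n, 0, 0.002)))
    p_smoke <- ifelse(group == "exposed",
                      min(1, 0.5 + config$smoking_exposure_corr), 0.5)
    cigs <- stats::rbinom(n, 1, p_smoke) *
      stats::rpois(n, ifelse(group == "exposed", 7.1, 6.6))
    x <- as.numeric(scale(aa))

    # latent factors per timepoint: marginally standardized, correlated Phi
    eta_var <- max(1 - a^2, 1e-6)
    fac <- lapply(1:2, function(tp) {
      eta <- MASS::mvrnorm(n, mu = rep(0, k),
                           Sigma = eta_var * config$factor_covariances)
      a * x + eta
    })

    # outcomes share the timepoint-1 first factor as operative mediator
    res_var <- 1 - cp^2 - b^2 - 2 * a * b * cp
    if (res_var <= 0) stop("outcome path coefficients imply variance > 1")
    draw_y <- function() cp * x + b * fac[[1]][, 1] +
      stats::rnorm(n, 0, sqrt(res_var))
    list(group = group, sex = sex, aa = aa, cigs = cigs, x = x, fac = fac,
         weight_z = -0.2 + 0.9 * draw_y(),
         length_z = -0.7 + 1.0 * draw_y(),
         hc_z = -0.5 + 0.8 * draw_y(),
         ftii = pmin(100, pmax(0, 61 + 6 * draw_y())))
  })

  ids <- sprintf("S%03d", seq_len(n))
  one_tp <- function(tp) {
    data.frame(subject_id = ids,
               timepoint = c("T2wk", "T6.5mo")[tp],
               group = subj$group, sex = subj$sex,
               aa_per_day = subj$aa, cigarettes_per_day = subj$cigs,
               weight_z = subj$weight_z, length_z = subj$length_z,
               hc_z = subj$hc_z, ftii_novelty = subj$ftii,
               stringsAsFactors = FALSE)
  }
  subjects <- rbind(one_tp(1), one_tp(2))
  subjects$sample_id <- paste(subjects$subject_id, subjects$timepoint,
                              sep = "_")

  mimat <- sprintf("MIMATS%06d", seq_len(config$n_mirnas_total))
  truth <- list(
    factor_scores = stats::setNames(subj$fac, c("T2wk", "T6.5mo")),
    loadings = config$factor_loadings,
    factor_assignment = config$factor_assignment,
    paths = list(a = a, b = b, c_prime = cp),
    responsive_ids = mimat[seq_len(config$n_responsive)],
    expressed_ids = mimat[seq_len(config$n_expressed)],
    exposure_effect_d = config$exposure_effect_d)
  list(subjects = subjects, truth = truth)
}

#' Generate a raw CT panel for a cohort
#'
#' Emulates the 2 x 384-well panel geometry: `n_mirnas_total` assay rows per
#' sample (one sample per infant x timepoint). Expressed miRNAs get baseline
#' CTs uniform in `[18, 34]`; responsive miRNAs additionally carry a latent
#' factor component (`- loading * factor score`) and an exposure shift on the
#' CT scale (negative shift = upregulation). The shift is calibrated against
#' the realized factor scores so that the standardized group difference of
#' the global-mean-normalized values matches `exposure_effect_d`, including
#' the bleed of responsive shifts into the per-sample global mean.
#' Non-detects arise by detection-limit censoring (latent CT above the assay
#' ceiling) or random dropout at `nondetect_rate`, and are encoded as `NA`
#' with `detected = FALSE`. Non-expressed assays detect sporadically
#' (per-assay probability < 0.2).
#'
#' @param cohort result of [generate_cohort()] (or its `subjects` with a
#'   `truth` attribute supplied via `truth`).
#' @param config the [cohort_config()] used to generate the cohort.
#' @param truth ground truth; defaults to `cohort$truth`.
#' @param ceiling_ct assay detection ceiling (CT cycles).
#' @param panel1_fail_fraction fraction of timepoint-1 samples whose first
#'   half-panel fails amplification QC (those assays become structurally
#'   missing, `panel_ok = FALSE`).
#' @return a `ct_panel` list: `ct` (miRNA x sample, NA = non-detect),
#'   `detected`, `panel_ok` (sample x half), `panel_half` per assay, plus the
#'   sample metadata.
#' @export
generate_ct_panel <- function(cohort, config, truth = cohort$truth,
                              ceiling_ct = 37, panel1_fail_fraction = 0) {
  subjects <- if (is.data.frame(cohort)) cohort else cohort$subjects
  stopifnot(nrow(subjects) > 0, inherits(config, "cohort_config"))
  ns <- nrow(subjects)
  p_tot <- config$n_mirnas_total
  p_exp <- config$n_expressed
  p_res <- config$n_responsive
  mimat <- sprintf("MIMATS%06d", seq_len(p_tot))
  sigma_e <- 1

  withr::with_seed(substream_seed(config$seed, 2), {
    baseline <- stats::runif(p_exp, 18, 34)

    # systematic latent component per expressed miRNA x sample
    tp_idx <- match(subjects$timepoint, c("T2wk", "T6.5mo"))
    subj_idx <- match(subjects$subject_id,
                      unique(subjects$subject_id))
    fscore <- matrix(0, ns, nrow(config$factor_covariances))
    for (i in seq_len(ns)) {
      fscore[i, ] <- truth$factor_scores[[tp_idx[i]]][subj_idx[i], ]
    }
    sys <- matrix(0, p_exp, ns)
    for (j in seq_len(p_res)) {
      sys[j, ] <- -config$factor_loadings[j] *
        fscore[, config$factor_assignment[j]]
    }
    bleed <- colMeans(sys)                      # enters each delta-CT
    sysn <- sweep(sys, 2, bleed)                # post-normalization systematic

    # calibrate exposure shifts so the normalized standardized group
    # difference equals the configured d (s_bar couples via the global mean)
    exposed <- subjects$group == "exposed"
    gdiff <- apply(sysn, 1, function(z) mean(z[!exposed]) - mean(z[exposed]))
    vwith <- apply(sysn, 1, function(z) {
      ((sum(!exposed) - 1) * stats::var(z[!exposed]) +
         (sum(exposed) - 1) * stats::var(z[exposed])) / (ns - 2)
    })
    sd_m <- sqrt(vwith[seq_len(p_res)] + sigma_e^2 * (1 - 1 / p_exp))
    c_m <- config$exposure_effect_d * sd_m - gdiff[seq_len(p_res)]
    s_bar <- sum(c_m) / (p_exp - p_res)
    shift <- c(c_m + s_bar, rep(0, p_exp - p_res))

    ct_exp <- baseline + sys -
      outer(shift, as.numeric(exposed)) +
      matrix(stats::rnorm(p_exp * ns, 0, sigma_e), p_exp, ns)

    detected <- matrix(TRUE, p_tot, ns,
                       dimnames = list(mimat, subjects$sample_id))
    ct <- matrix(NA_real_, p_tot, ns,
                 dimnames = list(mimat, subjects$sample_id))
    nd <- ct_exp > ceiling_ct |
      matrix(stats::runif(p_exp * ns) < config$nondetect_rate, p_exp, ns)
    ct_exp[nd] <- NA_real_
    ct[seq_len(p_exp), ] <- ct_exp
    detected[seq_len(p_exp), ] <- !nd

    # non-expressed assays: sporadic detection well below the 20 % bar
    if (p_tot > p_exp) {
      idx <- (p_exp + 1):p_tot
      pdet <- stats::runif(length(idx), 0, 0.15)
      det_ne <- matrix(stats::runif(length(idx) * ns), length(idx), ns) <
        pdet
      ct[idx, ][det_ne] <- stats::runif(sum(det_ne), 33, 36.5)
      detected[idx, ] <- det_ne
    }

    panel_half <- rep(c("I", "II"), c(ceiling(p_tot / 2), floor(p_tot / 2)))
    panel_ok <- matrix(TRUE, ns, 2,
                       dimnames = list(subjects$sample_id, c("I", "II")))
    if (panel1_fail_fraction > 0) {
      t1 <- which(subjects$timepoint == "T2wk")
      n_fail <- round(panel1_fail_fraction * length(t1))
      if (n_fail > 0) {
        fail <- sample(t1, n_fail)
        panel_ok[fail, "I"] <- FALSE
        ct[panel_half == "I", fail] <- NA_real_
        detected[panel_half == "I", fail] <- FALSE
      }
    }

    structure(list(ct = ct, detected = detected, panel_ok = panel_ok,
                   panel_half = panel_half, samples = subjects),
              class = "ct_panel")
  })
}

#' Generate per-sample hemolysis metrics
#'
#' Draws absorbance at 414 nm and CTs of the hemolysis marker pair
#' (miR-23a-3p, miR-451a) such that exactly `round(fraction * n)` samples
#' exceed both erythrocyte-contamination thresholds (a414 > 0.3 and
#' delta-CT(miR-23a - miR-451a) > 7); all other samples stay below at least
#' one threshold.
#'
#' @param subjects subject/sample table (one row per sample).
#' @param contamination_fraction fraction of contaminated samples in `[0,1]`.
#' @param seed RNG seed (default derives from nothing; pass for determinism).
#' @return data.frame with `sample_id`, `a414`, `ct_mir23a`, `ct_mir451a`,
#'   `slc4a1_detected`.
#' @export
generate_hemolysis_metrics <- function(subjects, contamination_fraction,
                                       seed = 1L) {
  stopifnot(contamination_fraction >= 0, contamination_fraction <= 1)
  n <- nrow(subjects)
  n_bad <- round(contamination_fraction * n)
  withr::with_seed(substream_seed(seed, 3), {
    bad <- rep(FALSE, n)
    if (n_bad > 0) bad[sample.int(n, n_bad)] <- TRUE
    a414 <- ifelse(bad, stats::runif(n, 0.35, 0.9),
                   stats::runif(n, 0.05, 0.28))
    dct <- ifelse(bad, stats::runif(n, 7.5, 10), stats::runif(n, 2, 6.8))
    ct451 <- stats::runif(n, 17, 21)
    data.frame(sample_id = subjects$sample_id,
               a414 = a414,
               ct_mir23a = ct451 + dct,
               ct_mir451a = ct451,
               slc4a1_detected = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic genomic coordinates for the expressed miRNAs
#'
#' Assigns each expressed miRNA a chromosome and 1-based coordinates in a
#' miRBase-like layout: some factor-mates are placed in genomic clusters
#' (< 10 kb apart) and a small fraction of miRNAs get a duplicated locus on a
#' second chromosome (mirroring miRBase ".1" duplications).
#'
#' @param truth ground truth from [generate_cohort()].
#' @param config the matching [cohort_config()].
#' @param cluster_spacing bp between clustered loci.
#' @param dup_fraction fraction of expressed miRNAs with a duplicated locus.
#' @return data.frame of loci: `mimat_id`, `name`, `chromosome`, `start`,
#'   `end`, `strand`, `copy_index`.
#' @export
synthetic_mirna_loci <- function(truth, config, cluster_spacing = 5000L,
                                 dup_fraction = 0.08) {
  ids <- truth$expressed_ids
  withr::with_seed(substream_seed(config$seed, 4), {
    chroms <- paste0("chr", c(1:22, "X"))
    chr <- sample(chroms, length(ids), replace = TRUE)
    start <- sample.int(2e8, length(ids))
    # cluster the first three miRNAs of each factor on a shared chromosome
    for (f in sort(unique(config$factor_assignment))) {
      members <- which(config$factor_assignment == f)[1:3]
      members <- members[!is.na(members)]
      host <- chroms[f]
      base <- 1e6 * f
      chr[members] <- host
      start[members] <- base + cluster_spacing * (seq_along(members) - 1)
    }
    loci <- data.frame(mimat_id = ids,
                       name = sub("MIMATS", "syn-miR-", ids),
                       chromosome = chr,
                       start = start,
                       end = start + 21L,
                       strand = sample(c("+", "-"), length(ids),
                                       replace = TRUE),
                       copy_index = 0L,
                       stringsAsFactors = FALSE)
    n_dup <- round(dup_fraction * length(ids))
    if (n_dup > 0) {
      di <- sample(seq_along(ids), n_dup)
      dup <- loci[di, ]
      dup$chromosome <- vapply(dup$chromosome, function(ch) {
        sample(setdiff(chroms, ch), 1)
      }, character(1))
      dup$start <- sample.int(2e8, n_dup)
      dup$end <- dup$start + 21L
      dup$copy_index <- 1L
      loci <- rbind(loci, dup)
    }
    loci[order(loci$mimat_id, loci$copy_index), ]
  })
}

#' Write miRNA loci as miRBase-dialect GFF3
#'
#' @param loci data.frame as returned by [synthetic_mirna_loci()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsynthetic\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s%s;Alias=%s;Name=%s",
                     loci$chromosome, loci$start, loci$end, loci$strand,
                     loci$mimat_id,
                     ifelse(loci$copy_index > 0,
                            paste0("_", loci$copy_index), ""),
                     loci$mimat_id, loci$name))
  writeLines(lines, path)
  invisible(path)
}

#' Write synthetic cohort artifacts to disk
#'
#' Emits the CT matrix as TSV (rows = MIMAT ids, columns = sample ids),
#' sample metadata as CSV, ground truth as JSON and the synthetic loci as
#' GFF3.
#'
#' @param cohort,panel,config outputs of the generator functions.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort_artifacts <- function(cohort, panel, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ct = file.path(dir, "ct_matrix.tsv"),
             meta = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "ground_truth.json"),
             gff3 = file.path(dir, "mirna_loci.gff3"))
  ct_out <- data.frame(mimat_id = rownames(panel$ct), panel$ct,
                       check.names = FALSE)
  utils::write.table(ct_out, paths["ct"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$subjects, paths["meta"], row.names = FALSE)
  truth <- cohort$truth
  truth$factor_scores <- lapply(truth$factor_scores, unname)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  write_mirna_gff3(synthetic_mirna_loci(cohort$truth, config), paths["gff3"])
  invisible(paths)
}
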