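# End-to-end orchestration: simulate -> qc -> effects -> corrnet -> cfa ->
# mediation, every stage writing file artifacts listed in a hashed manifest
# so runs are independently reproducible and comparable.

#' Default pipeline configuration
#'
#' Thresholds and bootstrap settings default to the reference analysis:
#' detection 0.80, effect cutoff 0.40, hemolysis 0.3 / 7, correlation alpha
#' 0.05, 2000 sex-bootstrap iterations, 99 % correlation CI.
#'
#' @param output_dir directory for artifacts.
#' @param seed master seed.
#' @param n_sex_boot,n_corr_boot,n_mediation_boot bootstrap sizes.
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param gff3_path optional external miRNA annotation; defaults to the
#'   GFF3 the simulate stage writes into `output_dir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            n_sex_boot = 2000, n_corr_boot = 1000,
                            n_mediation_boot = 10000,
                            cohort = cohort_config(seed = seed),
                            gff3_path = NULL) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 gff3_path = gff3_path,
                 detection_threshold = 0.80, effect_cutoff = 0.40,
                 hemolysis_a414 = 0.3, hemolysis_dct = 7,
                 correlation_alpha = 0.05, corr_ci_level = 0.99,
                 n_sex_boot = n_sex_boot, n_corr_boot = n_corr_boot,
                 n_mediation_boot = n_mediation_boot,
                 cohort = cohort), class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages run in order simulate -> qc -> effects -> corrnet -> cfa ->
#' mediation; every output file is recorded in a manifest JSON with md5
#' content hashes, so a rerun with the same seeds yields identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (the simulate and qc stages are
#'   always needed by later ones and run implicitly).
#' @return the manifest (named list of files and hashes), invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("effects", "corrnet", "cfa",
                                    "mediation")) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  note <- function(paths) artifacts <<- c(artifacts, unname(paths))

  cohort <- generate_cohort(config$cohort)
  panel <- generate_ct_panel(cohort, config$cohort)
  hemo <- generate_hemolysis_metrics(cohort$subjects, 0,
                                     seed = config$seed)
  note(write_cohort_artifacts(cohort, panel, config$cohort,
                              config$output_dir))

  qc <- qc_normalize_panel(panel, hemo,
                           threshold = config$detection_threshold)
  qc_path <- file.path(config$output_dir, "qc_report.json")
  jsonlite::write_json(qc$qc_report, qc_path, auto_unbox = TRUE,
                       digits = NA)
  expr_path <- file.path(config$output_dir, "delta_ct.tsv")
  utils::write.table(data.frame(mimat_id = rownames(qc$delta_ct),
                                qc$delta_ct, check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(c(qc_path, expr_path))

  tp1 <- qc$samples$timepoint == "T2wk"
  dct1 <- qc$delta_ct[, tp1, drop = FALSE]
  s1 <- qc$samples[tp1, ]

  if ("effects" %in% stages) {
    eff <- effect_table(dct1, s1$group, s1$cigarettes_per_day)
    scr <- screen_by_effect(eff, config$effect_cutoff)
    p <- file.path(config$output_dir, "effects_t2wk.tsv")
    utils::write.table(eff, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p2 <- file.path(config$output_dir, "screened_t2wk.tsv")
    utils::write.table(scr$screened, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(c(p, p2))
  }

  if ("corrnet" %in% stages) {
    gff <- config$gff3_path %||%
      file.path(config$output_dir, "mirna_loci.gff3")
    if (!file.exists(gff)) {
      stop("corrnet stage requires the GFF3 annotation: ", gff)
    }
    loci <- load_loci_gff3(gff)
    cs_c <- masked_correlations(dct1, s1$group, "control",
                                alpha = config$correlation_alpha)
    cs_e <- masked_correlations(dct1, s1$group, "exposed",
                                alpha = config$correlation_alpha)
    enr <- cross_chromosome_enrichment(cs_c, cs_e, loci)
    p <- file.path(config$output_dir, "cross_chromosome_t2wk.tsv")
    utils::write.table(enr, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p2 <- file.path(config$output_dir, "correlation_counts_t2wk.json")
    jsonlite::write_json(list(control = cs_c$n_significant,
                              exposed = cs_e$n_significant,
                              n_pairs = cs_c$n_pairs),
                         p2, auto_unbox = TRUE, digits = NA)
    note(c(p, p2))
  }

  spec3 <- responsive_cfa_spec(cohort$truth)
  if ("cfa" %in% stages) {
    fit <- fit_ml(spec3, t(dct1[spec3$items, , drop = FALSE]))
    bc <- bartlett_corrected_fit(fit)
    p <- file.path(config$output_dir, "cfa_t2wk.json")
    jsonlite::write_json(list(
      chi2 = fit$chi2, df = fit$df, p = fit$p_value,
      chi2_corrected = bc$chi2_corrected, p_corrected = bc$p_corrected,
      CFI = fit$CFI, TLI = fit$TLI, RMSEA = fit$RMSEA, SRMR = fit$SRMR,
      AIC = fit$AIC, BIC = fit$BIC, SABIC = fit$SABIC,
      converged = fit$converged),
      p, auto_unbox = TRUE, digits = NA)
    note(p)
  }

  if ("mediation" %in% stages) {
    scores <- factor_mean_scores(dct1, spec3)
    d <- cbind(s1, as.data.frame(scores))
    battery <- run_mediation_battery(
      d, factor_cols = colnames(scores),
      outcome_cols = c("weight_z", "length_z", "hc_z", "ftii_novelty"))
    p <- file.path(config$output_dir, "mediation_t2wk.tsv")
    utils::write.table(battery, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(p)
  }

  manifest <- list(seed = config$seed,
                   files = lapply(artifacts, function(f) {
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))
                   }))
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# 3-factor spec over the responsive miRNAs, using the generator's ground
# truth assignment
responsive_cfa_spec <- function(truth) {
  ids <- truth$responsive_ids
  fac <- split(ids, paste0("F", truth$factor_assignment))
  cfa_spec(fac)
}
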