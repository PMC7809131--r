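# QC and normalization of raw CT panels: hemolysis exclusion, non-detect
# imputation, expressed-miRNA filtering, global-mean delta-CT and group
# delta-delta-CT.

#' Hemolysis quality control
#'
#' A sample fails iff absorbance at 414 nm exceeds 0.3 AND the
#' delta-CT(miR-23a-3p minus miR-451a) exceeds 7 (both inequalities strict;
#' boundary values pass). Detection of the erythrocyte transcript SLC4A1 is
#' reported as a warning flag, never an exclusion. Missing marker CTs give an
#' indeterminate status: the sample is retained with a warning.
#'
#' @param a414 absorbance at 414 nm, per sample.
#' @param ct_mir23a,ct_mir451a marker CTs, per sample.
#' @param slc4a1_detected optional logical per sample.
#' @param a414_threshold,dct_threshold exclusion thresholds.
#' @return data.frame with `status` ("pass"/"fail"/"indeterminate"),
#'   `dct_markers`, and `slc4a1_flag`.
#' @export
assess_hemolysis <- function(a414, ct_mir23a, ct_mir451a,
                             slc4a1_detected = FALSE,
                             a414_threshold = 0.3, dct_threshold = 7) {
  n <- length(a414)
  slc4a1_detected <- rep_len(slc4a1_detected, n)
  dct <- ct_mir23a - ct_mir451a
  status <- ifelse(a414 > a414_threshold & dct > dct_threshold,
                   "fail", "pass")
  ind <- is.na(dct) | is.na(a414)
  if (any(ind)) {
    warning(sum(ind), " sample(s) with missing hemolysis markers retained ",
            "with indeterminate status")
    status[ind] <- "indeterminate"
  }
  if (any(slc4a1_detected, na.rm = TRUE)) {
    warning("SLC4A1 detected in ", sum(slc4a1_detected, na.rm = TRUE),
            " sample(s); flagged but not excluded")
  }
  data.frame(status = status, dct_markers = dct,
             slc4a1_flag = slc4a1_detected %in% TRUE)
}

#' Impute non-detected CT values
#'
#' Each missing entry of a miRNA is assigned one cycle more than the highest
#' CT at which that miRNA was detected (per miRNA, across all samples of the
#' matrix; both groups pooled). Detected values are unchanged; the operation
#' is idempotent.
#'
#' @param ct_matrix numeric matrix (miRNA x sample), `NA` = non-detect.
#' @param mirnas rows to impute (default all rows with any missing value).
#' @return list with `ct` (completed matrix) and `imputed` (logical matrix).
#' @export
impute_nondetects <- function(ct_matrix, mirnas = rownames(ct_matrix)) {
  if (is.null(mirnas)) mirnas <- seq_len(nrow(ct_matrix))
  imputed <- matrix(FALSE, nrow(ct_matrix), ncol(ct_matrix),
                    dimnames = dimnames(ct_matrix))
  for (m in mirnas) {
    row <- ct_matrix[m, ]
    nd <- is.na(row)
    if (!any(nd)) next
    if (all(nd)) {
      stop("cannot impute miRNA with zero detections: ", m)
    }
    ct_matrix[m, nd] <- max(row, na.rm = TRUE) + 1
    imputed[m, nd] <- TRUE
  }
  list(ct = ct_matrix, imputed = imputed)
}

#' Filter to expressed miRNAs
#'
#' Keeps a miRNA iff its detection rate is at least `threshold` within at
#' least one group x timepoint cell. Samples whose half-panel failed
#' amplification QC are excluded from both the numerator and denominator for
#' the assays on that half.
#'
#' @param detected logical matrix (miRNA x sample).
#' @param groups,timepoints labels per sample.
#' @param threshold detection-rate threshold (default 0.80, `>=` semantics).
#' @param panel_ok optional logical matrix (sample x panel half).
#' @param panel_half optional panel-half label per miRNA ("I"/"II").
#' @return character vector of retained miRNA ids.
#' @export
filter_expressed <- function(detected, groups, timepoints, threshold = 0.80,
                             panel_ok = NULL, panel_half = NULL) {
  stopifnot(length(groups) == ncol(detected),
            length(timepoints) == ncol(detected))
  usable <- matrix(TRUE, nrow(detected), ncol(detected))
  if (!is.null(panel_ok) && !is.null(panel_half)) {
    for (h in colnames(panel_ok)) {
      usable[panel_half == h, !panel_ok[, h]] <- FALSE
    }
  }
  cells <- interaction(groups, timepoints, drop = TRUE)
  keep <- rep(FALSE, nrow(detected))
  for (cell in levels(cells)) {
    idx <- cells == cell
    if (!any(idx)) {
      warning("empty group x timepoint cell skipped: ", cell)
      next
    }
    denom <- rowSums(usable[, idx, drop = FALSE])
    rate <- rowSums(detected[, idx, drop = FALSE] &
                      usable[, idx, drop = FALSE]) / pmax(denom, 1)
    keep <- keep | (denom > 0 & rate >= threshold)
  }
  ids <- rownames(detected) %||% as.character(seq_len(nrow(detected)))
  ids[keep]
}

#' Global-mean delta-CT normalization
#'
#' For each sample, the average CT over the expressed miRNAs entering the
#' matrix is subtracted from every CT: `delta_ct[m, s] = ct[m, s] -
#' mean_m(ct[, s])`. Per sample, the mean delta-CT is zero by construction.
#' A difference of 1.0 delta-CT between samples corresponds to a twofold
#' expression difference; lower values mean higher expression.
#'
#' @param ct_matrix complete CT matrix (run after imputation).
#' @return list with `delta_ct` and `sample_mean_ct`.
#' @export
global_mean_normalize <- function(ct_matrix) {
  if (anyNA(ct_matrix)) {
    stop("ct_matrix contains missing values; impute non-detects first")
  }
  mu <- colMeans(ct_matrix)
  list(delta_ct = sweep(ct_matrix, 2, mu), sample_mean_ct = mu)
}

#' Group delta-delta-CT
#'
#' `ddct = mean delta-CT(exposed) - mean delta-CT(control)` per miRNA;
#' negative values indicate higher expression in the exposed group.
#'
#' @param delta_ct normalized matrix (miRNA x sample).
#' @param groups "control"/"exposed" per sample.
#' @return named numeric vector of delta-delta-CT values.
#' @export
delta_delta_ct <- function(delta_ct, groups) {
  if (!all(c("control", "exposed") %in% groups)) {
    stop("both groups must be present")
  }
  rowMeans(delta_ct[, groups == "exposed", drop = FALSE]) -
    rowMeans(delta_ct[, groups == "control", drop = FALSE])
}

#' Run full panel QC and normalization
#'
#' Convenience wrapper: hemolysis exclusion, expressed filtering, imputation
#' and global-mean normalization, with a machine-readable QC report.
#'
#' @param panel a `ct_panel` (see [generate_ct_panel()]) or a compatible list.
#' @param hemolysis data.frame from [generate_hemolysis_metrics()] or NULL.
#' @param threshold detection threshold for [filter_expressed()].
#' @return list with `delta_ct`, `imputed`, `samples` (retained metadata),
#'   `expressed_ids`, and `qc_report` (excluded samples with reasons).
#' @export
qc_normalize_panel <- function(panel, hemolysis = NULL, threshold = 0.80) {
  samples <- panel$samples
  excluded <- data.frame(sample_id = character(), reason = character())
  keep_s <- rep(TRUE, nrow(samples))
  if (!is.null(hemolysis)) {
    hq <- assess_hemolysis(hemolysis$a414, hemolysis$ct_mir23a,
                           hemolysis$ct_mir451a, hemolysis$slc4a1_detected)
    fail <- hq$status == "fail"
    if (any(fail)) {
      excluded <- data.frame(sample_id = hemolysis$sample_id[fail],
                             reason = "hemolysis")
      keep_s <- !samples$sample_id %in% hemolysis$sample_id[fail]
    }
  }
  ct <- panel$ct[, keep_s, drop = FALSE]
  detected <- panel$detected[, keep_s, drop = FALSE]
  samples <- samples[keep_s, ]
  panel_ok <- panel$panel_ok[keep_s, , drop = FALSE]
  expressed <- filter_expressed(detected, samples$group, samples$timepoint,
                                threshold = threshold,
                                panel_ok = panel_ok,
                                panel_half = panel$panel_half)
  # imputation is per miRNA within a timepoint (groups pooled)
  ct_e <- ct[expressed, , drop = FALSE]
  imputed <- matrix(FALSE, nrow(ct_e), ncol(ct_e), dimnames = dimnames(ct_e))
  for (tp in unique(samples$timepoint)) {
    idx <- samples$timepoint == tp
    blk <- ct_e[, idx, drop = FALSE]
    # a miRNA undetected throughout this age borrows its other-age maximum
    all_nd <- rowSums(!is.na(blk)) == 0
    if (any(all_nd)) {
      blk[all_nd, 1] <- apply(ct_e[all_nd, , drop = FALSE], 1,
                              max, na.rm = TRUE)
    }
    imp_tp <- impute_nondetects(blk)
    if (any(all_nd)) {
      imp_tp$ct[all_nd, 1] <- imp_tp$ct[all_nd, 1] + 1
      imp_tp$imputed[all_nd, 1] <- TRUE
    }
    ct_e[, idx] <- imp_tp$ct
    imputed[, idx] <- imp_tp$imputed
  }
  imp <- list(ct = ct_e, imputed = imputed)
  norm <- global_mean_normalize(imp$ct)
  list(delta_ct = norm$delta_ct, imputed = imp$imputed,
       sample_mean_ct = norm$sample_mean_ct,
       samples = samples, expressed_ids = expressed,
       qc_report = list(excluded_samples = excluded,
                        n_expressed = length(expressed),
                        threshold = threshold))
}
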