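# Within-group co-expression structure: masked Pearson correlation matrices,
# significant-pair counting, bootstrap stability with percentile CIs,
# chromosome annotation from miRBase-dialect GFF3, and cross-chromosome
# enrichment.

#' Masked within-group Pearson correlations
#'
#' Pairwise Pearson correlations over the subjects of one group; two-sided
#' p-values from the t transform with `m - 2` degrees of freedom (m =
#' subjects). Correlations with p >= alpha are masked (set `NA` in the masked
#' matrix). Constant miRNAs give undefined correlations, treated as
#' non-significant with a warning. The clustering order is complete-linkage
#' hierarchical clustering on distance `1 - r`.
#'
#' @param delta_ct matrix (miRNA x sample) restricted to one group, or full
#'   matrix with `group`/`which_group` given.
#' @param group optional per-sample labels; @param which_group group to use.
#' @param alpha masking level (default 0.05).
#' @return list: `r`, `p`, `r_masked`, `mask` (logical, TRUE = significant),
#'   `n_significant`, `n_pairs`, `order`.
#' @export
masked_correlations <- function(delta_ct, group = NULL, which_group = NULL,
                                alpha = 0.05) {
  if (!is.null(group)) {
    delta_ct <- delta_ct[, group == which_group, drop = FALSE]
  }
  m <- ncol(delta_ct)   # subjects
  stopifnot(m >= 4)
  x <- t(delta_ct)
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant miRNA(s): correlations undefined, ",
            "treated as non-significant")
  }
  r <- suppressWarnings(stats::cor(x))
  tt <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), m - 2)
  p[is.na(r)] <- 1
  diag(p) <- 0
  mask <- p < alpha
  diag(mask) <- FALSE
  r_masked <- r
  r_masked[!mask & row(r) != col(r)] <- NA_real_
  r0 <- r
  r0[is.na(r0)] <- 0
  ord <- stats::hclust(stats::as.dist(1 - r0), method = "complete")$order
  list(r = r, p = p, r_masked = r_masked, mask = mask,
       n_subjects = m,
       n_significant = sum(mask[upper.tri(mask)]),
       n_pairs = choose(nrow(r), 2), order = ord)
}

#' Bootstrap stability of the significant-pair count
#'
#' Resamples subjects with replacement, recounts significant correlations,
#' and reports the percentile confidence interval of the count distribution
#' together with its mean +/- SD band.
#'
#' @param delta_ct matrix (miRNA x sample) for one group.
#' @param n_boot bootstrap resamples (>= 100).
#' @param ci_level confidence level (default 0.99).
#' @param alpha masking level.
#' @param seed RNG seed.
#' @return list: `counts`, `ci` (percentile), `mean`, `sd`.
#' @export
bootstrap_pair_count_stability <- function(delta_ct, n_boot = 1000,
                                           ci_level = 0.99, alpha = 0.05,
                                           seed = 1L) {
  stopifnot(n_boot >= 100)
  m <- ncol(delta_ct)
  counts <- withr::with_seed(substream_seed(seed, 6), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, replace = TRUE)
      cs <- suppressWarnings(
        masked_correlations(delta_ct[, idx, drop = FALSE], alpha = alpha))
      cs$n_significant
    }, numeric(1))
  })
  lo <- (1 - ci_level) / 2
  list(counts = counts,
       ci = unname(stats::quantile(counts, c(lo, 1 - lo), type = 7)),
       mean = mean(counts), sd = stats::sd(counts))
}

#' Load miRNA loci from a miRBase-dialect GFF3
#'
#' One locus per mature-miRNA record; a MIMAT accession occurring more than
#' once (chromosomal duplication) gets incrementing `copy_index` (0, 1, ...)
#' in file order. Coordinates are kept 1-based inclusive. Malformed
#' non-comment lines (fewer than 9 tab-separated fields) raise an error
#' naming the line number.
#'
#' @param path GFF3 file.
#' @return data.frame: `mimat_id`, `name`, `chromosome`, `start`, `end`,
#'   `strand`, `copy_index`.
#' @export
load_loci_gff3 <- function(path) {
  raw <- readLines(path)
  body <- !grepl("^#", raw) & nzchar(trimws(raw))
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    stop("malformed GFF3 line ", which(body)[nf != 9][1], " in ", path)
  }
  if (!any(body)) {
    return(data.frame(mimat_id = character(), name = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      copy_index = integer()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("miRNA", "miRNA_primary_transcript")]
  md <- S4Vectors::mcols(gr)
  alias <- if ("Alias" %in% names(md)) {
    vapply(md$Alias, function(a) if (length(a)) a[[1]] else NA_character_,
           character(1))
  } else NA_character_
  mimat <- ifelse(is.na(alias) | !nzchar(alias),
                  sub("_[0-9]+$", "", as.character(md$ID)), alias)
  loci <- data.frame(
    mimat_id = mimat,
    name = as.character(md$Name %||% mimat),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  loci$copy_index <- stats::ave(seq_len(nrow(loci)), loci$mimat_id,
                                FUN = function(i) seq_along(i) - 1L)
  loci
}

#' Flag genomically clustered miRNA loci
#'
#' A locus is flagged iff another miRNA locus on the same chromosome lies
#' within `window` bp (distance between nearest coordinates, 0 for
#' overlapping loci).
#'
#' @param loci data.frame from [load_loci_gff3()].
#' @param window bp window (default 10 kb).
#' @return logical vector per locus.
#' @export
chromosomal_cluster_flags <- function(loci, window = 10000) {
  n <- nrow(loci)
  flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    same <- which(loci$chromosome == loci$chromosome[i])
    same <- setdiff(same, i)
    if (!length(same)) next
    gap <- pmax(0, pmax(loci$start[i] - loci$end[same],
                        loci$start[same] - loci$end[i]))
    flag[i] <- any(gap <= window)
  }
  flag
}

#' Cross-chromosome correlation enrichment
#'
#' For each unordered chromosome pair, counts significant correlations with
#' one member on each chromosome, normalizes by the product of the numbers
#' of expressed miRNAs on the two chromosomes, and reports the exposed /
#' control fold change. A significant miRNA pair counts once per
#' chromosome-pair combination of its loci (duplicated loci contribute to
#' every combination). Division by zero yields `Inf` with a flag.
#'
#' @param summary_control,summary_exposed results of [masked_correlations()]
#'   computed on the same miRNA set (rownames must match `loci$mimat_id`).
#' @param loci annotated loci.
#' @return data.frame per chromosome pair: counts, normalized counts,
#'   `fold_change`, `undefined` flag.
#' @export
cross_chromosome_enrichment <- function(summary_control, summary_exposed,
                                        loci) {
  ids <- rownames(summary_control$r)
  stopifnot(identical(ids, rownames(summary_exposed$r)))
  unannot <- setdiff(ids, loci$mimat_id)
  if (length(unannot)) {
    warning(length(unannot), " unannotated miRNA(s) excluded from ",
            "enrichment")
  }
  chr_of <- split(loci$chromosome, loci$mimat_id)
  n_on_chr <- table(unique(loci[, c("mimat_id", "chromosome")])$chromosome)

  count_pairs <- function(mask) {
    counts <- list()
    idx <- which(upper.tri(mask) & mask, arr.ind = TRUE)
    for (q in seq_len(nrow(idx))) {
      m1 <- ids[idx[q, 1]]; m2 <- ids[idx[q, 2]]
      c1 <- chr_of[[m1]]; c2 <- chr_of[[m2]]
      if (is.null(c1) || is.null(c2)) next
      combos <- unique(expand.grid(a = c1, b = c2,
                                   stringsAsFactors = FALSE))
      combos <- combos[combos$a != combos$b, , drop = FALSE]
      for (q2 in seq_len(nrow(combos))) {
        key <- paste(sort(c(combos$a[q2], combos$b[q2])), collapse = "|")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
    counts
  }
  cc <- count_pairs(summary_control$mask)
  ce <- count_pairs(summary_exposed$mask)
  keys <- union(names(cc), names(ce))
  if (!length(keys)) {
    return(data.frame(chrom1 = character(), chrom2 = character(),
                      count_control = numeric(), count_exposed = numeric(),
                      norm_control = numeric(), norm_exposed = numeric(),
                      fold_change = numeric(), undefined = logical()))
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  denom <- as.numeric(n_on_chr[parts[, 1]]) *
    as.numeric(n_on_chr[parts[, 2]])
  nc <- vapply(keys, function(k) cc[[k]] %||% 0, numeric(1)) / denom
  ne <- vapply(keys, function(k) ce[[k]] %||% 0, numeric(1)) / denom
  fc <- ifelse(nc > 0, ne / nc, ifelse(ne > 0, Inf, NaN))
  data.frame(chrom1 = parts[, 1], chrom2 = parts[, 2],
             count_control = nc * denom, count_exposed = ne * denom,
             norm_control = nc, norm_exposed = ne,
             fold_change = fc, undefined = !is.finite(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}
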