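# Masked correlations, bootstrap stability, GFF3 loci, enrichment.

test_that("pair bookkeeping and masking behave as defined", {
  withr::with_seed(41, {
    x18 <- matrix(stats::rnorm(18 * 20), 18,
                  dimnames = list(sprintf("m%02d", 1:18), NULL))
    x26 <- matrix(stats::rnorm(26 * 20), 26,
                  dimnames = list(sprintf("m%02d", 1:26), NULL))
  })
  s18 <- masked_correlations(x18)
  s26 <- masked_correlations(x26)
  expect_equal(s18$n_pairs, 153)
  expect_equal(s26$n_pairs, 325)
  expect_true(s18$n_significant <= s18$n_pairs)
  # order is a permutation
  expect_setequal(s18$order, 1:18)

  # two perfectly correlated rows stay unmasked with r = 1
  x <- x18
  x[2, ] <- 2 * x[1, ] + 3
  sp <- masked_correlations(x)
  expect_equal(sp$r[1, 2], 1, tolerance = 1e-12)
  expect_true(sp$mask[1, 2])

  # constant row warns and is treated as non-significant
  x[3, ] <- 1
  expect_warning(sc <- masked_correlations(x), "constant")
  expect_false(any(sc$mask[3, ], na.rm = TRUE))
})

test_that("null correlation counts match the alpha level", {
  counts <- vapply(1:40, function(s) {
    withr::with_seed(500 + s, {
      x <- matrix(stats::rnorm(20 * 30), 20)
    })
    rownames(x) <- sprintf("m%02d", 1:20)
    masked_correlations(x)$n_significant
  }, numeric(1))
  expected <- 0.05 * choose(20, 2)
  mc_sd <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * max(mc_sd, 1e-6) + 1e-9)
})

test_that("bootstrap pair-count stability is seeded and degenerate-tight", {
  fx <- fixture_cohort()
  tp1 <- fx$qc$samples$timepoint == "T2wk"
  grp <- fx$qc$samples$group[tp1]
  dct <- fx$qc$delta_ct[fx$cohort$truth$responsive_ids, tp1]
  b1 <- bootstrap_pair_count_stability(dct[, grp == "exposed"],
                                       n_boot = 200, seed = 3)
  b2 <- bootstrap_pair_count_stability(dct[, grp == "exposed"],
                                       n_boot = 200, seed = 3)
  expect_identical(b1$ci, b2$ci)

  # perfectly co-moving miRNAs: every resample finds all pairs significant
  withr::with_seed(42, {
    signal <- stats::rnorm(30)
    dup <- outer(rep(1, 10), signal) +
      matrix(stats::rnorm(300, 0, 1e-6), 10, 30)
  })
  rownames(dup) <- sprintf("m%02d", 1:10)
  bd <- bootstrap_pair_count_stability(dup, n_boot = 120, seed = 1)
  expect_equal(unname(diff(bd$ci)), 0)

  # a shared factor in one group separates the count distributions,
  # mirroring the exposed-vs-control stability contrast
  withr::with_seed(77, {
    n <- 30; m <- 15
    f <- stats::rnorm(n)
    with_factor <- matrix(stats::rnorm(m * n), m, n) +
      outer(rep(0.9, m), f)
    no_factor <- matrix(stats::rnorm(m * n), m, n)
    rownames(with_factor) <- rownames(no_factor) <- sprintf("m%02d", 1:m)
  })
  bf <- bootstrap_pair_count_stability(with_factor, n_boot = 200, seed = 2)
  b0 <- bootstrap_pair_count_stability(no_factor, n_boot = 200, seed = 2)
  expect_gt(bf$ci[1], b0$ci[2])   # 99 % CIs separate
})

test_that("GFF3 loci round-trip and malformed input is located", {
  fx <- fixture_cohort()
  loci <- synthetic_mirna_loci(fx$cohort$truth, fx$cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_mirna_gff3(loci, path)
  back <- load_loci_gff3(path)
  expect_equal(nrow(back), nrow(loci))
  key <- function(d) d[order(d$mimat_id, d$copy_index),
                       c("mimat_id", "chromosome", "start", "end",
                         "strand", "copy_index")]
  expect_equal(key(back), key(loci), ignore_attr = TRUE)
  # duplicated MIMATs got copy_index 0 then 1
  dups <- table(loci$mimat_id)
  if (any(dups > 1)) {
    id <- names(dups)[dups > 1][1]
    expect_setequal(back$copy_index[back$mimat_id == id], c(0, 1))
  }

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tmiRNA\t10\t30\t.\t+\t.\tID=M1",
               "chr1\tx\tmiRNA\t10\t30"), bad)
  expect_error(load_loci_gff3(bad), "line 3")

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(load_loci_gff3(empty)), 0)
})

test_that("10-kb cluster flags use same-chromosome nearest distance", {
  loci <- data.frame(
    mimat_id = c("a", "b", "c", "d", "e"),
    name = letters[1:5],
    chromosome = c("chr1", "chr1", "chr2", "chr3", "chr3"),
    start = c(1000, 9000, 9000, 0, 18000),
    end = c(1021, 9021, 9021, 21, 18021),
    strand = "+", copy_index = 0L)
  flags <- chromosomal_cluster_flags(loci)
  expect_equal(flags, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  chain <- data.frame(
    mimat_id = c("x", "y", "z"), name = c("x", "y", "z"),
    chromosome = "chr5", start = c(0, 9000, 18000),
    end = c(21, 9021, 18021), strand = "+", copy_index = 0L)
  expect_true(all(chromosomal_cluster_flags(chain)))
})

test_that("cross-chromosome enrichment recovers constructed fold changes", {
  ids <- c("m1", "m2", "m3", "m4")
  loci <- data.frame(mimat_id = ids, name = ids,
                     chromosome = c("chr16", "chr16", "chr1", "chr1"),
                     start = c(1, 100, 1, 100) * 1e6,
                     end = c(1, 100, 1, 100) * 1e6 + 21,
                     strand = "+", copy_index = 0L)
  mk <- function(pairs) {
    mask <- matrix(FALSE, 4, 4, dimnames = list(ids, ids))
    for (pr in pairs) {
      mask[pr[1], pr[2]] <- mask[pr[2], pr[1]] <- TRUE
    }
    list(r = matrix(0, 4, 4, dimnames = list(ids, ids)), mask = mask)
  }
  # control: 1 cross pair m1-m3; exposed: all 4 cross pairs... scaled case
  ctrl <- mk(list(c(1, 3)))
  expo <- mk(list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  enr <- cross_chromosome_enrichment(ctrl, expo, loci)
  row <- enr[enr$chrom1 == "chr1" & enr$chrom2 == "chr16", ]
  expect_equal(row$fold_change, 4)
  expect_equal(row$count_control, 1)
  expect_equal(row$count_exposed, 4)

  # identical groups: fold change 1
  same <- cross_chromosome_enrichment(expo, expo, loci)
  expect_true(all(same$fold_change == 1))

  # everything masked: empty table
  none <- cross_chromosome_enrichment(mk(list()), mk(list()), loci)
  expect_equal(nrow(none), 0)

  # a 23x contrast is recovered exactly when counts are 1 vs 23
  ids2 <- c(sprintf("c16_%d", 1:6), sprintf("c1_%d", 1:6))
  loci2 <- data.frame(mimat_id = ids2, name = ids2,
                      chromosome = rep(c("chr16", "chr1"), each = 6),
                      start = seq(1e6, 12e6, length.out = 12),
                      end = seq(1e6, 12e6, length.out = 12) + 21,
                      strand = "+", copy_index = 0L)
  cross <- expand.grid(a = 1:6, b = 7:12)
  mk2 <- function(k) {
    mask <- matrix(FALSE, 12, 12, dimnames = list(ids2, ids2))
    for (i in seq_len(k)) {
      mask[cross$a[i], cross$b[i]] <- mask[cross$b[i], cross$a[i]] <- TRUE
    }
    list(r = matrix(0, 12, 12, dimnames = list(ids2, ids2)), mask = mask)
  }
  enr23 <- cross_chromosome_enrichment(mk2(1), mk2(23), loci2)
  expect_equal(enr23$fold_change[enr23$chrom1 == "chr1"], 23)
})

test_that("significant pairs partition into within- and cross-chromosome", {
  fx <- fixture_cohort()
  tp1 <- fx$qc$samples$timepoint == "T2wk"
  grp <- fx$qc$samples$group[tp1]
  dct <- fx$qc$delta_ct[, tp1]
  cs <- masked_correlations(dct, grp, "exposed")
  loci <- synthetic_mirna_loci(fx$cohort$truth, fx$cfg)
  loci <- loci[loci$copy_index == 0, ]   # single-locus bookkeeping
  chr <- loci$chromosome[match(rownames(cs$r), loci$mimat_id)]
  idx <- which(upper.tri(cs$mask) & cs$mask, arr.ind = TRUE)
  n_within <- sum(chr[idx[, 1]] == chr[idx[, 2]])
  n_cross <- sum(chr[idx[, 1]] != chr[idx[, 2]])
  expect_equal(n_within + n_cross, cs$n_significant)
  enr <- cross_chromosome_enrichment(cs, cs, loci)
  expect_equal(sum(enr$count_control), n_cross)
})
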