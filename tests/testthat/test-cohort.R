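test_that("the emulated cohort matches the study design", {
  prof <- cohort_profile()
  expect_identical(unname(prof$samples[c("TIW", "GAL", "TIJ", "YAR", "PNG")]),
                   c(34, 17, 7, 31, 25))

  small <- cohort_profile(samples = default_sample_config(4, 3, 2, 4, 3, 2))
  ds <- emulate_cohort(small, locus_config(8, 2e4), seed = 5)
  expect_identical(as.integer(table(ds$samples$population)[c("TIW", "GAL")]),
                   c(4L, 3L))
  expect_false(is.null(ds$masks))
  expect_type(attr(ds, "provenance"), "list")
  pt <- attr(ds, "provenance")$pulse_time
  expect_true(pt >= 3 && pt <= 7)

  # zero masking reproduces the unmasked dataset
  zero <- cohort_profile(samples = default_sample_config(3, 2, 2, 2, 2, 2),
                         mask_mean = c(TIW = 0, GAL = 0, TIJ = 0, YAR = 0,
                                       PNG = 0, OUT = 0))
  dz <- emulate_cohort(zero, locus_config(6, 2e4), seed = 9)
  expect_true(all(vapply(dz$loci, function(l) !anyNA(l$geno), logical(1))))
})

test_that("the Yarrabah pulse moves lineages into PNG and depresses admixture F3", {
  # lineage-level mechanism at the calibrated 1.8% proportion: with the
  # pulse (and no migration bands) some YAR-PNG pairs coalesce more
  # recently than the AU-PNG split; without it, none can
  sam <- c(YAR = 10, PNG = 10)
  m_on <- scenario4_calibrated(yarrabah_pulse = TRUE, migration = FALSE,
                               include_outgroup = FALSE)
  m_off <- scenario4_calibrated(yarrabah_pulse = FALSE, migration = FALSE,
                                include_outgroup = FALSE)
  lc0 <- locus_config(120, 1e3, 0)
  d_on <- simulate_dataset(m_on, sam, lc0, seed = 8, keep_trees = TRUE)
  d_off <- simulate_dataset(m_off, sam, lc0, seed = 8, keep_trees = TRUE)
  t_on <- pair_coalescence_times(d_on$trees, "YAR", "PNG")
  t_off <- pair_coalescence_times(d_off$trees, "YAR", "PNG")
  expect_true(all(t_off > 1636))
  expect_gt(sum(t_on < 1636), 0)

  # direction of the admixture-F3 shift, at an amplified proportion where
  # the desk-scale effect clears replicate noise
  lc <- locus_config(80, 2e4)
  samf <- default_sample_config(6, 6, 6, 10, 10, 0)
  m_big <- m_on
  m_big$pulses$proportion <- 0.15
  diffs <- vapply(1:10, function(r) {
    d1 <- simulate_dataset(m_big, samf, lc, seed = 600 + r)
    d0 <- simulate_dataset(m_off, samf, lc, seed = 600 + r)
    f_statistic(d1, "F3", c("YAR", "PNG", "TIJ"))$estimate -
      f_statistic(d0, "F3", c("YAR", "PNG", "TIJ"))$estimate
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("apply_mask hits requested fractions and flags heavy masking", {
  m <- simple_model(ne = 2000)
  ds <- simulate_dataset(m, c(A = 4), locus_config(10, 5e4), seed = 3)

  id <- apply_mask(ds, fractions = 0, seed = 1)
  expect_true(all(vapply(id$loci, function(l) !anyNA(l$geno), logical(1))))

  full <- apply_mask(ds, fractions = c(1, 0, 0, 0), seed = 1)
  expect_true(all(is.na(full$loci[[1]]$geno[, 1:2])))
  expect_identical(attr(full, "flagged"), "A_001")

  for (f in c(0.05, 0.2, 0.5)) {
    dm <- apply_mask(ds, fractions = f, seed = 7)
    realized <- vapply(seq_len(4), function(i) {
      1 - coalabc:::unmasked_fraction_individual(dm, i)
    }, numeric(1))
    expect_true(all(abs(realized - f) < 0.02))
  }
  expect_error(apply_mask(ds, fractions = c(0.5, 0.2)), "input error")
})

test_that("masking never creates variants", {
  m <- simple_model(ne = 3000)
  ds <- simulate_dataset(m, c(A = 6), locus_config(12, 2e4), seed = 21)
  dm <- apply_mask(ds, fractions = 0.4, seed = 2)
  for (i in seq_along(ds$loci)) {
    seg_before <- ds$loci[[i]]$pos[
      rowSums(ds$loci[[i]]$geno, na.rm = TRUE) > 0]
    g <- dm$loci[[i]]$geno
    seg_after <- dm$loci[[i]]$pos[rowSums(g, na.rm = TRUE) > 0 &
                                    rowSums(!is.na(g)) > 0]
    expect_true(all(seg_after %in% seg_before))
  }
})

test_that("pairwise unmasked fractions match a per-base oracle", {
  expect_identical(pairwise_unmasked_fraction(
    list(matrix(numeric(0), 0, 2)), list(matrix(numeric(0), 0, 2)), 1e4), 1)

  half1 <- list(rbind(c(0, 5000)))
  half2 <- list(rbind(c(5000, 10000)))
  expect_identical(pairwise_unmasked_fraction(half1, half2, 1e4), 0)

  set.seed(9)
  for (rep in 1:6) {
    mk <- function() {
      n <- sample(1:4, 1)
      s <- sort(sample(0:9000, n))
      list(coalabc:::merge_intervals(cbind(s, s + sample(200:1500, n,
                                                         replace = TRUE))))
    }
    a <- mk(); b <- mk()
    base_cov <- rep(FALSE, 1e4)
    for (iv in list(a[[1]], b[[1]])) {
      for (r in seq_len(nrow(iv))) {
        lo <- max(0, iv[r, 1]); hi <- min(1e4, iv[r, 2])
        if (hi > lo) base_cov[(lo + 1):hi] <- TRUE
      }
    }
    expect_equal(pairwise_unmasked_fraction(a, b, 1e4),
                 1 - sum(base_cov) / 1e4)
  }
})

test_that("masked-then-rescaled statistics track the unmasked truth", {
  m <- simple_model(ne = 5000)
  ds <- simulate_dataset(m, c(A = 10), locus_config(12, 5e4), seed = 11)
  truth_het <- het_per_individual(ds)
  dm <- apply_mask(ds, fractions = 0.3, seed = 4)
  resc <- het_per_individual(dm, rescale = TRUE)
  expect_lt(abs(mean(resc) / mean(truth_het) - 1), 0.1)
})
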