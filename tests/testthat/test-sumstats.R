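# brute-force oracles -------------------------------------------------------

pi_oracle <- function(g, L) {
  # mean pairwise Hamming distance per site over all haplotype pairs
  n <- ncol(g)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(g[, i] != g[, j], na.rm = TRUE)
  }
  tot / choose(n, 2) / L
}

test_that("nucleotide diversity matches hand values and the all-pairs oracle", {
  mono <- make_dataset(matrix(0L, 3, 4)[0, , drop = FALSE],
                       pops = c("A", "A"), locus_length = 10)
  expect_identical(nucleotide_diversity(mono, "A"), 0)

  # 4 haplotypes, one singleton site, L = 1: 3 of 6 pairs differ
  single <- make_dataset(matrix(c(1L, 0L, 0L, 0L), 1, 4),
                         pops = c("A", "A"), locus_length = 1)
  expect_equal(nucleotide_diversity(single, "A"), 0.5)

  for (s in 1:8) {
    g <- random_geno(20, 10, seed = s)
    ds <- make_dataset(g, pops = rep("A", 5), locus_length = 20)
    expect_equal(nucleotide_diversity(ds, "A"), pi_oracle(g, 20))
  }
  expect_error(nucleotide_diversity(
    make_dataset(matrix(0L, 1, 2), "A"), "B"))
})

test_that("segregating sites are counted within the focal population only", {
  # site fixed derived in A but variable globally
  g <- rbind(c(1L, 1L, 1L, 1L, 0L, 0L),
             c(0L, 1L, 0L, 0L, 0L, 0L))
  ds <- make_dataset(g, pops = c("A", "A", "B"))
  expect_equal(segregating_sites(ds, "A"), 1)
  expect_identical(segregating_sites(ds, "Z"), 0L)

  for (s in 1:8) {
    g <- random_geno(30, 8, seed = 100 + s)
    ds <- make_dataset(g, pops = rep("A", 4))
    expect_equal(segregating_sites(ds, "A"),
                 sum(rowSums(g) > 0 & rowSums(g) < 8))
  }
})

test_that("Tajima's D reproduces the hand-worked n=4 cases", {
  # single singleton: frozen hand computation via the standard constants
  # a1 = 11/6, theta_W = 6/11, pi = 1/2 -> D = -0.6124
  single <- make_dataset(matrix(c(1L, 0L, 0L, 0L), 1, 4),
                         pops = c("A", "A"), locus_length = 1)
  expect_equal(tajimas_d(single, "A"), -0.6124, tolerance = 1e-3)

  # single doubleton: pi = 2/3 > theta_W -> positive D
  doub <- make_dataset(matrix(c(1L, 1L, 0L, 0L), 1, 4), pops = c("A", "A"))
  expect_gt(tajimas_d(doub, "A"), 0)

  # no segregating sites -> undefined marker, not zero
  mono <- make_dataset(matrix(1L, 1, 4), pops = c("A", "A"))
  expect_true(is.na(tajimas_d(mono, "A")))
})

test_that("F-statistic point values follow the estimator algebra", {
  # F4 with identical frequency vectors for A and B is exactly 0
  g <- random_geno(25, 16, seed = 3)
  ds <- make_dataset(cbind(g[, 1:4], g[, 1:4], g[, 5:8], g[, 9:12]),
                     pops = c("A", "A", "B", "B", "C", "C", "D", "D"))
  expect_equal(f_statistic(ds, "F4", c("A", "B", "C", "D"))$estimate, 0)

  # F3(C; A, B) = 1 for a site with C fixed ancestral, A and B fixed derived
  g1 <- matrix(c(0L, 0L, 1L, 1L, 1L, 1L), 1, 6)
  ds1 <- make_dataset(g1, pops = c("C", "A", "B"))
  expect_equal(f_statistic(ds1, "F3", c("C", "A", "B"))$estimate, 1)

  # F3 with identical sources reduces to corrected F2 >= 0 in expectation
  m <- simple_model(ne = 1000, split_gen = 800)
  dd <- simulate_dataset(m, c(A = 4, B = 4), locus_config(30, 2e4), seed = 6)
  f3 <- f_statistic(dd, "F3", c("A", "B", "B"))
  f2 <- f_statistic(dd, "F2", c("A", "B"))
  expect_gt(f3$estimate, 0)
  expect_equal(f3$estimate, f2$estimate, tolerance = 0.2)
})

test_that("F-statistic symmetry identities hold exactly", {
  g <- random_geno(60, 16, seed = 9)
  ds <- make_dataset(g, pops = rep(c("A", "B", "C", "D"), each = 2))
  f3ab <- f_statistic(ds, "F3", c("C", "A", "B"))$estimate
  f3ba <- f_statistic(ds, "F3", c("C", "B", "A"))$estimate
  expect_identical(f3ab, f3ba)

  f4 <- f_statistic(ds, "F4", c("A", "B", "C", "D"))$estimate
  expect_identical(f_statistic(ds, "F4", c("B", "A", "C", "D"))$estimate, -f4)
  expect_identical(f_statistic(ds, "F4", c("C", "D", "A", "B"))$estimate, f4)
})

test_that("frequency statistics are invariant to ancestral/derived relabeling", {
  g <- random_geno(40, 12, seed = 21)
  ds <- make_dataset(g, pops = rep(c("A", "B", "C"), each = 2))
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), nrow(g), replace = TRUE)
  g2 <- g
  g2[flip, ] <- 1L - g2[flip, ]
  ds2 <- make_dataset(g2, pops = rep(c("A", "B", "C"), each = 2))

  expect_equal(nucleotide_diversity(ds, "A"), nucleotide_diversity(ds2, "A"))
  expect_identical(segregating_sites(ds, "A"), segregating_sites(ds2, "A"))
  expect_equal(tajimas_d(ds, "A"), tajimas_d(ds2, "A"))
  expect_equal(fst_hudson(ds, "A", "B"), fst_hudson(ds2, "A", "B"))
  expect_equal(f_statistic(ds, "F3", c("C", "A", "B"))$estimate,
               f_statistic(ds2, "F3", c("C", "A", "B"))$estimate)
})

test_that("weighted block jackknife behaves like a jackknife", {
  m <- simple_model(ne = 2000, split_gen = 400)
  ds <- simulate_dataset(m, c(A = 3, B = 3), locus_config(25, 2e4), seed = 2)
  r <- f_statistic(ds, "F2", c("A", "B"))
  expect_gt(r$se, 0)
  expect_equal(r$z, r$estimate / r$se)

  # estimate invariant under block permutation
  set.seed(1)
  perm <- sample(length(ds$loci))
  ds2 <- ds
  ds2$loci <- ds$loci[perm]
  r2 <- f_statistic(ds2, "F2", c("A", "B"))
  expect_equal(r$estimate, r2$estimate)
  expect_equal(r$se, r2$se, tolerance = 1e-12)
})

test_that("F moments are central moments of block values", {
  fake <- structure(list(block_values = c(-1, 0, 1)), class = "fstat_result")
  expect_equal(unname(f_moments(fake)), c(2 / 3, 0))

  const <- structure(list(block_values = rep(0.4, 5)), class = "fstat_result")
  expect_equal(unname(f_moments(const)), c(0, 0))

  set.seed(77)
  x <- rnorm(40)
  r <- structure(list(block_values = x), class = "fstat_result")
  expect_equal(unname(f_moments(r)),
               c(mean((x - mean(x))^2), mean((x - mean(x))^3)))

  expect_error(f_moments(structure(list(block_values = c(1, 2)),
                                   class = "fstat_result")), "3 blocks")
})

test_that("Hudson FST hits its algebraic anchors and drift monotonicity", {
  # two samples drawn from one panmictic population: FST ~ 0 (>= 1e4 sites)
  m0 <- simple_model(ne = 5000)
  d0 <- simulate_dataset(m0, c(A = 8), locus_config(100, 1e5), seed = 19)
  d0$samples$population <- rep(c("A", "B"), each = 4)
  expect_lt(abs(fst_hudson(d0, "A", "B")), 0.01)

  # single fixed-difference site
  gf <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 1, 8)
  dsf <- make_dataset(gf, pops = c(rep("A", 2), rep("B", 2)))
  expect_identical(fst_hudson(dsf, "A", "B"), 1)

  fst_at <- function(t) {
    m <- simple_model(ne = 2000, split_gen = t)
    d <- simulate_dataset(m, c(A = 5, B = 5), locus_config(60, 2e4), seed = 8)
    fst_hudson(d, "A", "B")
  }
  f <- vapply(c(100, 1000, 5000), fst_at, numeric(1))
  expect_true(all(diff(f) > 0))

  # ascertainment restricts the site set
  m <- simple_model(ne = 2000, split_gen = 500)
  d <- simulate_dataset(m, c(A = 4, B = 4), locus_config(20, 2e4), seed = 4)
  expect_false(isTRUE(all.equal(fst_hudson(d, "A", "B"),
                                fst_hudson(d, "A", "B",
                                           ascertainment_pop = "B"))))
})

test_that("sharing classes partition variants and match the oracle", {
  pops <- c("P1", "P1", "P2", "P2", "P3", "P3")
  conts <- c("c1", "c1", "c1", "c1", "c2", "c2")
  # one individual per entry above (2 haplotypes each)
  sharing_oracle <- function(g, pop_of, cont_of) {
    upops <- unique(pop_of)
    res <- matrix(0L, length(upops), 4, dimnames = list(upops, NULL))
    n_cont <- length(unique(cont_of))
    for (s in seq_len(nrow(g))) {
      pres <- vapply(upops, function(p) {
        any(g[s, rep(pop_of, each = 2) == p] == 1, na.rm = TRUE)
      }, logical(1))
      if (!any(pres)) next
      cc <- unique(cont_of[match(upops[pres], pop_of)])
      cls <- if (sum(pres) == 1) 1 else if (length(cc) == 1) 2
             else if (length(cc) < n_cont) 3 else 4
      res[pres, cls] <- res[pres, cls] + 1L
    }
    res
  }
  for (s in 1:10) {
    g <- random_geno(40, 12, seed = 200 + s)
    ds <- make_dataset(g, pops = pops, continents = conts)
    got <- sharing_classes(ds)
    ora <- sharing_oracle(g, pops, conts)
    expect_identical(unname(as.matrix(got[, -1])),
                     unname(ora[got$population, ]))
    # per-population counts sum to variants observed in that population
    for (p in unique(pops)) {
      ix <- rep(pops, each = 2) == p
      expect_identical(sum(as.matrix(got[got$population == p, -1])),
                       sum(rowSums(g[, ix, drop = FALSE]) > 0))
    }
  }

  # anchored patterns
  g <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
             c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))
  ds <- make_dataset(g, pops = pops, continents = conts)
  tw <- sharing_classes(ds)
  p1 <- tw[tw$population == "P1", ]
  expect_identical(p1$population_private, 1L)  # site 1
  expect_identical(p1$continent_private, 1L)   # site 2 (P1+P2, same cont)
  expect_identical(p1$shared_all, 1L)          # site 3 (both continents)
})

test_that("MAC spectrum uses the global minor allele and fills bin 2n", {
  # pop B fixed for the global minor allele -> bin 10
  g <- matrix(0L, 1, 40)
  g[1, 31:40] <- 1L  # 10 of 40 haplotypes -> derived is globally minor
  ds <- make_dataset(g, pops = c(rep("A", 15), rep("B", 5)))
  sp <- mac_spectrum(ds, "B", subsample_n = 5, seed = 1)
  expect_identical(unname(sp["10"]), 1L)
  expect_identical(sum(sp), 1L)

  # pop lacking the minor allele contributes nothing
  spA <- mac_spectrum(ds, "A", subsample_n = 5, seed = 1)
  # A carries only the major allele at this site
  expect_identical(sum(spA), 0L)

  # oracle: spectrum totals = sites where the subsample carries the minor
  for (s in 1:6) {
    g <- random_geno(30, 24, seed = 300 + s)
    ds <- make_dataset(g, pops = c(rep("A", 7), rep("B", 5)))
    set.seed(1); pick <- sample(which(ds$samples$population == "B"), 5)
    cols <- sort(c(2L * pick - 1L, 2L * pick))
    minor_derived <- rowSums(g) / ncol(g) < 0.5
    cnt <- ifelse(minor_derived, rowSums(g[, cols, drop = FALSE]),
                  10 - rowSums(g[, cols, drop = FALSE]))
    sp <- mac_spectrum(ds, "B", subsample_n = 5, seed = 1)
    expect_identical(sum(sp), sum(cnt >= 1))
  }
  expect_error(mac_spectrum(ds, "B", subsample_n = 50), "input error")
})

test_that("heterozygosity counts and mask rescaling", {
  g <- rbind(c(0L, 0L, 0L, 1L),
             c(0L, 0L, 1L, 0L),
             c(1L, 1L, 1L, 1L))
  ds <- make_dataset(g, pops = c("A", "A"))
  het <- het_per_individual(ds)
  expect_identical(unname(het), c(0, 2))

  expect_identical(rescale_count(1000, 0.8), 1250)
  expect_identical(rescale_count(50, 0.5), 100)
  expect_identical(rescale_count(7, 1), 7)
  expect_true(is.na(rescale_count(5, 0)))
})

test_that("rare-allele sharing counts pairs carrying the same rare variants", {
  # duplicated genotypes: maximal off-diagonal value at the twin pair
  g <- random_geno(40, 8, seed = 41)
  gl <- cbind(g, g[, 1:2])  # individual 5 duplicates individual 1
  ds <- make_dataset(gl, pops = rep("A", 5))
  M <- rare_sharing_matrix(ds, max_count = 5)
  off <- M; diag(off) <- NA
  expect_identical(which.max(off[1, ]), c(A_005 = 5L))

  # disjoint rare variants share nothing
  g2 <- rbind(c(1L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L))
  ds2 <- make_dataset(g2, pops = c("A", "A"))
  M2 <- rare_sharing_matrix(ds2, max_count = 5)
  expect_identical(M2[1, 2], 0)
})

test_that("discovery curves are nested, monotone and saturate at the truth", {
  m <- simple_model(ne = 2000)
  ds <- simulate_dataset(m, c(A = 8), locus_config(20, 2e4), seed = 13)
  dc <- discovery_curve(ds, "A", replicates = 5, seed = 2)
  reps <- attr(dc, "replicates")
  expect_true(all(apply(reps, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(reps[8, ] == segregating_sites(ds, "A")))
  expect_error(discovery_curve(ds, "A", n_max = 9), "input error")
})

test_that("novel-variant curves are zero for duplicated continents and monotone", {
  g <- random_geno(60, 12, seed = 51)
  # continent c2 duplicates haplotypes of c1 -> nothing novel
  ds <- make_dataset(cbind(g, g), pops = c(rep("P1", 6), rep("P2", 6)),
                     continents = c(rep("c1", 6), rep("c2", 6)))
  nv <- novel_by_continent_curve(ds, "c2", pre_sample = 6, replicates = 3,
                                 seed = 3)
  expect_true(all(nv$mean_new_variants == 0))

  m <- simple_model(ne = 2000, split_gen = 2000)
  ds2 <- simulate_dataset(m, c(A = 6, B = 6), locus_config(15, 2e4), seed = 5)
  ds2$samples$continent <- rep(c("c1", "c2"), each = 6)
  nv2 <- novel_by_continent_curve(ds2, "c2", pre_sample = 6, replicates = 4,
                                  seed = 4)
  expect_true(all(apply(attr(nv2, "replicates"), 2,
                        function(x) all(diff(x) >= 0))))
  expect_gt(max(nv2$mean_new_variants), 0)
})

test_that("summary vectors are deterministic, complete and cross-checked", {
  m <- scenario4_calibrated()
  sam <- default_sample_config(2, 2, 2, 2, 2, 2)
  lc <- locus_config(15, 2e4)
  ds <- simulate_dataset(m, sam, lc, seed = 31)
  sv <- summary_vector(ds)
  sv2 <- summary_vector(ds)
  expect_identical(sv, sv2)
  expect_false(anyNA(sv))

  # entries equal the standalone operations
  expect_equal(unname(sv["pi_TIW"]), nucleotide_diversity(ds, "TIW"))
  expect_equal(unname(sv["s_GAL"]), as.numeric(segregating_sites(ds, "GAL")))
  f <- f_statistic(ds, "F3", c("OUT", "TIW", "GAL"))
  expect_equal(unname(sv["f3o_TIW_GAL"]), f$estimate)
  expect_equal(unname(sv["f3o_TIW_GAL_m2"]), unname(f_moments(f)["m2"]))

  # fast simulation route agrees with the dataset route
  sv3 <- simulate_summary_vector(m, sam, lc, seed = 31)
  expect_equal(sv, sv3, tolerance = 1e-10)

  expect_error(summary_vector(ds, summary_config(pops = c("TIW", "XX", "PNG"))),
               "input error")
})
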