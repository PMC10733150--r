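# small shared table for the mechanical tests (built once per file)
small_cfg <- abc_sim_config(
  samples = default_sample_config(2, 2, 2, 2, 2, 2),
  locus = locus_config(n_loci = 12, length_bp = 2e4))
small_tab <- generate_reference_table(scenario_catalog(), 6, small_cfg,
                                      seed = 321)

test_that("reference tables have one row per draw and are reproducible", {
  cat7 <- scenario_catalog()
  t1 <- generate_reference_table(cat7, 1, small_cfg, seed = 17)
  expect_identical(nrow(t1), 7L)
  expect_identical(sort(unique(t1$scenario_id)), as.numeric(1:7))
  t2 <- generate_reference_table(cat7, 1, small_cfg, seed = 17)
  expect_identical(t1, t2)
  expect_true(all(grepl("^(scenario_id|par_|ss_)", names(t1))))
})

test_that("prior effective size drives simulated diversity upward", {
  cat_small <- scenario_catalog(list(ne_range = c(500, 2000)))[4]
  cat_large <- scenario_catalog(list(ne_range = c(10000, 30000)))[4]
  ts <- generate_reference_table(cat_small, 12, small_cfg, seed = 5)
  tl <- generate_reference_table(cat_large, 12, small_cfg, seed = 5)
  expect_gt(mean(tl$ss_pi_TIW), mean(ts$ss_pi_TIW))
})

test_that("normalization centers the observed vector and preserves rankings", {
  obs_row <- small_tab[3, ]
  obs <- unlist(obs_row[grep("^ss_", names(small_tab))])
  names(obs) <- sub("^ss_", "", names(obs))

  nz <- suppressWarnings(normalize_summaries(small_tab, obs))
  med <- apply(nz$table_scaled, 2, median)
  expect_true(all(abs(med) < 1e-9))

  # affine rescaling of a raw dimension leaves acceptance order unchanged
  tab2 <- small_tab
  tab2$ss_pi_TIW <- tab2$ss_pi_TIW * 10 + 5
  obs2 <- obs
  obs2["pi_TIW"] <- obs2["pi_TIW"] * 10 + 5
  r1 <- suppressWarnings(abc_reject(small_tab, obs, tolerance = 0.3))
  r2 <- suppressWarnings(abc_reject(tab2, obs2, tolerance = 0.3))
  expect_identical(r1$accepted, r2$accepted)

  # observed identical to a table row -> accepted first at distance 0
  expect_identical(r1$accepted[1], 3L)
  expect_equal(r1$distance[1], 0)
})

test_that("rejection matches a brute-force distance sort exactly", {
  obs <- unlist(small_tab[10, grep("^ss_", names(small_tab))])
  names(obs) <- sub("^ss_", "", names(obs))
  rej <- suppressWarnings(abc_reject(small_tab, obs, tolerance = 0.25))

  nz <- suppressWarnings(normalize_summaries(small_tab, obs))
  d_oracle <- sqrt(colSums((t(nz$table_scaled) - nz$observed_scaled)^2))
  ord <- order(d_oracle)
  n_keep <- ceiling(0.25 * nrow(small_tab))
  expect_identical(sort(rej$accepted), sort(ord[seq_len(n_keep)]))
  expect_equal(unname(rej$distance), unname(d_oracle[rej$accepted]))

  # tolerance 1 accepts everything
  r_all <- suppressWarnings(abc_reject(small_tab, obs, tolerance = 1))
  expect_identical(length(r_all$accepted), nrow(small_tab))
  # determinism
  rej2 <- suppressWarnings(abc_reject(small_tab, obs, tolerance = 0.25))
  expect_identical(rej$accepted, rej2$accepted)
  expect_error(abc_reject(small_tab[0, ], obs), "input error")
})

test_that("model posteriors sum to one and respect degenerate acceptance", {
  obs <- unlist(small_tab[1, grep("^ss_", names(small_tab))])
  names(obs) <- sub("^ss_", "", names(obs))
  rej <- suppressWarnings(abc_reject(small_tab, obs, tolerance = 0.5))
  mp <- model_posterior(rej)
  expect_equal(sum(mp$probabilities), 1)
  expect_equal(unname(mp$group_probabilities["4-6"]),
               sum(mp$probabilities[c("4", "5", "6")]))

  # all accepted rows from one scenario
  fake <- rej
  fake$scenario_id <- rep(4, length(fake$accepted))
  mp4 <- model_posterior(fake)
  expect_equal(unname(mp4$probabilities["4"]), 1)
  expect_equal(unname(mp4$group_probabilities["4-6"]), 1)
  expect_identical(mp4$top_scenario, 4)

  # equal weighted acceptance over scenarios -> uniform, BF = 1
  fake2 <- rej
  fake2$scenario_id <- rep(1:7, length.out = length(fake2$accepted))
  fake2$weight <- rep(1, length(fake2$weight))
  mp7 <- model_posterior(fake2)
  expect_true(all(abs(mp7$probabilities - 1 / 7) < 0.01))
})

test_that("parameter estimates follow order-statistics anchors", {
  # constant parameter collapses to a point
  tab <- data.frame(scenario_id = 4, par_x = rep(7, 40),
                    ss_a = rnorm(40), ss_b = rnorm(40))
  obs <- c(a = 0, b = 0)
  rej <- suppressWarnings(abc_reject(tab, obs, tolerance = 1))
  est <- estimate_parameters(rej, 4)
  expect_equal(est$median, 7)
  expect_equal(est$hpd_low, 7)
  expect_equal(est$hpd_high, 7)
  expect_true(est$degenerate)

  # uniform 1..100 with equal weights: median 50.5, HPD width ~ 95
  rej2 <- rej
  rej2$table <- data.frame(scenario_id = 4, par_x = 1:100,
                           ss_a = 0, ss_b = 0)
  rej2$accepted <- 1:100
  rej2$scenario_id <- rep(4, 100)
  rej2$weight <- rep(1, 100)
  est2 <- estimate_parameters(rej2, 4)
  expect_equal(est2$median, 50.5)
  expect_lt(abs((est2$hpd_high - est2$hpd_low) - 95), 2.5)

  # HPD is never wider than the equal-tailed interval
  set.seed(8)
  for (i in 1:20) {
    x <- rexp(200, 0.3)
    w <- runif(200)
    hpd <- coalabc:::weighted_hpd(x, w, 0.95)
    o <- order(x); cw <- cumsum(w[o] / sum(w))
    eq_lo <- x[o][which(cw >= 0.025)[1]]
    eq_hi <- x[o][which(cw >= 0.975)[1]]
    expect_lte(hpd[2] - hpd[1], eq_hi - eq_lo + 1e-9)
  }
})

test_that("with tolerance one the posterior reproduces the prior", {
  obs <- unlist(small_tab[20, grep("^ss_", names(small_tab))])
  names(obs) <- sub("^ss_", "", names(obs))
  rej <- suppressWarnings(abc_reject(small_tab, obs, tolerance = 1))
  est <- estimate_parameters(rej, 4)
  root <- "t_anc_GAL_PNG_TIJ_TIW_YAR"
  prior_med <- median(small_tab$par_t_anc_GAL_PNG_TIJ_TIW_YAR[
    small_tab$scenario_id == 4])
  got <- est$median[est$parameter == root]
  # Epanechnikov weighting keeps this approximate; wide MC tolerance
  expect_lt(abs(got - prior_med), 900)
})

test_that("recovery harness runs end to end and reports coverage", {
  expect_identical(recovery_experiment(scenario_catalog()[[4]],
                                       scenario4_calibration_params(),
                                       0, small_tab)$summary,
                   data.frame())
  rec <- recovery_experiment(scenario_catalog()[[4]],
                             scenario4_calibration_params(),
                             3, small_tab, sim_config = small_cfg,
                             seed = 3, tolerance = 0.3)
  expect_identical(nrow(rec$summary), 13L)
  expect_true(all(rec$summary$coverage >= 0 & rec$summary$coverage <= 1))
  expect_true(all(c("parameter", "truth", "bias", "median_rel_error",
                    "coverage") %in% names(rec$summary)))
})

test_that("random-forest scenario choice exposes the same interface", {
  skip_if_not_installed("ranger")
  rf <- abc_rf_train(small_tab, num_trees = 50, seed = 2)
  obs <- unlist(small_tab[8, grep("^ss_", names(small_tab))])
  names(obs) <- sub("^ss_", "", names(obs))
  mp <- abc_rf_posterior(rf, obs)
  expect_equal(sum(mp$probabilities), 1, tolerance = 1e-9)
  expect_true(mp$top_scenario %in% 1:7)
  expect_equal(unname(mp$group_probabilities["4-6"]),
               sum(mp$probabilities[c("4", "5", "6")]))
})
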