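#' Desk-scale simulation configuration for ABC
#'
#' Bundles the per-row simulation settings used when building reference
#' tables: diploid sample sizes, locus layout and the summary schema.
#' Defaults are the package's desk-scale study conditions: 12 diploids per
#' population (plus 12 outgroup) and 800 unlinked loci of 20 kb at
#' mu = 1.25e-8 — many short loci, because the across-locus genealogical
#' variance of the F statistics, not locus length, limits scenario
#' discrimination.
#'
#' @param samples named diploid counts.
#' @param locus a [locus_config()].
#' @param summary a [summary_config()].
#' @return an `abc_sim_config` list.
#' @export
abc_sim_config <- function(samples = default_sample_config(12, 12, 12, 12,
                                                           12, 12),
                           locus = locus_config(n_loci = 800,
                                                length_bp = 2e4),
                           summary = summary_config()) {
  structure(list(samples = samples, locus = locus, summary = summary),
            class = "abc_sim_config")
}

row_seed <- function(seed, scenario_id, row) {
  (seed %% 2^31) * 1e6 + scenario_id * 1e5 + row
}

#' Generate an ABC reference table
#'
#' For each scenario: draw parameters from the priors, simulate a dataset,
#' compute the summary vector. Rows are independent; row `r` of scenario `s`
#' is reproducible from `(seed, s, r)` alone. Failed simulations are
#' skipped and recorded in the `failures` attribute.
#'
#' @param catalog list of `scenario_spec` (see [scenario_catalog()]).
#' @param n_per_scenario rows per scenario.
#' @param sim_config an [abc_sim_config()].
#' @param seed integer seed.
#' @param progress print progress every 500 rows.
#' @return data.frame with `scenario_id`, parameter columns (`par_`
#'   prefix) and summary columns (`ss_` prefix); attributes `seed`,
#'   `sim_config`, `failures`.
#' @export
generate_reference_table <- function(catalog, n_per_scenario,
                                     sim_config = abc_sim_config(), seed = 1,
                                     progress = FALSE) {
  rows <- list()
  failures <- list()
  for (sc in catalog) {
    for (r in seq_len(n_per_scenario)) {
      rs <- row_seed(seed, sc$id, r)
      res <- tryCatch({
        set.seed(rs %% 2^31)
        params <- sample_prior(sc)
        model <- build_model(sc, params)
        ss <- simulate_summary_vector(model, sim_config$samples,
                                      sim_config$locus, seed = rs,
                                      config = sim_config$summary)
        c(scenario_id = sc$id,
          stats::setNames(params, paste0("par_", names(params))),
          stats::setNames(ss, paste0("ss_", names(ss))))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(scenario = sc$id, row = r, seed = rs,
               message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
      if (progress && (length(rows) %% 500 == 0)) {
        message("reference table: ", length(rows), " rows")
      }
    }
  }
  # parameter names differ across topologies: align columns by name
  all_names <- unique(unlist(lapply(rows, names)))
  mat <- matrix(NA_real_, length(rows), length(all_names),
                dimnames = list(NULL, all_names))
  for (i in seq_along(rows)) mat[i, names(rows[[i]])] <- rows[[i]]
  tab <- as.data.frame(mat)
  attr(tab, "seed") <- seed
  attr(tab, "sim_config") <- sim_config
  attr(tab, "failures") <- failures
  tab
}

#' Median/MAD normalization of summary dimensions
#'
#' Centers and scales every summary column by the reference-table median
#' and MAD (robust to the heavy-tailed F-moment summaries); the observed
#' vector is transformed with the same constants. Zero-MAD dimensions are
#' dropped with a warning.
#'
#' @param table reference table (or any data.frame with `ss_` columns).
#' @param observed named summary vector (names without the `ss_` prefix,
#'   as returned by [summary_vector()]).
#' @return list: `table_scaled` (matrix), `observed_scaled`, `center`,
#'   `scale`, `kept` (column names retained).
#' @export
normalize_summaries <- function(table, observed) {
  ss_cols <- grep("^ss_", names(table), value = TRUE)
  if (length(ss_cols) == 0) stop("input error: table has no ss_ columns")
  obs <- observed
  names(obs) <- paste0("ss_", names(observed))
  if (!all(ss_cols %in% names(obs))) {
    stop("input error: schema mismatch between table and observed vector")
  }
  X <- as.matrix(table[, ss_cols, drop = FALSE])
  X[!is.finite(X)] <- 0
  center <- apply(X, 2, median)
  scl <- apply(X, 2, mad)
  keep <- scl > 0
  if (any(!keep)) {
    warning("dropping zero-MAD summary dimension(s): ",
            paste(ss_cols[!keep], collapse = ", "))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
              scl[keep], "/")
  ov <- obs[ss_cols][keep]
  ov[!is.finite(ov)] <- 0
  os <- (ov - center[keep]) / scl[keep]
  list(table_scaled = Xs, observed_scaled = os, center = center[keep],
       scale = scl[keep], kept = ss_cols[keep])
}

#' Rejection-ABC acceptance step
#'
#' Euclidean distance in median/MAD-normalized summary space; the nearest
#' `ceiling(tolerance * nrow)` rows are accepted with Epanechnikov weights
#' `1 - (d/d_max)^2` (uniform if all accepted distances are equal).
#'
#' @param table reference table from [generate_reference_table()].
#' @param observed named summary vector of the observed dataset.
#' @param tolerance accepted fraction of rows, in `(0, 1]`.
#' @return an `abc_rejection`: `accepted` (row indices into `table`),
#'   `distance`, `weight`, `scenario_id`, plus the normalization record.
#' @export
abc_reject <- function(table, observed, tolerance = 0.05) {
  if (nrow(table) == 0) stop("input error: empty reference table")
  if (tolerance <= 0 || tolerance > 1) {
    stop("input error: tolerance must be in (0, 1]")
  }
  nz <- normalize_summaries(table, observed)
  d2 <- colSums((t(nz$table_scaled) - nz$observed_scaled)^2)
  d <- sqrt(d2)
  n_keep <- ceiling(tolerance * nrow(table))
  ord <- order(d)
  acc <- ord[seq_len(n_keep)]
  dmax <- d[acc[n_keep]]
  w <- if (dmax > 0) 1 - (d[acc] / dmax)^2 else rep(1, n_keep)
  if (all(w == 0)) w <- rep(1, n_keep)
  structure(list(accepted = acc, distance = d[acc], weight = w,
                 scenario_id = table$scenario_id[acc],
                 table = table, observed = observed,
                 normalization = nz[c("center", "scale", "kept")],
                 tolerance = tolerance),
            class = "abc_rejection")
}

#' Posterior scenario probabilities and Bayes factors
#'
#' Scenario probability = weighted fraction of accepted rows (equal scenario
#' priors); group probability = sum over members. Pairwise Bayes factors
#' are posterior-probability ratios (equal priors); group Bayes factors are
#' posterior-odds over prior-odds for the group against the rest.
#'
#' @param rejection an `abc_rejection`.
#' @param groups named list of scenario-id groups (default `{4,5,6}` and
#'   `{1,2}` against the rest).
#' @return list: `probabilities` (named by scenario id), `bf` (pairwise
#'   matrix; `Inf` marker where the denominator is zero),
#'   `group_probabilities`, `group_bf`, `top_scenario`.
#' @export
model_posterior <- function(rejection,
                            groups = list(`4-6` = c(4, 5, 6),
                                          `1-2` = c(1, 2))) {
  if (length(rejection$accepted) == 0) stop("input error: empty accepted set")
  ids <- sort(unique(rejection$table$scenario_id))
  w <- rejection$weight / sum(rejection$weight)
  p <- vapply(ids, function(i) sum(w[rejection$scenario_id == i]),
              numeric(1))
  names(p) <- as.character(ids)
  bf <- outer(p, p, function(a, b) ifelse(b > 0, a / b, Inf))
  n_sc <- length(ids)
  gp <- vapply(groups, function(g) sum(p[as.character(g)], na.rm = TRUE),
               numeric(1))
  gbf <- vapply(seq_along(groups), function(k) {
    prior <- length(groups[[k]]) / n_sc
    post <- gp[k]
    if (post >= 1) return(Inf)
    (post / (1 - post)) / (prior / (1 - prior))
  }, numeric(1))
  names(gbf) <- names(groups)
  list(probabilities = p, bf = bf, group_probabilities = gp,
       group_bf = gbf, top_scenario = ids[which.max(p)])
}

#' Train a random-forest scenario classifier on a reference table
#'
#' The ABC-random-forest variant of scenario choice: a probability forest
#' trained on the table's summary columns, used in place of the rejection
#' kernel when scenario discrimination, not parameter estimation, is the
#' goal. Non-finite summaries are recoded to zero, consistently at training
#' and prediction time.
#'
#' @param table reference table from [generate_reference_table()].
#' @param num_trees number of trees (default 500).
#' @param seed forest seed.
#' @return a trained `ranger` probability forest (carries the summary
#'   schema in attribute `ss_cols`).
#' @export
abc_rf_train <- function(table, num_trees = 500, seed = 1) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("the random-forest scenario classifier requires the ranger package")
  }
  ss_cols <- grep("^ss_", names(table), value = TRUE)
  X <- as.matrix(table[, ss_cols, drop = FALSE])
  X[!is.finite(X)] <- 0
  fit <- ranger::ranger(
    y ~ ., data = data.frame(y = factor(table$scenario_id), X),
    num.trees = num_trees, probability = TRUE, seed = seed,
    num.threads = 1)
  attr(fit, "ss_cols") <- ss_cols
  fit
}

#' Scenario posterior from a trained random forest
#'
#' @param forest forest from [abc_rf_train()].
#' @param observed named summary vector (names without the `ss_` prefix).
#' @param groups scenario groups as in [model_posterior()].
#' @return list with `probabilities`, `bf`, `group_probabilities`,
#'   `group_bf` and `top_scenario`, matching [model_posterior()].
#' @export
abc_rf_posterior <- function(forest, observed,
                             groups = list(`4-6` = c(4, 5, 6),
                                           `1-2` = c(1, 2))) {
  obs <- observed
  obs[!is.finite(obs)] <- 0
  nd <- as.data.frame(t(obs))
  names(nd) <- paste0("ss_", names(observed))
  nd <- nd[, attr(forest, "ss_cols"), drop = FALSE]
  p <- drop(stats::predict(forest, nd, num.threads = 1)$predictions)
  ids <- as.integer(names(p))
  bf <- outer(p, p, function(a, b) ifelse(b > 0, a / b, Inf))
  n_sc <- length(ids)
  gp <- vapply(groups, function(g) sum(p[as.character(g)], na.rm = TRUE),
               numeric(1))
  gbf <- vapply(seq_along(groups), function(k) {
    prior <- length(groups[[k]]) / n_sc
    post <- gp[k]
    if (post >= 1) return(Inf)
    (post / (1 - post)) / (prior / (1 - prior))
  }, numeric(1))
  names(gbf) <- names(groups)
  list(probabilities = p, bf = bf, group_probabilities = gp,
       group_bf = gbf, top_scenario = ids[which.max(p)])
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2
  else x[i]
}

# shortest interval holding >= level of the weighted mass (grid over draws)
weighted_hpd <- function(x, w, level = 0.95) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  n <- length(x)
  cw <- c(0, cumsum(w))
  best <- c(x[1], x[n])
  best_width <- Inf
  j <- 1
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && cw[j + 1] - cw[i] < level) j <- j + 1
    if (j > n) break
    width <- x[j] - x[i]
    if (width < best_width) {
      best_width <- width
      best <- c(x[i], x[j])
    }
  }
  best
}

#' Posterior parameter estimates with 95% HPD intervals
#'
#' Weighted posterior sample from the accepted rows of one scenario;
#' reports the weighted median and the shortest interval containing the
#' target mass (highest posterior density, computed on the sorted draws).
#' Optional local-linear regression adjustment regresses each parameter on
#' the normalized summaries among accepted rows and shifts draws to the
#' observed summary position.
#'
#' @param rejection an `abc_rejection`.
#' @param scenario_id scenario whose accepted rows to use (default: the
#'   scenario with most accepted weight).
#' @param adjust apply regression adjustment (default off).
#' @param level HPD mass (default 0.95).
#' @return data.frame: `parameter`, `median`, `hpd_low`, `hpd_high`,
#'   `degenerate` (TRUE when all draws coincide and the interval collapses
#'   to a point).
#' @export
estimate_parameters <- function(rejection, scenario_id = NULL,
                                adjust = FALSE, level = 0.95) {
  if (is.null(scenario_id)) {
    scenario_id <- model_posterior(rejection)$top_scenario
  }
  sel <- rejection$scenario_id == scenario_id
  if (!any(sel)) stop("input error: no accepted rows for scenario ", scenario_id)
  rows <- rejection$table[rejection$accepted[sel], , drop = FALSE]
  w <- rejection$weight[sel]
  par_cols <- grep("^par_", names(rows), value = TRUE)
  par_cols <- par_cols[colSums(!is.na(rows[par_cols])) > 0]
  adj_mat <- NULL
  if (adjust) {
    nz <- rejection$normalization
    X <- as.matrix(rows[, nz$kept, drop = FALSE])
    X[!is.finite(X)] <- 0
    Xs <- sweep(sweep(X, 2, nz$center), 2, nz$scale, "/")
    obs <- rejection$observed
    names(obs) <- paste0("ss_", names(rejection$observed))
    os <- (obs[nz$kept] - nz$center) / nz$scale
    adj_mat <- sweep(Xs, 2, os)  # summary deviation from observed
  }
  out <- do.call(rbind, lapply(par_cols, function(pc) {
    x <- rows[[pc]]
    if (adjust && nrow(rows) > ncol(adj_mat) + 2) {
      fit <- stats::lm.wfit(cbind(1, adj_mat), x, w)
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      x <- x - as.numeric(adj_mat %*% beta)
    }
    hpd <- weighted_hpd(x, w, level)
    data.frame(parameter = sub("^par_", "", pc),
               median = weighted_median(x, w),
               hpd_low = hpd[1], hpd_high = hpd[2],
               degenerate = hpd[1] == hpd[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Parameter-recovery and coverage harness
#'
#' Repeatedly simulates pseudo-observed datasets at known parameter values,
#' runs the rejection step against a reference table, estimates parameters,
#' and reports per-parameter bias, median relative error and 95%-HPD
#' coverage of the truth.
#'
#' @param scenario a `scenario_spec`.
#' @param true_params named parameter map (truth for every trial).
#' @param n_trials number of pseudo-observed trials.
#' @param table reference table (must not contain the pseudo-observed
#'   draws; generated with a different seed).
#' @param sim_config the [abc_sim_config()] used for the table.
#' @param seed trial seed (distinct stream from the table's).
#' @param tolerance rejection tolerance.
#' @param adjust regression adjustment flag for [estimate_parameters()].
#' @return list: `summary` data.frame (parameter, truth, bias,
#'   median_rel_error, coverage), `trials` (per-trial estimates).
#' @export
recovery_experiment <- function(scenario, true_params, n_trials, table,
                                sim_config = abc_sim_config(), seed = 1,
                                tolerance = 0.05, adjust = FALSE) {
  if (n_trials == 0) {
    return(list(summary = data.frame(), trials = list()))
  }
  model <- build_model(scenario, true_params)
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    ss <- simulate_summary_vector(model, sim_config$samples,
                                  sim_config$locus,
                                  seed = row_seed(seed, 99, tr),
                                  config = sim_config$summary)
    rej <- suppressWarnings(abc_reject(table, ss, tolerance))
    est <- estimate_parameters(rej, scenario_id = scenario$id,
                               adjust = adjust)
    est$trial <- tr
    trials[[tr]] <- est
  }
  all_est <- do.call(rbind, trials)
  pars <- intersect(unique(all_est$parameter), names(true_params))
  summary_df <- do.call(rbind, lapply(pars, function(p) {
    e <- all_est[all_est$parameter == p, ]
    truth <- true_params[[p]]
    data.frame(parameter = p, truth = truth,
               bias = mean(e$median) - truth,
               median_rel_error = median(abs(e$median - truth) /
                                           max(abs(truth), .Machine$double.eps)),
               coverage = mean(e$hpd_low <= truth & truth <= e$hpd_high),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary_df, trials = trials)
}
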