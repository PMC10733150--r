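#' @useDynLib coalabc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rexp median mad quantile ks.test lm predict rbinom
#' @importFrom utils combn head
NULL

#' Study population labels
#'
#' Five sampled populations: four Indigenous Australian communities (Tiwi
#' Islands, Galiwin'ku, Titjikala, Yarrabah) and Highland Papua New Guinea,
#' plus an optional deep outgroup (Yoruba-like African reference).
#'
#' @param include_outgroup add the `OUT` outgroup population.
#' @return data.frame with columns `name`, `continent`.
#' @export
study_populations <- function(include_outgroup = TRUE) {
  pops <- data.frame(
    name = c("TIW", "GAL", "TIJ", "YAR", "PNG"),
    continent = c("Australia", "Australia", "Australia", "Australia",
                  "Oceania-PNG"),
    stringsAsFactors = FALSE
  )
  if (include_outgroup) {
    pops <- rbind(pops, data.frame(name = "OUT", continent = "Outgroup"))
  }
  pops
}

anc_name <- function(tips) paste0("anc_", paste(sort(tips), collapse = "_"))

#' Parse a rooted topology string
#'
#' Newick-like rooted notation without branch lengths, e.g.
#' `"(PNG,(TIW,(GAL,(TIJ,YAR))))"`. Internal nodes are named after the sorted
#' leaf set they subtend (`anc_GAL_TIJ_YAR`, ...).
#'
#' @param topology topology string.
#' @return data.frame of splits with columns `node` (ancestor name),
#'   `child_a`, `child_b` (population or ancestor names), ordered root first.
#' @export
.topology_cache <- new.env(parent = emptyenv())

parse_topology <- function(topology) {
  hit <- .topology_cache[[topology]]
  if (!is.null(hit)) return(hit)
  tr <- tryCatch(ape::read.tree(text = paste0(topology, ";")),
                 error = function(e) NULL)
  if (is.null(tr) || is.null(tr$edge)) {
    stop("topology error: cannot parse topology string: ", topology)
  }
  n_tip <- length(tr$tip.label)
  if (tr$Nnode != n_tip - 1L) {
    stop("topology error: topology is not a rooted binary tree: ", topology)
  }
  # leaf set under every node
  node_tips <- function(node) {
    if (node <= n_tip) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, node_tips))
  }
  node_label <- function(node) {
    if (node <= n_tip) tr$tip.label[node] else anc_name(node_tips(node))
  }
  internal <- (n_tip + 1L):(n_tip + tr$Nnode)
  splits <- do.call(rbind, lapply(internal, function(v) {
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    if (length(kids) != 2L) {
      stop("topology error: node with ", length(kids),
           " children (binary tree required)")
    }
    data.frame(node = node_label(v),
               child_a = node_label(kids[1]), child_b = node_label(kids[2]),
               n_tips = length(node_tips(v)), stringsAsFactors = FALSE)
  }))
  splits <- splits[order(-splits$n_tips), ]
  rownames(splits) <- NULL
  out <- splits[, c("node", "child_a", "child_b")]
  .topology_cache[[topology]] <- out
  out
}

#' Default prior specification for one parameter
#'
#' @param parameter parameter name.
#' @param distribution `"uniform"` or `"log-uniform"`.
#' @param low,high bounds in the parameter's units; `log-uniform` requires
#'   `low > 0`.
#' @param parent optional name of another parameter whose drawn value replaces
#'   `high` (nested split-time sampling: a child split is drawn uniformly on
#'   `[0, parent split time]`, so topologies are valid by construction).
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(parameter, distribution = c("uniform", "log-uniform"),
                       low, high, parent = NA_character_) {
  distribution <- match.arg(distribution)
  if (!is.na(high) && low >= high) {
    stop("configuration error: prior for ", parameter, " needs low < high")
  }
  if (distribution == "log-uniform" && low <= 0) {
    stop("configuration error: log-uniform prior for ", parameter,
         " needs low > 0")
  }
  structure(list(parameter = parameter, distribution = distribution,
                 low = low, high = high, parent = parent),
            class = "prior_spec")
}

# scenarios 4-6 (Tiwi outgroup) and 1-2 ((TIW,GAL) clade) are anchored;
# 3 and 7 default to the remaining balanced shapes, chosen so that no
# sister pair is repeated across more than two candidate histories —
# candidate hypotheses should be as mutually distinguishable as possible
default_topologies <- function() {
  c(`1` = "(PNG,((TIW,GAL),(TIJ,YAR)))",
    `2` = "(PNG,(TIJ,(YAR,(TIW,GAL))))",
    `3` = "(PNG,((TIW,TIJ),(GAL,YAR)))",
    `4` = "(PNG,(TIW,(GAL,(TIJ,YAR))))",
    `5` = "(PNG,(TIW,(TIJ,(GAL,YAR))))",
    `6` = "(PNG,(TIW,(YAR,(GAL,TIJ))))",
    `7` = "(PNG,((TIW,YAR),(GAL,TIJ)))")
}

#' Catalog of the seven candidate population histories
#'
#' Builds the seven scenario specifications over \{TIW, GAL, TIJ, YAR\} with
#' PNG as the outermost sampled population. Scenarios 4-6 place Tiwi as the
#' outgroup to the other Australian groups; scenarios 1-2 contain a
#' (TIW,GAL) clade; 3 and 7 cover the remaining distinct rooted shapes.
#' Free parameters per scenario: four split times (root uniform, children
#' nested uniform below their parent) and one effective size per extant and
#' ancestral population (log-uniform). PNG-to-Australia migration bands and
#' the recent Yarrabah admixture pulse can be switched on.
#'
#' @param config optional list of overrides: `topologies` (named character
#'   vector by scenario id), `t_root_range` (default `c(800, 3000)` gen),
#'   `ne_range` (default `c(500, 30000)`), `migration` (logical, add
#'   PNG->Australia migration-rate priors, default `FALSE`),
#'   `migration_rate_range` (default `c(1e-6, 1e-3)`), `yarrabah_pulse`
#'   (logical, add pulse proportion/time priors, default `FALSE`),
#'   `include_outgroup` (default `TRUE`), `generation_time_years`
#'   (default 28.7).
#' @return list of 7 `scenario_spec` objects.
#' @export
scenario_catalog <- function(config = list()) {
  topo <- default_topologies()
  if (!is.null(config$topologies)) {
    ids <- names(config$topologies)
    if (anyDuplicated(ids) > 0L) {
      stop("configuration error: duplicate scenario ids in topology override")
    }
    topo[ids] <- config$topologies
  }
  if (anyDuplicated(names(topo)) > 0L) {
    stop("configuration error: duplicate scenario ids")
  }
  t_root_range <- config$t_root_range %||% c(800, 3000)
  ne_range <- config$ne_range %||% c(500, 30000)
  gy <- config$generation_time_years %||% 28.7
  include_outgroup <- config$include_outgroup %||% TRUE
  lapply(names(topo), function(id) {
    splits <- parse_topology(topo[[id]])
    priors <- list()
    # split times, root first so nested draws see their parent
    for (i in seq_len(nrow(splits))) {
      node <- splits$node[i]
      par_row <- which(splits$child_a == node | splits$child_b == node)
      if (length(par_row) == 0L) {
        priors[[length(priors) + 1L]] <-
          prior_spec(paste0("t_", node), "uniform",
                     t_root_range[1], t_root_range[2])
      } else {
        priors[[length(priors) + 1L]] <-
          prior_spec(paste0("t_", node), "uniform", 0, NA,
                     parent = paste0("t_", splits$node[par_row]))
      }
    }
    leaves <- c("TIW", "GAL", "TIJ", "YAR", "PNG")
    for (p in c(leaves, splits$node)) {
      priors[[length(priors) + 1L]] <-
        prior_spec(paste0("ne_", p), "log-uniform", ne_range[1], ne_range[2])
    }
    if (isTRUE(config$migration)) {
      mr <- config$migration_rate_range %||% c(1e-6, 1e-3)
      for (p in c("TIW", "GAL", "TIJ", "YAR")) {
        priors[[length(priors) + 1L]] <-
          prior_spec(paste0("m_png_", tolower(p)), "log-uniform",
                     mr[1], mr[2])
      }
    }
    if (isTRUE(config$yarrabah_pulse)) {
      priors[[length(priors) + 1L]] <-
        prior_spec("pulse_yar_prop", "uniform", 0, 0.1)
      priors[[length(priors) + 1L]] <-
        prior_spec("pulse_yar_time", "uniform", 3, 7)
    }
    structure(list(id = as.integer(id), topology = topo[[id]],
                   priors = priors,
                   fixed = list(generation_time_years = gy,
                                include_outgroup = include_outgroup,
                                t_out = 3500, ne_out = 15000,
                                ne_anc_root = 10000)),
              class = "scenario_spec")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw one parameter map from a scenario's priors
#'
#' Parameters are drawn independently from their prior specifications, in
#' listed order; nested split-time priors use the already-drawn parent value
#' as their upper bound, so every draw respects the topology ordering.
#'
#' @param scenario a `scenario_spec`.
#' @param seed optional integer seed (deterministic draw if given).
#' @return named numeric vector of parameter values.
#' @export
sample_prior <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  for (pr in scenario$priors) {
    high <- pr$high
    if (!is.na(pr$parent)) {
      if (!pr$parent %in% names(out)) {
        stop("configuration error: nested prior for ", pr$parameter,
             " references undrawn parameter ", pr$parent)
      }
      high <- out[[pr$parent]]
    }
    val <- if (pr$distribution == "uniform") {
      if (pr$low == high) pr$low else runif(1, pr$low, high)
    } else {
      exp(runif(1, log(pr$low), log(high)))
    }
    out[pr$parameter] <- val
  }
  out
}

#' Build a demographic model from a scenario and a parameter map
#'
#' Converts a scenario topology plus drawn (or fixed) parameter values into a
#' concrete rooted population history: one constant-size epoch per extant and
#' ancestral population spanning its existence interval, split events per
#' internal node, optional PNG-to-Australia migration bands and the Yarrabah
#' admixture pulse. When the scenario includes the outgroup, an `OUT`
#' population splits from the study root at the fixed outgroup time.
#'
#' @param scenario a `scenario_spec`.
#' @param params named numeric vector covering every free parameter.
#' @return a validated `demographic_model`.
#' @export
build_model <- function(scenario, params) {
  splits <- parse_topology(scenario$topology)
  need_t <- paste0("t_", splits$node)
  leaves <- setdiff(unique(c(splits$child_a, splits$child_b)), splits$node)
  need_n <- paste0("ne_", c(leaves, splits$node))
  missing <- setdiff(c(need_t, need_n), names(params))
  if (length(missing) > 0L) {
    stop("configuration error: missing parameter(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(params[need_t] < 0) || any(params[need_n] <= 0)) {
    stop("configuration error: split times must be >= 0 and sizes > 0")
  }
  # nesting check: each child split younger than its parent's
  for (i in seq_len(nrow(splits))) {
    for (ch in c(splits$child_a[i], splits$child_b[i])) {
      if (ch %in% splits$node &&
          params[[paste0("t_", ch)]] > params[[paste0("t_", splits$node[i])]]) {
        stop("topology error: split of ", ch,
             " is older than its parent ", splits$node[i])
      }
    }
  }
  include_outgroup <- isTRUE(scenario$fixed$include_outgroup)
  pops <- study_populations(include_outgroup)
  anc <- data.frame(name = splits$node, continent = "ancestral",
                    stringsAsFactors = FALSE)
  root_node <- splits$node[1]
  split_df <- data.frame(
    time_gen = unname(params[need_t]),
    child_a = splits$child_a, child_b = splits$child_b,
    parent = splits$node, stringsAsFactors = FALSE)

  # existence window of each population
  end_of <- function(name) {
    i <- which(split_df$child_a == name | split_df$child_b == name)
    if (length(i) == 0L) Inf else split_df$time_gen[i]
  }
  start_of <- function(name) {
    i <- which(split_df$parent == name)
    if (length(i) == 0L) 0 else split_df$time_gen[i]
  }
  sizes <- do.call(rbind, lapply(c(leaves, splits$node), function(p) {
    data.frame(population = p, start_gen = start_of(p), end_gen = end_of(p),
               ne = unname(params[[paste0("ne_", p)]]),
               stringsAsFactors = FALSE)
  }))

  if (include_outgroup) {
    t_out <- scenario$fixed$t_out %||% 3500
    if (t_out <= params[[paste0("t_", root_node)]]) {
      stop("topology error: outgroup split must be older than the study root")
    }
    anc <- rbind(anc, data.frame(name = "anc_root", continent = "ancestral"))
    split_df <- rbind(
      data.frame(time_gen = t_out, child_a = "OUT", child_b = root_node,
                 parent = "anc_root", stringsAsFactors = FALSE),
      split_df)
    sizes$end_gen[sizes$population == root_node] <- t_out
    sizes <- rbind(sizes, data.frame(
      population = c("OUT", "anc_root"), start_gen = c(0, t_out),
      end_gen = c(t_out, Inf),
      ne = c(scenario$fixed$ne_out %||% 15000,
             scenario$fixed$ne_anc_root %||% 10000)))
  }

  migrations <- data.frame(source = character(0), dest = character(0),
                           rate = numeric(0), start_gen = numeric(0),
                           end_gen = numeric(0), stringsAsFactors = FALSE)
  for (p in c("TIW", "GAL", "TIJ", "YAR")) {
    key <- paste0("m_png_", tolower(p))
    if (key %in% names(params) && params[[key]] > 0) {
      migrations <- rbind(migrations, data.frame(
        source = "PNG", dest = p, rate = unname(params[[key]]),
        start_gen = 0, end_gen = end_of(p), stringsAsFactors = FALSE))
    }
  }
  pulses <- data.frame(time_gen = numeric(0), from_pop = character(0),
                       into_pop = character(0), proportion = numeric(0),
                       stringsAsFactors = FALSE)
  if ("pulse_yar_prop" %in% names(params) && params[["pulse_yar_prop"]] > 0) {
    pulses <- rbind(pulses, data.frame(
      time_gen = unname(params[["pulse_yar_time"]] %||% 5),
      from_pop = "PNG", into_pop = "YAR",
      proportion = unname(params[["pulse_yar_prop"]]),
      stringsAsFactors = FALSE))
  }

  model <- structure(list(
    populations = rbind(pops, anc),
    splits = split_df, sizes = sizes,
    migrations = migrations, pulses = pulses,
    generation_time_years =
      scenario$fixed$generation_time_years %||% 28.7),
    class = "demographic_model")
  problems <- validate_model(model)
  if (length(problems) > 0L) {
    stop("invalid model: ", paste(problems, collapse = "; "))
  }
  model
}

#' Validate a demographic model
#'
#' Reporting operation: checks every structural invariant (unique population
#' names, a single rooted binary split tree, epochs that tile each
#' population's existence without gaps or overlap, positive sizes, migration
#' windows inside both populations' lifetimes, pulse proportions in `[0,1]`)
#' and returns the list of violations.
#'
#' @param model a `demographic_model`.
#' @return character vector of violations; empty iff the model is valid.
#' @export
validate_model <- function(model) {
  bad <- character(0)
  pops <- model$populations$name
  if (anyDuplicated(pops) > 0L) bad <- c(bad, "population names not unique")

  sp <- model$splits
  children <- c(sp$child_a, sp$child_b)
  if (anyDuplicated(children) > 0L) {
    bad <- c(bad, "a population has more than one parent split")
  }
  if (nrow(sp) == 0L) {
    if (length(unique(model$sizes$population)) != 1L) {
      bad <- c(bad, "multiple populations but no splits (no single root)")
    }
  } else {
    roots <- setdiff(sp$parent, children)
    if (length(unique(roots)) != 1L) {
      bad <- c(bad, sprintf("expected exactly one root population, found %d",
                            length(unique(roots))))
    }
  }
  if (any(sp$time_gen <= 0)) bad <- c(bad, "split time must be > 0")
  for (i in seq_len(nrow(sp))) {
    for (ch in c(sp$child_a[i], sp$child_b[i])) {
      j <- which(sp$parent == ch)
      if (length(j) == 1L && sp$time_gen[j] > sp$time_gen[i]) {
        bad <- c(bad, sprintf("split of %s older than its parent %s",
                              ch, sp$parent[i]))
      }
    }
  }

  # epoch tiling per population over its existence window
  exist_start <- function(p) {
    j <- which(sp$parent == p); if (length(j) == 0L) 0 else sp$time_gen[j]
  }
  exist_end <- function(p) {
    j <- which(sp$child_a == p | sp$child_b == p)
    if (length(j) == 0L) Inf else sp$time_gen[j]
  }
  for (p in unique(model$sizes$population)) {
    ep <- model$sizes[model$sizes$population == p, , drop = FALSE]
    ep <- ep[order(ep$start_gen), , drop = FALSE]
    if (any(ep$ne <= 0)) bad <- c(bad, sprintf("ne <= 0 for %s", p))
    if (any(ep$start_gen >= ep$end_gen)) {
      bad <- c(bad, sprintf("epoch with start >= end for %s", p))
    }
    lo <- exist_start(p); hi <- exist_end(p)
    if (abs(ep$start_gen[1] - lo) > 1e-9 ||
        (is.finite(hi) && abs(ep$end_gen[nrow(ep)] - hi) > 1e-9) ||
        (!is.finite(hi) && is.finite(ep$end_gen[nrow(ep)]))) {
      bad <- c(bad, sprintf("epochs do not tile time for %s", p))
    } else if (nrow(ep) > 1L &&
               any(abs(ep$end_gen[-nrow(ep)] - ep$start_gen[-1]) > 1e-9)) {
      bad <- c(bad, sprintf("epochs do not tile time for %s", p))
    }
  }
  for (p in setdiff(pops, model$sizes$population)) {
    bad <- c(bad, sprintf("no epoch sizes for %s", p))
  }

  mg <- model$migrations
  for (i in seq_len(nrow(mg))) {
    if (mg$rate[i] < 0 || mg$rate[i] >= 1) {
      bad <- c(bad, "migration rate outside [0, 1)")
    }
    for (p in c(mg$source[i], mg$dest[i])) {
      if (mg$start_gen[i] < exist_start(p) - 1e-9 ||
          mg$end_gen[i] > exist_end(p) + 1e-9) {
        bad <- c(bad, sprintf("migration window outside lifetime of %s", p))
      }
    }
  }
  pu <- model$pulses
  for (i in seq_len(nrow(pu))) {
    if (pu$proportion[i] < 0 || pu$proportion[i] > 1) {
      bad <- c(bad, "pulse proportion outside [0,1]")
    }
    for (p in c(pu$from_pop[i], pu$into_pop[i])) {
      if (pu$time_gen[i] < exist_start(p) - 1e-9 ||
          pu$time_gen[i] > exist_end(p) + 1e-9) {
        bad <- c(bad, sprintf("pulse outside lifetime of %s", p))
      }
    }
  }
  bad
}

#' Convert generations before present to years
#'
#' @param t_gen time in generations, `>= 0`.
#' @param generation_time_years years per generation (default 28.7).
#' @param digits optional rounding.
#' @return time in years.
#' @export
gens_to_years <- function(t_gen, generation_time_years = 28.7, digits = NULL) {
  if (any(t_gen < 0)) stop("domain error: negative time")
  y <- t_gen * generation_time_years
  if (!is.null(digits)) y <- round(y, digits)
  y
}

#' Paper-calibration parameter map for scenario 4
#'
#' The point calibration of the best-supported history: AU-PNG split 1,636
#' generations ago, Tiwi split 1,207, Galiwin'ku 1,069, Titjikala-Yarrabah
#' 897 (35/31/26 ka at 29 y/gen); ancestral Australian N_e 2,000.
#'
#' @return named numeric vector usable with [build_model()] and scenario 4.
#' @export
scenario4_calibration_params <- function() {
  c(t_anc_GAL_PNG_TIJ_TIW_YAR = 1636,
    t_anc_GAL_TIJ_TIW_YAR = 1207,
    t_anc_GAL_TIJ_YAR = 1069,
    t_anc_TIJ_YAR = 897,
    ne_TIW = 7000, ne_GAL = 10000, ne_TIJ = 3000, ne_YAR = 10000,
    ne_PNG = 6000,
    ne_anc_TIJ_YAR = 2000, ne_anc_GAL_TIJ_YAR = 2000,
    ne_anc_GAL_TIJ_TIW_YAR = 2000, ne_anc_GAL_PNG_TIJ_TIW_YAR = 3000)
}

#' Calibrated scenario-4 demographic model
#'
#' The package's reference history for the five study populations plus
#' outgroup: scenario-4 topology (Tiwi as Australian outgroup) with the
#' calibration of [scenario4_calibration_params()], refined with
#' piecewise sizes (recent reductions to N_e 1,500 for Tiwi and 2,000 for
#' Galiwin'ku starting 209 generations ago, i.e. the last ~6,000 years),
#' PNG-to-northern-Australia migration bands (rate 3e-4/generation into Tiwi
#' and Galiwin'ku over their lifetimes, encoding the extended genetic
#' interaction between PNG and northern Australia as an excess of shared
#' drift resolvable at the package's locus counts), and, optionally, the
#' recent 1.8% PNG pulse into Yarrabah.
#'
#' @param migration include the PNG->TIW / PNG->GAL migration bands.
#' @param yarrabah_pulse include the 1.8% PNG pulse into Yarrabah
#'   (time in generations, default 5, inside the reported 3-7 window).
#' @param pulse_time_gen pulse time in generations.
#' @param include_outgroup include the `OUT` outgroup.
#' @return a validated `demographic_model`.
#' @export
scenario4_calibrated <- function(migration = TRUE, yarrabah_pulse = TRUE,
                                 pulse_time_gen = 5,
                                 include_outgroup = TRUE) {
  pops <- study_populations(include_outgroup)
  anc <- data.frame(
    name = c("anc_TIJ_YAR", "anc_GAL_TIJ_YAR", "anc_GAL_TIJ_TIW_YAR",
             "anc_GAL_PNG_TIJ_TIW_YAR"),
    continent = "ancestral", stringsAsFactors = FALSE)
  splits <- data.frame(
    time_gen = c(897, 1069, 1207, 1636),
    child_a = c("TIJ", "GAL", "TIW", "PNG"),
    child_b = c("YAR", "anc_TIJ_YAR", "anc_GAL_TIJ_YAR",
                "anc_GAL_TIJ_TIW_YAR"),
    parent = c("anc_TIJ_YAR", "anc_GAL_TIJ_YAR", "anc_GAL_TIJ_TIW_YAR",
               "anc_GAL_PNG_TIJ_TIW_YAR"),
    stringsAsFactors = FALSE)
  t_red <- 209  # onset of recent size reduction, ~6 ky at 28.7 y/gen
  sizes <- data.frame(
    population = c("TIW", "TIW", "GAL", "GAL", "TIJ", "YAR", "PNG",
                   "anc_TIJ_YAR", "anc_GAL_TIJ_YAR", "anc_GAL_TIJ_TIW_YAR",
                   "anc_GAL_PNG_TIJ_TIW_YAR"),
    start_gen = c(0, t_red, 0, t_red, 0, 0, 0, 897, 1069, 1207, 1636),
    end_gen = c(t_red, 1207, t_red, 1069, 897, 897, 1636,
                1069, 1207, 1636, Inf),
    ne = c(1500, 7000, 2000, 10000, 3000, 10000, 6000,
           2000, 2000, 2000, 3000),
    stringsAsFactors = FALSE)
  if (include_outgroup) {
    anc <- rbind(anc, data.frame(name = "anc_root", continent = "ancestral"))
    splits <- rbind(splits, data.frame(
      time_gen = 3500, child_a = "OUT", child_b = "anc_GAL_PNG_TIJ_TIW_YAR",
      parent = "anc_root", stringsAsFactors = FALSE))
    sizes$end_gen[sizes$population == "anc_GAL_PNG_TIJ_TIW_YAR"] <- 3500
    sizes <- rbind(sizes, data.frame(
      population = c("OUT", "anc_root"), start_gen = c(0, 3500),
      end_gen = c(3500, Inf), ne = c(15000, 10000)))
  }
  migrations <- data.frame(source = character(0), dest = character(0),
                           rate = numeric(0), start_gen = numeric(0),
                           end_gen = numeric(0), stringsAsFactors = FALSE)
  if (migration) {
    migrations <- data.frame(
      source = c("PNG", "PNG"), dest = c("TIW", "GAL"), rate = 3e-4,
      start_gen = 0, end_gen = c(1207, 1069), stringsAsFactors = FALSE)
  }
  pulses <- data.frame(time_gen = numeric(0), from_pop = character(0),
                       into_pop = character(0), proportion = numeric(0),
                       stringsAsFactors = FALSE)
  if (yarrabah_pulse) {
    pulses <- data.frame(time_gen = pulse_time_gen, from_pop = "PNG",
                         into_pop = "YAR", proportion = 0.018,
                         stringsAsFactors = FALSE)
  }
  model <- structure(list(populations = rbind(pops, anc), splits = splits,
                          sizes = sizes, migrations = migrations,
                          pulses = pulses, generation_time_years = 28.7),
                     class = "demographic_model")
  problems <- validate_model(model)
  if (length(problems) > 0L) {
    stop("invalid calibrated model: ", paste(problems, collapse = "; "))
  }
  model
}

#' Minimal single- or multi-population model helper
#'
#' Convenience constructor used throughout tests and calibration
#' experiments: either one panmictic population of constant size, or two
#' populations of equal constant size splitting at `split_gen`, with an
#' optional symmetric-window migration band between them.
#'
#' @param ne diploid effective size.
#' @param split_gen optional split time (two populations `A`, `B`).
#' @param migration_rate optional backward migration rate `B -> A` applied on
#'   `[0, split_gen)` for lineages in `B` (and `A -> B` if `symmetric`).
#' @param symmetric make the band symmetric.
#' @return a `demographic_model`.
#' @export
simple_model <- function(ne = 1000, split_gen = NULL, migration_rate = 0,
                         symmetric = TRUE) {
  if (is.null(split_gen)) {
    model <- structure(list(
      populations = data.frame(name = "A", continent = "x"),
      splits = data.frame(time_gen = numeric(0), child_a = character(0),
                          child_b = character(0), parent = character(0)),
      sizes = data.frame(population = "A", start_gen = 0, end_gen = Inf,
                         ne = ne),
      migrations = data.frame(source = character(0), dest = character(0),
                              rate = numeric(0), start_gen = numeric(0),
                              end_gen = numeric(0)),
      pulses = data.frame(time_gen = numeric(0), from_pop = character(0),
                          into_pop = character(0), proportion = numeric(0)),
      generation_time_years = 28.7), class = "demographic_model")
    return(model)
  }
  migrations <- data.frame(source = character(0), dest = character(0),
                           rate = numeric(0), start_gen = numeric(0),
                           end_gen = numeric(0), stringsAsFactors = FALSE)
  if (migration_rate > 0) {
    migrations <- data.frame(source = "A", dest = "B", rate = migration_rate,
                             start_gen = 0, end_gen = split_gen,
                             stringsAsFactors = FALSE)
    if (symmetric) {
      migrations <- rbind(migrations, data.frame(
        source = "B", dest = "A", rate = migration_rate,
        start_gen = 0, end_gen = split_gen))
    }
  }
  structure(list(
    populations = data.frame(name = c("A", "B", "AB"),
                             continent = c("x", "y", "ancestral")),
    splits = data.frame(time_gen = split_gen, child_a = "A", child_b = "B",
                        parent = "AB", stringsAsFactors = FALSE),
    sizes = data.frame(population = c("A", "B", "AB"),
                       start_gen = c(0, 0, split_gen),
                       end_gen = c(split_gen, split_gen, Inf), ne = ne),
    migrations = migrations,
    pulses = data.frame(time_gen = numeric(0), from_pop = character(0),
                        into_pop = character(0), proportion = numeric(0)),
    generation_time_years = 28.7), class = "demographic_model")
}
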