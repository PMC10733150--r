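#' Default rCCR time bins
#'
#' 32 logarithmically spaced bins between 10 and 1e5 generations (MSMC-style
#' time discretization).
#'
#' @param n_bins number of bins.
#' @param t_min,t_max range in generations.
#' @return numeric vector of bin edges (length `n_bins + 1`).
#' @export
default_ccr_bins <- function(n_bins = 32, t_min = 10, t_max = 1e5) {
  exp(seq(log(t_min), log(t_max), length.out = n_bins + 1))
}

hazard_one <- function(times, edges) {
  nb <- length(edges) - 1
  events <- integer(nb); exposure <- numeric(nb); at_risk <- integer(nb)
  for (k in seq_len(nb)) {
    a <- edges[k]; b <- edges[k + 1]
    events[k] <- sum(times >= a & times < b)
    exposure[k] <- sum(pmax(0, pmin(times, b) - a))
    at_risk[k] <- sum(times >= a)
  }
  list(hazard = ifelse(exposure > 0, events / exposure, NA_real_),
       at_risk = at_risk)
}

#' Within/cross coalescence hazard curves and the rCCR ratio
#'
#' Per time bin, the hazard is (number of pair coalescences in the bin) /
#' (summed exposure time of not-yet-coalesced pairs in the bin); the
#' relative cross-coalescence rate is
#' `rccr = 2*lambda_cross / (lambda_within_A + lambda_within_B)`, reported
#' only where at least `min_pairs` pairs are still at risk in every
#' component.
#'
#' @param within_a,within_b,cross pair coalescence times (generations).
#' @param bins bin edges (default [default_ccr_bins()]).
#' @param min_pairs minimum at-risk pairs per bin (default 10).
#' @return an `rccr_curve` data.frame: `bin_start`, `bin_end`, `lam_a`,
#'   `lam_b`, `lam_cross`, `rccr`, `n_pairs`.
#' @export
hazard_curves <- function(within_a, within_b, cross,
                          bins = default_ccr_bins(), min_pairs = 10) {
  if (length(within_a) == 0 || length(within_b) == 0 || length(cross) == 0) {
    stop("input error: empty coalescence-time list")
  }
  ha <- hazard_one(within_a, bins)
  hb <- hazard_one(within_b, bins)
  hc <- hazard_one(cross, bins)
  denom <- ha$hazard + hb$hazard
  rccr <- ifelse(!is.na(denom) & denom > 0 & !is.na(hc$hazard),
                 2 * hc$hazard / denom, NA_real_)
  n_pairs <- pmin(ha$at_risk, hb$at_risk, hc$at_risk)
  rccr[n_pairs < min_pairs] <- NA_real_
  structure(data.frame(bin_start = bins[-length(bins)], bin_end = bins[-1],
                       lam_a = ha$hazard, lam_b = hb$hazard,
                       lam_cross = hc$hazard, rccr = rccr,
                       n_pairs = n_pairs),
            class = c("rccr_curve", "data.frame"))
}

#' Ground-truth rCCR curve between two populations
#'
#' Simulates genealogies under the model, extracts within- and
#' cross-population pair coalescence times from the true trees (no sequence
#' inference involved), and assembles the hazard/rCCR curve. When
#' `popA == popB` the within- and cross-hazards coincide and the curve sits
#' at 1 up to noise.
#'
#' @param model a `demographic_model`.
#' @param popA,popB population labels.
#' @param n_pairs target number of cross pairs (controls the locus count).
#' @param haps_per_pop haplotypes sampled per population per locus.
#' @param bins bin edges.
#' @param seed integer seed.
#' @param min_pairs minimum at-risk pairs per reported bin.
#' @return an `rccr_curve`.
#' @export
rccr_between <- function(model, popA, popB, n_pairs = 1e4, haps_per_pop = 4,
                         bins = default_ccr_bins(), seed = 1,
                         min_pairs = 10) {
  same <- popA == popB
  cross_per_locus <- if (same) choose(haps_per_pop, 2) else haps_per_pop^2
  n_loci <- ceiling(n_pairs / cross_per_locus)
  cm <- compile_model(model)
  if (same) {
    samp <- stats::setNames(haps_per_pop, popA)  # haplotype pool, split in two
    pop_idx <- match(rep(popA, 2 * haps_per_pop), cm$pops)
  } else {
    pop_idx <- match(rep(c(popA, popB), each = haps_per_pop), cm$pops)
  }
  ia <- seq_len(haps_per_pop)
  ib <- if (same) haps_per_pop + ia else haps_per_pop + ia
  pairs_w <- function(ix) t(combn(ix, 2))
  wA <- pairs_w(ia); wB <- pairs_w(ib)
  cr <- as.matrix(expand.grid(a = ia, b = ib))
  tA <- tB <- tC <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    g <- cpp_sim_genealogy(cm, pop_idx, as.numeric(seed), as.numeric(i))
    tA[[i]] <- cpp_pair_mrca(g$parent, g$time, wA)
    tB[[i]] <- cpp_pair_mrca(g$parent, g$time, wB)
    tC[[i]] <- cpp_pair_mrca(g$parent, g$time, cr)
  }
  hazard_curves(unlist(tA), unlist(tB), unlist(tC), bins = bins,
                min_pairs = min_pairs)
}

#' Crossing time of an rCCR curve
#'
#' Isotonic (monotone non-decreasing toward the past) smoothing of the
#' populated bins, then an oldest-to-youngest scan for the first adjacent
#' bin pair straddling the level, with linear interpolation between bin
#' midpoints. Returns `NA` when the level is never crossed.
#'
#' @param curve an `rccr_curve`.
#' @param level rCCR level, e.g. 0.5 (split heuristic) or 0.9 (onset of
#'   structure).
#' @param smooth apply isotonic smoothing first (default TRUE).
#' @return crossing time in generations, or `NA_real_`.
#' @export
crossing_time <- function(curve, level = 0.5, smooth = TRUE) {
  ok <- !is.na(curve$rccr)
  if (sum(ok) < 2) stop("input error: need >= 2 populated bins")
  mid <- (curve$bin_start[ok] + curve$bin_end[ok]) / 2
  y <- curve$rccr[ok]
  if (smooth) y <- stats::isoreg(mid, y)$yf  # non-decreasing toward the past
  nb <- length(y)
  for (k in nb:2) {
    hi <- y[k]; lo <- y[k - 1]
    if (hi >= level && lo <= level) {
      if (hi == lo) return(mid[k - 1])
      return(mid[k - 1] + (mid[k] - mid[k - 1]) * (level - lo) / (hi - lo))
    }
  }
  NA_real_
}
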