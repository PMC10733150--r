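#' @title Population-genetic summary statistics
#' @description Per-site frequency machinery shared by the diversity and
#'   F-statistic estimators. All statistics are complete-case per
#'   comparison: a site is used only where every involved population has at
#'   least two called (unmasked) haplotypes.
#' @name sumstats
NULL

# per-locus derived-allele counts and called-haplotype counts per population
# returns list per locus: der (sites x npop), called (sites x npop)
pop_counts <- function(dataset, pops) {
  n_hap <- 2L * nrow(dataset$samples)
  Z <- matrix(0, n_hap, length(pops), dimnames = list(NULL, pops))
  for (j in seq_along(pops)) Z[hap_indices(dataset, pops[j]), j] <- 1
  hap_per_pop <- colSums(Z)
  lapply(dataset$loci, function(lc) {
    g <- lc$geno
    if (nrow(g) == 0) {
      z <- matrix(0, 0, length(pops), dimnames = list(NULL, pops))
      return(list(der = z, called = z))
    }
    if (anyNA(g)) {
      gna <- is.na(g)
      g0 <- g
      g0[gna] <- 0L
      der <- g0 %*% Z
      called <- (!gna) %*% Z
    } else {
      der <- g %*% Z
      called <- matrix(hap_per_pop, nrow(g), length(pops), byrow = TRUE,
                       dimnames = list(NULL, pops))
    }
    list(der = der, called = called)
  })
}

unmasked_fraction_individual <- function(dataset, ind_index) {
  if (is.null(dataset$masks)) return(1)
  total <- length(dataset$loci) * dataset$locus_length
  masked <- sum(vapply(dataset$masks[[ind_index]], function(iv) {
    if (is.null(iv) || nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])
  }, numeric(1)))
  1 - masked / total
}

#' Nucleotide diversity
#'
#' Mean pairwise difference per site within a population: per site the
#' unbiased estimator `2*p*(1-p)*n/(n-1)` (n = called haplotypes), summed
#' over sites and divided by the total unmasked sequence length.
#'
#' @param dataset a `haplotype_dataset`.
#' @param pop population label.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(dataset, pop) {
  ix <- hap_indices(dataset, pop)
  if (length(ix) < 2) stop("input error: need >= 2 haplotypes in ", pop)
  pc <- pop_counts(dataset, pop)
  num <- sum(vapply(pc, function(l) {
    n <- l$called[, 1]; d <- l$der[, 1]
    use <- n >= 2
    p <- d[use] / n[use]
    sum(2 * p * (1 - p) * n[use] / (n[use] - 1))
  }, numeric(1)))
  len <- length(dataset$loci) * dataset$locus_length
  if (!is.null(dataset$masks)) {
    ind <- which(dataset$samples$population == pop)
    len <- len * mean(vapply(ind, function(i) {
      unmasked_fraction_individual(dataset, i)
    }, numeric(1)))
  }
  num / len
}

#' Count of segregating sites within a population
#'
#' Sites polymorphic among the population's called haplotypes (a site fixed
#' derived within the population does not count, even if variable globally).
#'
#' @inheritParams nucleotide_diversity
#' @return integer count.
#' @export
segregating_sites <- function(dataset, pop) {
  if (!pop %in% dataset$samples$population) return(0L)
  pc <- pop_counts(dataset, pop)
  sum(vapply(pc, function(l) {
    sum(l$der[, 1] > 0 & l$der[, 1] < l$called[, 1])
  }, numeric(1)))
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants computed from the population's haplotype count. Returns `NA`
#' (undefined, not zero) when no site segregates.
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA_real_` when S = 0.
#' @export
tajimas_d <- function(dataset, pop) {
  n <- length(hap_indices(dataset, pop))
  if (n < 3) stop("input error: need >= 3 haplotypes for Tajima's D")
  pc <- pop_counts(dataset, pop)
  S <- 0; pi_total <- 0
  for (l in pc) {
    cn <- l$called[, 1]; d <- l$der[, 1]
    seg <- d > 0 & d < cn
    S <- S + sum(seg)
    p <- d[seg] / cn[seg]
    pi_total <- pi_total + sum(2 * p * (1 - p) * cn[seg] / (cn[seg] - 1))
  }
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# Busing et al. (1999) weighted delete-one-block jackknife
# block_sums/block_counts: per-block sum of per-site values and usable sites
weighted_block_jackknife <- function(block_sums, block_counts) {
  keep <- block_counts > 0
  s <- block_sums[keep]; w <- block_counts[keep]
  g <- length(s)
  TT <- sum(s); W <- sum(w)
  est <- TT / W
  if (g < 2) {
    return(list(estimate = est, block_values = s / w, block_weights = w,
                se = NA_real_, z = NA_real_))
  }
  loo <- (TT - s) / (W - w)
  h <- W / w
  theta_j <- g * est - sum((1 - w / W) * loo)
  pseudo <- h * est - (h - 1) * loo
  var_j <- sum((pseudo - theta_j)^2 / (h - 1)) / g
  se <- sqrt(var_j)
  list(estimate = est, block_values = s / w, block_weights = w,
       se = se, z = if (se > 0) est / se else NA_real_)
}

# concatenated-site view of pop_counts: der/called (sites_total x npop),
# block = locus index per site; p/hn (= h/n correction term) and a per-pop
# validity mask are precomputed so each F statistic is a few vector ops
make_flat <- function(der, called, block, n_blocks) {
  valid <- called >= 2
  p <- der / called
  p[!valid] <- 0
  hn <- p * (1 - p) / (called - 1)  # h/n = p(1-p)/(n-1)
  hn[!valid] <- 0
  # cumulative site index at each block's end (sites are block-ordered)
  block_ends <- cumsum(tabulate(block, nbins = n_blocks))
  list(der = der, called = called, block = block, n_blocks = n_blocks,
       block_ends = block_ends, p = p, hn = hn, valid = valid,
       pops = colnames(der))
}

flat_counts <- function(dataset, pops) {
  cache <- pop_counts(dataset, pops)
  der <- do.call(rbind, lapply(cache, `[[`, "der"))
  called <- do.call(rbind, lapply(cache, `[[`, "called"))
  block <- rep(seq_along(cache),
               times = vapply(cache, function(l) nrow(l$der), integer(1)))
  make_flat(der, called, block, length(cache))
}

# per-block per-site F-statistic sums from a flat_counts cache
fstat_block_sums <- function(flat, kind, pops) {
  ix <- match(pops, flat$pops)
  nb <- flat$n_blocks
  use <- flat$valid[, ix[1]]
  for (j in ix[-1]) use <- use & flat$valid[, j]
  if (!any(use)) return(list(sums = numeric(nb), counts = numeric(nb)))
  P <- flat$p
  v <- switch(kind,
    F2 = (P[, ix[1]] - P[, ix[2]])^2 -
      flat$hn[, ix[1]] - flat$hn[, ix[2]],
    F3 = (P[, ix[1]] - P[, ix[2]]) * (P[, ix[1]] - P[, ix[3]]) -
      flat$hn[, ix[1]],
    F4 = (P[, ix[1]] - P[, ix[2]]) * (P[, ix[3]] - P[, ix[4]]))
  v[!use] <- 0
  cs <- c(0, cumsum(v))
  cu <- c(0, cumsum(use))
  e1 <- flat$block_ends + 1L
  sums <- diff(c(0, cs[e1]))
  counts <- diff(c(0, cu[e1]))
  list(sums = sums, counts = counts)
}

#' F-statistics with weighted block jackknife
#'
#' Per-site estimators (p = derived-allele frequency, h = unbiased
#' within-population heterozygosity term, n = called haplotypes):
#' `F2(A,B) = (pA-pB)^2 - hA/nA - hB/nB`;
#' `F3(C;A,B) = (pC-pA)(pC-pB) - hC/nC` (C first in `pops`);
#' `F4(A,B;C,D) = (pA-pB)(pC-pD)`. The estimate is the usable-site-weighted
#' mean; standard errors come from the weighted delete-one-block jackknife
#' over loci (weights = usable sites per block), and `z = estimate/se`.
#'
#' @param dataset a `haplotype_dataset`.
#' @param kind `"F2"`, `"F3"` or `"F4"`.
#' @param pops population labels: `c(A,B)`, `c(C,A,B)` or `c(A,B,C,D)`.
#' @param cache optional precomputed [pop_counts()] cache (internal reuse).
#' @return an `fstat_result`: estimate, per-block values/weights, se, z.
#' @export
f_statistic <- function(dataset, kind = c("F2", "F3", "F4"), pops,
                        cache = NULL) {
  kind <- match.arg(kind)
  need <- c(F2 = 2L, F3 = 3L, F4 = 4L)[[kind]]
  if (length(pops) != need) {
    stop("input error: ", kind, " needs ", need, " populations")
  }
  if (is.null(cache)) cache <- flat_counts(dataset, unique(pops))
  bs <- fstat_block_sums(cache, kind, pops)
  if (sum(bs$counts) == 0) {
    stop("input error: no usable sites (a population may be fully missing)")
  }
  jk <- weighted_block_jackknife(bs$sums, bs$counts)
  structure(c(list(kind = kind, populations = pops), jk),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g (se %.3g, Z %.2f)\n", x$kind,
              paste(x$populations, collapse = ","), x$estimate, x$se, x$z))
  invisible(x)
}

#' Cladeness F4 test
#'
#' `F4(outgroup, PNG; X, Y)` tests whether the two focal populations are
#' equally related to the reference (form a clade with respect to it); the
#' relationship is called non-cladistic when `|Z| > 3`.
#'
#' @param dataset a `haplotype_dataset`.
#' @param ausX,ausY focal populations.
#' @param png reference population sharing drift with one side under the
#'   alternative.
#' @param outgroup outgroup label.
#' @return `fstat_result` with a `verdict` field (`"clade"` or
#'   `"non-cladistic"`).
#' @export
cladeness_f4_test <- function(dataset, ausX, ausY, png = "PNG",
                              outgroup = "OUT") {
  if (ausX == ausY) {
    r <- f_statistic(dataset, "F4", c(outgroup, png, ausX, ausX))
  } else {
    r <- f_statistic(dataset, "F4", c(outgroup, png, ausX, ausY))
  }
  r$verdict <- if (is.finite(r$z) && abs(r$z) > 3) "non-cladistic" else "clade"
  r
}

#' Admixture F3 test
#'
#' `F3(target; sourceA, sourceB)`: a significantly negative value
#' (`z < -3`) indicates the target is admixed between populations related
#' to the two sources.
#'
#' @param dataset a `haplotype_dataset`.
#' @param target candidate admixed population.
#' @param sourceA,sourceB proxy source populations.
#' @return `fstat_result` with a `verdict` field (`"admixed"` or
#'   `"not-admixed"`).
#' @export
admixture_f3_test <- function(dataset, target, sourceA, sourceB) {
  r <- f_statistic(dataset, "F3", c(target, sourceA, sourceB))
  r$verdict <- if (is.finite(r$z) && r$z < -3) "admixed" else "not-admixed"
  r
}

#' Hudson FST (ratio of sums)
#'
#' Unbiased Hudson-type estimator: `sum(N_hd) / sum(D_hd)` over sites, with
#' `N_hd = (pA-pB)^2 - hA/nA - hB/nB` and
#' `D_hd = pA(1-pB) + pB(1-pA)`. Optionally ascertained on sites polymorphic
#' in a third population (the Mbuti-style ascertainment scheme).
#'
#' @param dataset a `haplotype_dataset`.
#' @param popA,popB population labels.
#' @param ascertainment_pop optional: restrict to sites polymorphic there.
#' @return FST value (`NA` if the denominator is zero).
#' @export
fst_hudson <- function(dataset, popA, popB, ascertainment_pop = NULL) {
  pops <- c(popA, popB, ascertainment_pop)
  cache <- pop_counts(dataset, unique(pops))
  num <- 0; den <- 0
  for (l in cache) {
    cn <- l$called[, c(popA, popB), drop = FALSE]
    use <- rowSums(cn >= 2) == 2
    if (!is.null(ascertainment_pop)) {
      da <- l$der[, ascertainment_pop]; ca <- l$called[, ascertainment_pop]
      use <- use & da > 0 & da < ca
    }
    if (!any(use)) next
    d <- l$der[use, c(popA, popB), drop = FALSE]
    n <- cn[use, , drop = FALSE]
    p <- d / n
    h <- p * (1 - p) * n / (n - 1)
    num <- num + sum((p[, 1] - p[, 2])^2 - h[, 1] / n[, 1] - h[, 2] / n[, 2])
    den <- den + sum(p[, 1] * (1 - p[, 2]) + p[, 2] * (1 - p[, 1]))
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Second and third central moments of per-block F-statistic values
#'
#' @param result an `fstat_result`.
#' @return named vector `c(m2, m3)` (unweighted central moments across
#'   blocks).
#' @export
f_moments <- function(result) {
  x <- result$block_values
  if (length(x) < 3) stop("input error: need >= 3 blocks for moments")
  m <- mean(x)
  c(m2 = mean((x - m)^2), m3 = mean((x - m)^3))
}

#' Variant-sharing classes
#'
#' Assigns every variant site to exactly one of four non-overlapping
#' classes from its presence pattern across population samples:
#' population-private (one population), continent-private (several
#' populations of one continent), shared across some continents, shared
#' across all continents. Counts are tabulated per population over the
#' sites where that population carries the variant.
#'
#' @param dataset a `haplotype_dataset`.
#' @param continent_map optional named vector population -> continent
#'   (defaults to the dataset's sample table).
#' @return data.frame with one row per population and the four class
#'   counts; rows sum to the number of variant sites observed in that
#'   population.
#' @export
sharing_classes <- function(dataset, continent_map = NULL) {
  pops <- unique(dataset$samples$population)
  if (is.null(continent_map)) {
    continent_map <- tapply(dataset$samples$continent,
                            dataset$samples$population, `[`, 1)
  }
  if (any(!pops %in% names(continent_map))) {
    stop("configuration error: population without continent assignment")
  }
  conts <- continent_map[pops]
  n_cont_total <- length(unique(conts))
  cache <- pop_counts(dataset, pops)
  counts <- matrix(0L, length(pops), 4,
                   dimnames = list(pops, c("population_private",
                                           "continent_private",
                                           "shared_some", "shared_all")))
  for (l in cache) {
    pres <- l$der > 0
    if (nrow(pres) == 0) next
    npop <- rowSums(pres)
    ncont <- apply(pres, 1, function(r) length(unique(conts[r])))
    class_idx <- ifelse(npop == 0, NA,
                 ifelse(npop == 1, 1L,
                 ifelse(ncont == 1, 2L,
                 ifelse(ncont < n_cont_total, 3L, 4L))))
    for (k in 1:4) {
      sel <- which(class_idx == k)
      if (length(sel) > 0) {
        counts[, k] <- counts[, k] + colSums(pres[sel, , drop = FALSE])
      }
    }
  }
  storage.mode(counts) <- "integer"
  data.frame(population = pops, counts, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Minor-allele-count spectrum in a fixed-size subsample
#'
#' The minor allele is defined from the pooled frequency over the whole
#' dataset (ties broken toward the ancestral/0 allele, deterministically);
#' the statistic is its count among `2*subsample_n` haplotypes randomly
#' subsampled from the population, binned 1..`2*subsample_n` (count 0
#' excluded; the top bin means fixed in the subsample).
#'
#' @param dataset a `haplotype_dataset`.
#' @param pop population label.
#' @param subsample_n diploids to subsample (default 5).
#' @param seed subsampling seed.
#' @return integer vector of bin counts, names `1..2*subsample_n`.
#' @export
mac_spectrum <- function(dataset, pop, subsample_n = 5, seed = 1) {
  ind <- which(dataset$samples$population == pop)
  if (length(ind) < subsample_n) {
    stop("input error: fewer than ", subsample_n, " individuals in ", pop)
  }
  set.seed(seed)
  pick <- sample(ind, subsample_n)
  cols <- sort(c(2L * pick - 1L, 2L * pick))
  nb <- 2L * subsample_n
  bins <- integer(nb)
  for (lc in dataset$loci) {
    g <- lc$geno
    if (nrow(g) == 0) next
    der_glob <- rowSums(g, na.rm = TRUE)
    called_glob <- rowSums(!is.na(g))
    minor_is_derived <- der_glob / called_glob < 0.5  # tie -> allele 0 minor
    sub <- g[, cols, drop = FALSE]
    der_sub <- rowSums(sub, na.rm = TRUE)
    called_sub <- rowSums(!is.na(sub))
    cnt <- ifelse(minor_is_derived, der_sub, called_sub - der_sub)
    cnt <- cnt[cnt >= 1 & cnt <= nb]
    if (length(cnt) > 0) {
      tb <- tabulate(cnt, nbins = nb)
      bins <- bins + tb
    }
  }
  names(bins) <- as.character(seq_len(nb))
  bins
}

#' Per-individual heterozygous-site counts
#'
#' Counts sites where an individual's two haplotypes carry unlike alleles;
#' optionally rescaled by the individual's unmasked genome fraction (the
#' ancestry-masking correction). Fully masked individuals yield `NA`.
#'
#' @param dataset a `haplotype_dataset`.
#' @param rescale divide by the unmasked fraction.
#' @return named numeric vector, one entry per individual.
#' @export
het_per_individual <- function(dataset, rescale = FALSE) {
  n_ind <- nrow(dataset$samples)
  het <- numeric(n_ind)
  for (lc in dataset$loci) {
    g <- lc$geno
    if (nrow(g) == 0) next
    a <- g[, 2L * seq_len(n_ind) - 1L, drop = FALSE]
    b <- g[, 2L * seq_len(n_ind), drop = FALSE]
    het <- het + colSums(a != b, na.rm = TRUE)
  }
  names(het) <- dataset$samples$individual
  if (rescale) {
    fr <- vapply(seq_len(n_ind), function(i) {
      unmasked_fraction_individual(dataset, i)
    }, numeric(1))
    het <- ifelse(fr > 0, het / fr, NA_real_)
    names(het) <- dataset$samples$individual
  }
  het
}

#' Rare-allele sharing between individuals
#'
#' For every individual pair, the number of rare variants both carry. A
#' variant is rare when its dataset-wide derived-allele count is at most
#' `max_count`; with missing data the observed count is rescaled by the
#' site's callable fraction so the classification stays comparable between
#' masked and unmasked data. With `rescale`, each pair's count is divided
#' by the fraction of the genome unmasked in both individuals.
#'
#' @param dataset a `haplotype_dataset`.
#' @param max_count rare-allele count threshold (default 5).
#' @param rescale apply the pairwise mask correction.
#' @return symmetric individuals x individuals matrix (diagonal = own rare
#'   variant count).
#' @export
rare_sharing_matrix <- function(dataset, max_count = 5, rescale = FALSE) {
  n_ind <- nrow(dataset$samples)
  if (n_ind < 2) stop("input error: need >= 2 individuals")
  n_hap <- 2L * n_ind
  M <- matrix(0, n_ind, n_ind,
              dimnames = list(dataset$samples$individual,
                              dataset$samples$individual))
  for (lc in dataset$loci) {
    g <- lc$geno
    if (nrow(g) == 0) next
    der <- rowSums(g, na.rm = TRUE)
    called <- rowSums(!is.na(g))
    # mask-aware allele count for a carrying pair: the pair's own two
    # copies are observed by construction, so only the remaining copies
    # are rescaled by the callable fraction of the remaining haplotypes
    # (reduces to the raw count on complete data)
    khat <- ifelse(called > 4,
                   2 + (der - 2) * (n_hap - 4) / (called - 4),
                   der)
    rare <- which(der >= 1 & khat <= max_count)
    if (length(rare) == 0) next
    a <- g[rare, 2L * seq_len(n_ind) - 1L, drop = FALSE]
    b <- g[rare, 2L * seq_len(n_ind), drop = FALSE]
    carrier <- (!is.na(a) & a == 1L) | (!is.na(b) & b == 1L)
    storage.mode(carrier) <- "numeric"
    M <- M + crossprod(carrier)
  }
  if (rescale) {
    fr <- pairwise_unmasked_matrix(dataset)
    M <- ifelse(fr > 0, M / fr, NA_real_)
  }
  M
}

#' Variant discovery curve within a population
#'
#' Mean cumulative count of segregating sites as the sample is progressively
#' increased 1..`n_max` individuals, averaged over replicates; orderings are
#' nested within a replicate, so every curve is monotone non-decreasing.
#'
#' @param dataset a `haplotype_dataset`.
#' @param pop population label.
#' @param n_max largest subsample (defaults to the population size).
#' @param replicates number of random orderings (default 10).
#' @param seed ordering seed.
#' @return data.frame `n`, `mean_segregating`, plus a `replicates` matrix
#'   attribute (n x replicates).
#' @export
discovery_curve <- function(dataset, pop, n_max = NULL, replicates = 10,
                            seed = 1) {
  ind <- which(dataset$samples$population == pop)
  if (is.null(n_max)) n_max <- length(ind)
  if (n_max > length(ind)) stop("input error: n_max exceeds population size")
  G <- do.call(rbind, lapply(dataset$loci, function(l) l$geno))
  set.seed(seed)
  reps <- matrix(0, n_max, replicates)
  for (r in seq_len(replicates)) {
    ord <- sample(ind)
    der <- numeric(nrow(G)); called <- numeric(nrow(G))
    for (n in seq_len(n_max)) {
      cols <- c(2L * ord[n] - 1L, 2L * ord[n])
      sub <- G[, cols, drop = FALSE]
      der <- der + rowSums(sub, na.rm = TRUE)
      called <- called + rowSums(!is.na(sub))
      reps[n, r] <- sum(der > 0 & der < called)
    }
  }
  out <- data.frame(n = seq_len(n_max), mean_segregating = rowMeans(reps))
  attr(out, "replicates") <- reps
  out
}

#' Novel-variant discovery curve by continent
#'
#' After pre-sampling `pre_sample` individuals from each non-focal
#' continent, counts how many additional variants (absent from the
#' pre-sampled union) are observed as the focal continent is sampled
#' 1..`n_max`, averaged over replicates.
#'
#' @param dataset a `haplotype_dataset`.
#' @param focal_continent continent label to accumulate.
#' @param pre_sample individuals pre-sampled per other continent (capped at
#'   each continent's size).
#' @param n_max largest focal subsample.
#' @param replicates number of random orderings.
#' @param seed ordering seed.
#' @return data.frame `n`, `mean_new_variants` with a `replicates`
#'   attribute.
#' @export
novel_by_continent_curve <- function(dataset, focal_continent,
                                     pre_sample = 80, n_max = NULL,
                                     replicates = 10, seed = 1) {
  foc <- which(dataset$samples$continent == focal_continent)
  if (length(foc) == 0) stop("input error: unknown continent")
  if (is.null(n_max)) n_max <- length(foc)
  if (n_max > length(foc)) stop("input error: n_max exceeds continent size")
  G <- do.call(rbind, lapply(dataset$loci, function(l) l$geno))
  others <- setdiff(unique(dataset$samples$continent), focal_continent)
  set.seed(seed)
  reps <- matrix(0, n_max, replicates)
  for (r in seq_len(replicates)) {
    pre <- unlist(lapply(others, function(ct) {
      ix <- which(dataset$samples$continent == ct)
      sample(ix, min(pre_sample, length(ix)))
    }))
    pre_cols <- sort(c(2L * pre - 1L, 2L * pre))
    seen <- rowSums(G[, pre_cols, drop = FALSE], na.rm = TRUE) > 0
    ord <- sample(foc)
    der <- numeric(nrow(G))
    for (n in seq_len(n_max)) {
      cols <- c(2L * ord[n] - 1L, 2L * ord[n])
      der <- der + rowSums(G[, cols, drop = FALSE], na.rm = TRUE)
      reps[n, r] <- sum(!seen & der > 0)
    }
  }
  out <- data.frame(n = seq_len(n_max), mean_new_variants = rowMeans(reps))
  attr(out, "replicates") <- reps
  out
}

#' Default summary-statistic schema
#'
#' The ABC summary set: outgroup F3 for all study-population pairs,
#' cladeness-form F4(OUT, PNG; X, Y) for Australian pairs, admixture-form
#' F3(X; PNG, Y) for ordered Australian pairs, each with its per-block
#' second and third central moments, plus per-population Tajima's D,
#' nucleotide diversity and segregating-site counts.
#'
#' @param pops study populations (default the five samples).
#' @param outgroup outgroup label.
#' @param moments include per-statistic m2/m3 entries.
#' @return a `summary_config` list.
#' @export
summary_config <- function(pops = c("TIW", "GAL", "TIJ", "YAR", "PNG"),
                           outgroup = "OUT", moments = TRUE) {
  structure(list(pops = pops, outgroup = outgroup, moments = moments),
            class = "summary_config")
}

#' Assemble the fixed-schema summary vector
#'
#' Computes every statistic of the configured schema; the schema (names and
#' order) depends only on the configuration, so observed and simulated
#' datasets are directly comparable.
#'
#' @param dataset a `haplotype_dataset`.
#' @param config a [summary_config()].
#' @return named numeric vector.
#' @export
summary_vector <- function(dataset, config = summary_config()) {
  have <- unique(dataset$samples$population)
  need <- c(config$pops, config$outgroup)
  if (any(!need %in% have)) {
    stop("input error: dataset lacks populations: ",
         paste(setdiff(need, have), collapse = ", "))
  }
  cache <- flat_counts(dataset, need)
  len <- length(dataset$loci) * dataset$locus_length
  hap_n <- vapply(config$pops, function(p) length(hap_indices(dataset, p)),
                  integer(1))
  pop_len <- stats::setNames(rep(len, length(config$pops)), config$pops)
  if (!is.null(dataset$masks)) {
    for (p in config$pops) {
      ind <- which(dataset$samples$population == p)
      pop_len[p] <- len * mean(vapply(ind, function(i) {
        unmasked_fraction_individual(dataset, i)
      }, numeric(1)))
    }
  }
  summary_from_flat(cache, config, hap_n, pop_len)
}

# declarative F-statistic schema: name, kind, up to 4 population labels.
# Order: outgroup F3 (all study pairs), cladeness F4(O,PNG;X,Y), admixture
# F3(X;PNG,Y), treeness contrasts F4(O,X;Y,Z) over Australian triples (the
# statistics sensitive to which populations share internal branches).
fstat_schema <- function(config) {
  pops <- config$pops
  og <- config$outgroup
  rows <- list()
  prs <- combn(pops, 2)
  for (j in seq_len(ncol(prs))) {
    rows[[length(rows) + 1L]] <- c(paste0("f3o_", prs[1, j], "_", prs[2, j]),
                                   "F3", og, prs[1, j], prs[2, j], NA)
  }
  aus <- setdiff(pops, "PNG")
  aprs <- combn(aus, 2)
  for (j in seq_len(ncol(aprs))) {
    rows[[length(rows) + 1L]] <- c(paste0("f4_", aprs[1, j], "_", aprs[2, j]),
                                   "F4", og, "PNG", aprs[1, j], aprs[2, j])
  }
  for (x in aus) for (y in setdiff(aus, x)) {
    rows[[length(rows) + 1L]] <- c(paste0("f3a_", x, "_", y),
                                   "F3", x, "PNG", y, NA)
  }
  for (x in aus) {
    rest <- setdiff(aus, x)
    rpr <- combn(rest, 2)
    for (j in seq_len(ncol(rpr))) {
      rows[[length(rows) + 1L]] <- c(paste0("f4t_", x, "_", rpr[1, j], "_",
                                            rpr[2, j]),
                                     "F4", og, x, rpr[1, j], rpr[2, j])
      # the same contrast anchored on PNG: a shallower anchor gives the
      # internal-branch signal with less deep-genealogy noise
      rows[[length(rows) + 1L]] <- c(paste0("f4p_", x, "_", rpr[1, j], "_",
                                            rpr[2, j]),
                                     "F4", "PNG", x, rpr[1, j], rpr[2, j])
    }
  }
  m <- do.call(rbind, rows)
  data.frame(name = m[, 1], kind = m[, 2], p1 = m[, 3], p2 = m[, 4],
             p3 = m[, 5], p4 = m[, 6], stringsAsFactors = FALSE)
}

# assemble named summary entries from per-stat block sums/counts
assemble_summaries <- function(schema, sums, counts, config,
                               pop_pi, pop_S, hap_n, pop_len) {
  out <- numeric(0)
  for (s in seq_len(nrow(schema))) {
    jk <- weighted_block_jackknife(sums[, s], counts[, s])
    nm <- schema$name[s]
    out[nm] <- jk$estimate
    if (config$moments) {
      x <- jk$block_values
      if (length(x) >= 3) {
        m <- mean(x)
        out[paste0(nm, "_m2")] <- mean((x - m)^2)
        out[paste0(nm, "_m3")] <- mean((x - m)^3)
      } else {
        out[paste0(nm, "_m2")] <- NA_real_
        out[paste0(nm, "_m3")] <- NA_real_
      }
    }
  }
  for (p in config$pops) {
    out[paste0("pi_", p)] <- pop_pi[[p]] / pop_len[[p]]
    S <- pop_S[[p]]
    out[paste0("s_", p)] <- S
    out[paste0("d_", p)] <- if (S == 0) 0 else {
      k <- tajima_constants(hap_n[[p]])
      (pop_pi[[p]] - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    }
  }
  out
}

# core schema assembly shared by summary_vector and the fast simulation path
summary_from_flat <- function(cache, config, hap_n, pop_len) {
  schema <- fstat_schema(config)
  ns <- nrow(schema)
  sums <- matrix(0, cache$n_blocks, ns)
  counts <- matrix(0, cache$n_blocks, ns)
  for (s in seq_len(ns)) {
    fpops <- stats::na.omit(unlist(schema[s, c("p1", "p2", "p3", "p4")]))
    bs <- fstat_block_sums(cache, schema$kind[s], fpops)
    sums[, s] <- bs$sums
    counts[, s] <- bs$counts
  }
  pop_pi <- numeric(0); pop_S <- numeric(0)
  for (p in config$pops) {
    cn <- cache$called[, p]; dd <- cache$der[, p]
    seg <- dd > 0 & dd < cn
    pr <- dd[seg] / cn[seg]
    pop_pi[p] <- sum(2 * pr * (1 - pr) * cn[seg] / (cn[seg] - 1))
    pop_S[p] <- sum(seg)
  }
  assemble_summaries(schema, sums, counts, config, pop_pi, pop_S,
                     hap_n, pop_len)
}

#' Simulate a dataset's summary vector without materializing genotypes
#'
#' Equivalent to `summary_vector(simulate_dataset(...))` — the per-locus
#' mutation stream is shared, so the same `(seed, locus)` pair yields the
#' same mutations — but only per-population allele counts are ever formed
#' (in compiled code), which makes reference-table generation an order of
#' magnitude faster.
#'
#' @param model a `demographic_model`.
#' @param samples named diploid counts.
#' @param locus a [locus_config()].
#' @param seed integer seed.
#' @param config a [summary_config()].
#' @return named numeric summary vector.
#' @export
simulate_summary_vector <- function(model, samples, locus, seed,
                                    config = summary_config()) {
  cm <- compile_model(model)
  leaf_pop <- sampled_pop_vector(model, samples)
  spops <- names(samples)
  schema <- fstat_schema(config)
  kind_code <- c(F2 = 2L, F3 = 3L, F4 = 4L)
  stats_mat <- cbind(
    kind_code[schema$kind],
    match(schema$p1, spops), match(schema$p2, spops),
    match(schema$p3, spops), match(schema$p4, spops))
  stats_mat[is.na(stats_mat)] <- 0L
  storage.mode(stats_mat) <- "integer"
  hap_n <- stats::setNames(2L * as.integer(samples), spops)
  bl <- cpp_sim_summary_blocks(cm, match(leaf_pop, cm$pops),
                               match(leaf_pop, spops), length(spops),
                               as.integer(hap_n), locus$mu, locus$length_bp,
                               locus$n_loci, stats_mat, as.numeric(seed))
  names(bl$pop_pi) <- spops
  names(bl$pop_S) <- spops
  len <- locus$n_loci * locus$length_bp
  assemble_summaries(schema, bl$sums, bl$counts, config,
                     bl$pop_pi, bl$pop_S, hap_n,
                     stats::setNames(rep(len, length(config$pops)),
                                     config$pops))
}
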