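#' Cohort profile for synthetic-data generation
#'
#' Per-population diploid counts, ancestry-mask missingness distributions
#' and the recent Yarrabah admixture-pulse settings. Masked fractions are
#' drawn per individual from a Beta distribution with the stated mean and
#' concentration; defaults are order-of-magnitude choices exposed here
#' (the empirical per-population distribution is not derivable from public
#' data).
#'
#' @param samples named diploid counts (default the study design).
#' @param mask_mean named per-population mean masked fraction.
#' @param mask_concentration Beta concentration (mean * c, (1-mean) * c).
#' @param yarrabah_pulse enable the 1.8% PNG pulse into Yarrabah.
#' @param pulse_proportion pulse admixture proportion (default 0.018).
#' @param pulse_time_range generations-before-present window for the pulse
#'   time draw (default 3-7).
#' @return a `cohort_profile` list.
#' @export
cohort_profile <- function(samples = default_sample_config(),
                           mask_mean = c(TIW = 0.05, GAL = 0.05, TIJ = 0.08,
                                         YAR = 0.25, PNG = 0.02, OUT = 0),
                           mask_concentration = 20,
                           yarrabah_pulse = TRUE,
                           pulse_proportion = 0.018,
                           pulse_time_range = c(3, 7)) {
  if (pulse_proportion < 0 || pulse_proportion > 1) {
    stop("configuration error: pulse proportion outside [0,1]")
  }
  structure(list(samples = samples, mask_mean = mask_mean,
                 mask_concentration = mask_concentration,
                 yarrabah_pulse = yarrabah_pulse,
                 pulse_proportion = pulse_proportion,
                 pulse_time_range = pulse_time_range),
            class = "cohort_profile")
}

#' Emulate the study cohort
#'
#' Simulates a haplotype dataset under the calibrated scenario-4 history
#' (with the Yarrabah pulse when enabled, its time drawn uniformly from the
#' profile's window) and applies per-individual ancestry-mask missingness
#' drawn from the profile's Beta distributions. All derived seeds are
#' recorded in the `provenance` attribute.
#'
#' @param profile a [cohort_profile()].
#' @param locus a [locus_config()].
#' @param seed integer seed.
#' @param keep_trees retain genealogies.
#' @return a masked `haplotype_dataset` (see [apply_mask()]).
#' @export
emulate_cohort <- function(profile = cohort_profile(),
                           locus = locus_config(), seed = 1,
                           keep_trees = FALSE) {
  set.seed(seed)
  pulse_time <- runif(1, profile$pulse_time_range[1],
                      profile$pulse_time_range[2])
  model <- scenario4_calibrated(
    yarrabah_pulse = profile$yarrabah_pulse && profile$pulse_proportion > 0,
    pulse_time_gen = pulse_time,
    include_outgroup = "OUT" %in% names(profile$samples))
  if (profile$yarrabah_pulse && profile$pulse_proportion != 0.018 &&
      nrow(model$pulses) > 0) {
    model$pulses$proportion <- profile$pulse_proportion
  }
  ds <- simulate_dataset(model, profile$samples, locus, seed = seed,
                         keep_trees = keep_trees)
  mm <- profile$mask_mean[ds$samples$population]
  cc <- profile$mask_concentration
  fractions <- ifelse(mm <= 0, 0,
                      stats::rbeta(nrow(ds$samples), mm * cc, (1 - mm) * cc))
  ds <- apply_mask(ds, fractions, seed = seed + 1)
  attr(ds, "provenance") <- list(seed = seed, mask_seed = seed + 1,
                                 pulse_time = pulse_time,
                                 fractions = fractions)
  ds
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Apply ancestry-mask missingness to a dataset
#'
#' Places contiguous masked spans (exponential lengths, uniform starts)
#' across an individual's loci until the requested masked fraction of the
#' genome is reached (the final span is trimmed so the realized fraction
#' matches the request to base-pair resolution). Both haplotypes of the
#' individual are set to missing inside a span — the diploid masking rule
#' under which a region is dropped when one or both haplotypes are of
#' non-target ancestry. Individuals masked above 95% are flagged (the
#' analysis convention is to drop them).
#'
#' @param dataset a `haplotype_dataset`.
#' @param fractions masked fraction per individual, in `[0, 1]`.
#' @param span_mean_bp mean masked-span length (default: locus length / 20,
#'   the multi-megabase-tract scale mapped onto a locus).
#' @param seed integer seed.
#' @return the dataset with `masks` set (per individual, per locus,
#'   0-based half-open interval matrices) and genotypes inside spans set to
#'   `NA`; attribute `flagged` lists individuals masked above 95%.
#' @export
apply_mask <- function(dataset, fractions, span_mean_bp = NULL, seed = 1) {
  n_ind <- nrow(dataset$samples)
  if (length(fractions) == 1) fractions <- rep(fractions, n_ind)
  if (length(fractions) != n_ind) {
    stop("input error: one masked fraction per individual required")
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("input error: masked fractions must lie in [0, 1]")
  }
  L <- dataset$locus_length
  n_loci <- length(dataset$loci)
  if (is.null(span_mean_bp)) span_mean_bp <- L / 20
  total <- n_loci * L
  set.seed(seed)
  masks <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    target <- round(fractions[i] * total)
    per_locus <- rep(list(matrix(numeric(0), 0, 2)), n_loci)
    if (target > 0 && n_loci > 0) {
      masked <- 0
      while (masked < target) {
        lc <- sample.int(n_loci, 1)
        start <- floor(runif(1, 0, L))
        len <- max(1, ceiling(rexp(1, 1 / span_mean_bp)))
        prev <- span_total(per_locus[[lc]])
        iv <- merge_intervals(rbind(per_locus[[lc]],
                                    c(start, min(L, start + len))))
        masked <- masked - prev + span_total(iv)
        if (masked > target) {
          # trim the last-placed coverage so the realized total hits target
          iv <- trim_intervals(iv, masked - target)
          masked <- target
        }
        per_locus[[lc]] <- iv
      }
    }
    masks[[i]] <- per_locus
  }
  # apply to genotypes
  for (lc in seq_len(n_loci)) {
    g <- dataset$loci[[lc]]$geno
    if (nrow(g) == 0) next
    pos0 <- dataset$loci[[lc]]$pos - 1L  # to 0-based
    for (i in seq_len(n_ind)) {
      iv <- masks[[i]][[lc]]
      if (nrow(iv) == 0) next
      hit <- rep(FALSE, length(pos0))
      for (r in seq_len(nrow(iv))) {
        hit <- hit | (pos0 >= iv[r, 1] & pos0 < iv[r, 2])
      }
      if (any(hit)) g[hit, c(2L * i - 1L, 2L * i)] <- NA_integer_
    }
    dataset$loci[[lc]]$geno <- g
  }
  dataset$masks <- masks
  flagged <- which(fractions > 0.95)
  attr(dataset, "flagged") <- dataset$samples$individual[flagged]
  dataset
}

span_total <- function(iv) if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

# remove `excess` bp from the end of the last interval(s)
trim_intervals <- function(iv, excess) {
  i <- nrow(iv)
  while (excess > 0 && i >= 1) {
    len <- iv[i, 2] - iv[i, 1]
    cut <- min(len, excess)
    iv[i, 2] <- iv[i, 2] - cut
    excess <- excess - cut
    i <- i - 1
  }
  iv[iv[, 2] > iv[, 1], , drop = FALSE]
}

#' Fraction of the genome unmasked in both of two mask tracks
#'
#' @param maskA,maskB per-locus interval lists (one individual's mask each,
#'   as stored in `dataset$masks`).
#' @param locus_length locus length in bp.
#' @return fraction of total length outside the union of both masks.
#' @export
pairwise_unmasked_fraction <- function(maskA, maskB, locus_length) {
  if (length(maskA) != length(maskB)) {
    stop("input error: mismatched locus structure")
  }
  total <- length(maskA) * locus_length
  if (total == 0) return(1)
  masked <- 0
  for (lc in seq_along(maskA)) {
    u <- merge_intervals(rbind(maskA[[lc]], maskB[[lc]]))
    masked <- masked + span_total(u)
  }
  1 - masked / total
}

# all-pairs unmasked fraction matrix for a masked dataset
pairwise_unmasked_matrix <- function(dataset) {
  n_ind <- nrow(dataset$samples)
  if (is.null(dataset$masks)) {
    return(matrix(1, n_ind, n_ind))
  }
  M <- matrix(1, n_ind, n_ind)
  for (i in seq_len(n_ind)) {
    for (j in i:n_ind) {
      f <- pairwise_unmasked_fraction(dataset$masks[[i]], dataset$masks[[j]],
                                      dataset$locus_length)
      M[i, j] <- f; M[j, i] <- f
    }
  }
  M
}

#' Rescale a masked count by the unmasked fraction
#'
#' @param raw raw count.
#' @param unmasked_fraction fraction in `(0, 1]`.
#' @return `raw / unmasked_fraction`; `NA` when the fraction is zero.
#' @export
rescale_count <- function(raw, unmasked_fraction) {
  ifelse(unmasked_fraction > 0, raw / unmasked_fraction, NA_real_)
}
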