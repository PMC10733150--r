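#' Sampling configuration
#'
#' Diploid sample counts per population. Defaults follow the study design:
#' 34 Tiwi, 17 Galiwin'ku, 7 Titjikala, 31 Yarrabah and 25 Highland-PNG
#' individuals, plus a configurable outgroup sample.
#'
#' @param tiw,gal,tij,yar,png,out diploid counts.
#' @return named integer vector of diploid counts.
#' @export
default_sample_config <- function(tiw = 34, gal = 17, tij = 7, yar = 31,
                                  png = 25, out = 5) {
  cfg <- c(TIW = tiw, GAL = gal, TIJ = tij, YAR = yar, PNG = png, OUT = out)
  cfg[cfg > 0]
}

#' Locus configuration
#'
#' Loci are unlinked and internally non-recombining; each locus doubles as a
#' jackknife block. The default mutation rate is the human-typical
#' 1.25e-8 per bp per generation.
#'
#' @param n_loci number of independent loci.
#' @param length_bp locus length in bases.
#' @param mu mutation rate per bp per generation.
#' @return a `locus_config` list.
#' @export
locus_config <- function(n_loci = 100, length_bp = 1e5, mu = 1.25e-8) {
  stopifnot(n_loci >= 0, length_bp > 0, mu >= 0)
  structure(list(n_loci = as.integer(n_loci), length_bp = length_bp, mu = mu),
            class = "locus_config")
}

# flatten a demographic_model into the index-based structure the C++
# simulator consumes; pop order = model$populations$name
compile_model <- function(model) {
  pops <- model$populations$name
  idx <- function(x) {
    i <- match(x, pops)
    if (anyNA(i)) stop("unknown population: ", paste(x[is.na(i)], collapse = ", "))
    i
  }
  epochs <- as.matrix(data.frame(
    pop = idx(model$sizes$population),
    start = model$sizes$start_gen, end = model$sizes$end_gen,
    N = model$sizes$ne))
  ev <- matrix(numeric(0), ncol = 6)
  if (nrow(model$pulses) > 0) {
    ev <- rbind(ev, cbind(model$pulses$time_gen, 1,
                          idx(model$pulses$from_pop),
                          idx(model$pulses$into_pop), 1,
                          model$pulses$proportion))
  }
  if (nrow(model$splits) > 0) {
    ev <- rbind(ev, cbind(model$splits$time_gen, 0,
                          idx(model$splits$child_a),
                          idx(model$splits$child_b),
                          idx(model$splits$parent), 0))
  }
  bands <- matrix(numeric(0), ncol = 5)
  if (nrow(model$migrations) > 0) {
    bands <- cbind(idx(model$migrations$source), idx(model$migrations$dest),
                   model$migrations$rate, model$migrations$start_gen,
                   model$migrations$end_gen)
  }
  list(n_pop = length(pops), epochs = epochs, events = ev, bands = bands,
       pops = pops)
}

sampled_pop_vector <- function(model, samples) {
  pops <- names(samples)
  present_at_zero <- model$sizes$population[model$sizes$start_gen == 0]
  absent <- setdiff(pops, present_at_zero)
  if (length(absent) > 0) {
    stop("input error: population(s) not present at sampling time: ",
         paste(absent, collapse = ", "))
  }
  rep(pops, times = 2L * as.integer(samples))
}

#' Simulate one genealogy under a demographic model
#'
#' Structured Kingman coalescent realization: within a population of diploid
#' size N each lineage pair coalesces at rate 1/(2N) per generation;
#' migration bands move lineages between populations (backward-time
#' convention); at a split, child lineages merge into the parent population;
#' at an admixture pulse, each lineage in the receiving population moves to
#' the source with the pulse proportion.
#'
#' @param model a `demographic_model`.
#' @param samples named vector of diploid counts per sampled population.
#' @param seed integer seed; combined with `stream` for per-locus
#'   reproducibility.
#' @param stream sub-stream index (locus counter).
#' @return a `genealogy`: `parent` (1-based, 0 at the root), `time`
#'   (generations), `n_leaves`, `leaf_pop`.
#' @export
simulate_genealogy <- function(model, samples, seed, stream = 0) {
  cm <- compile_model(model)
  leaf_pop <- sampled_pop_vector(model, samples)
  g <- cpp_sim_genealogy(cm, match(leaf_pop, cm$pops), as.numeric(seed),
                         as.numeric(stream))
  structure(list(parent = g$parent, time = g$time, n_leaves = g$n_leaves,
                 leaf_pop = leaf_pop), class = "genealogy")
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Mutation count is Poisson(mu x total branch length x locus length);
#' mutations land uniformly on branches at distinct positions; carriers are
#' the subtending leaves, so every emitted site is biallelic.
#'
#' @param tree a `genealogy`.
#' @param locus a [locus_config()].
#' @param seed,stream RNG seed and sub-stream.
#' @return list with `pos` (ascending bp) and `geno` (sites x haplotypes
#'   0/1 matrix).
#' @export
drop_mutations <- function(tree, locus, seed, stream = 0) {
  m <- cpp_drop_mutations(tree$parent, tree$time, tree$n_leaves,
                          locus$mu, locus$length_bp,
                          as.numeric(seed), as.numeric(stream))
  list(pos = as.integer(m$pos), geno = m$geno)
}

#' Simulate a multi-locus haplotype dataset
#'
#' Draws `n_loci` independent genealogy + mutation realizations and pairs
#' haplotypes into diploid individuals within populations. Locus `i` is
#' reproducible in isolation: its RNG stream is derived from `(seed, i)`.
#'
#' @param model a `demographic_model`.
#' @param samples named vector of diploid counts.
#' @param locus a [locus_config()].
#' @param seed integer seed.
#' @param keep_trees retain genealogies (needed for coalescence-time
#'   extraction).
#' @return a `haplotype_dataset`: `loci` (list of `pos`/`geno`),
#'   `samples` (data.frame individual/population/continent), `locus_length`,
#'   `masks` (NULL until [apply_mask()]), optionally `trees`.
#' @export
simulate_dataset <- function(model, samples, locus = locus_config(), seed,
                             keep_trees = FALSE) {
  cm <- compile_model(model)
  leaf_pop <- sampled_pop_vector(model, samples)
  pop_idx <- match(leaf_pop, cm$pops)
  loci <- vector("list", locus$n_loci)
  trees <- if (keep_trees) vector("list", locus$n_loci) else NULL
  for (i in seq_len(locus$n_loci)) {
    g <- cpp_sim_genealogy(cm, pop_idx, as.numeric(seed), as.numeric(i))
    m <- cpp_drop_mutations(g$parent, g$time, g$n_leaves,
                            locus$mu, locus$length_bp,
                            as.numeric(seed), as.numeric(i))
    loci[[i]] <- list(pos = as.integer(m$pos), geno = m$geno)
    if (keep_trees) {
      trees[[i]] <- structure(list(parent = g$parent, time = g$time,
                                   n_leaves = g$n_leaves,
                                   leaf_pop = leaf_pop), class = "genealogy")
    }
  }
  cont <- model$populations$continent[match(names(samples),
                                            model$populations$name)]
  sample_df <- data.frame(
    individual = unlist(lapply(seq_along(samples), function(j) {
      sprintf("%s_%03d", names(samples)[j], seq_len(samples[[j]]))
    })),
    population = rep(names(samples), times = as.integer(samples)),
    continent = rep(cont, times = as.integer(samples)),
    stringsAsFactors = FALSE)
  structure(list(loci = loci, samples = sample_df,
                 locus_length = locus$length_bp, masks = NULL,
                 trees = trees),
            class = "haplotype_dataset")
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat(sprintf("haplotype_dataset: %d loci x %s bp, %d diploids (%d pops)%s\n",
              length(x$loci), format(x$locus_length, big.mark = ","),
              nrow(x$samples), length(unique(x$samples$population)),
              if (is.null(x$masks)) "" else ", masked"))
  invisible(x)
}

# haplotype column indices for a population (2 per diploid)
hap_indices <- function(dataset, pop) {
  ind <- which(dataset$samples$population == pop)
  sort(c(2L * ind - 1L, 2L * ind))
}

#' Pairwise coalescence times from recorded genealogies
#'
#' For each locus, the TMRCA of haplotype pairs drawn across (or, when
#' `popA == popB`, within) the two populations. Pairs can be subsampled per
#' locus to bound cost.
#'
#' @param trees list of `genealogy` objects (e.g. `dataset$trees`).
#' @param popA,popB population labels.
#' @param max_pairs_per_locus cap on pairs used per locus.
#' @param seed seed for pair subsampling.
#' @return numeric vector of coalescence times (generations).
#' @export
pair_coalescence_times <- function(trees, popA, popB,
                                   max_pairs_per_locus = Inf, seed = 1) {
  if (length(trees) == 0) return(numeric(0))
  lp <- trees[[1]]$leaf_pop
  ia <- which(lp == popA)
  ib <- which(lp == popB)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("input error: population absent from sample")
  }
  if (popA == popB) {
    if (length(ia) < 2) stop("input error: need >= 2 haplotypes for within-population pairs")
    pairs <- t(combn(ia, 2))
  } else {
    pairs <- as.matrix(expand.grid(a = ia, b = ib))
  }
  set.seed(seed)
  out <- lapply(trees, function(tr) {
    pr <- pairs
    if (nrow(pr) > max_pairs_per_locus) {
      pr <- pr[sample.int(nrow(pr), max_pairs_per_locus), , drop = FALSE]
    }
    cpp_pair_mrca(tr$parent, tr$time, pr)
  })
  unlist(out)
}
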