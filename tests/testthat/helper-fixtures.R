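# Hand-built fixtures shared across test files.

# haplotype_dataset from explicit genotype matrices (sites x haplotypes,
# two consecutive columns per diploid individual)
make_dataset <- function(genos, pops, continents = NULL, locus_length = 100,
                         pos = NULL) {
  if (is.matrix(genos)) genos <- list(genos)
  n_hap <- ncol(genos[[1]])
  stopifnot(n_hap %% 2 == 0, length(pops) == n_hap / 2)
  if (is.null(continents)) continents <- rep("cont1", length(pops))
  loci <- lapply(seq_along(genos), function(i) {
    g <- genos[[i]]
    p <- if (is.null(pos)) seq_len(nrow(g)) else pos[[i]]
    list(pos = as.integer(p), geno = g)
  })
  structure(list(
    loci = loci,
    samples = data.frame(
      individual = sprintf("%s_%03d", pops, stats::ave(seq_along(pops),
                                                       pops, FUN = seq_along)),
      population = pops, continent = continents,
      stringsAsFactors = FALSE),
    locus_length = locus_length, masks = NULL, trees = NULL),
    class = "haplotype_dataset")
}

# symmetric four-population clade history ((A,B),(C,D)) with no migration
clade_model <- function(ne = 3000, t_inner = 500, t_outer = 1500) {
  structure(list(
    populations = data.frame(name = c("A", "B", "C", "D", "AB", "CD", "R"),
                             continent = c("w", "w", "e", "e", "anc", "anc",
                                           "anc")),
    splits = data.frame(
      time_gen = c(t_inner, t_inner, t_outer),
      child_a = c("A", "C", "AB"), child_b = c("B", "D", "CD"),
      parent = c("AB", "CD", "R"), stringsAsFactors = FALSE),
    sizes = data.frame(
      population = c("A", "B", "C", "D", "AB", "CD", "R"),
      start_gen = c(0, 0, 0, 0, t_inner, t_inner, t_outer),
      end_gen = c(t_inner, t_inner, t_inner, t_inner, t_outer, t_outer, Inf),
      ne = ne),
    migrations = data.frame(source = character(0), dest = character(0),
                            rate = numeric(0), start_gen = numeric(0),
                            end_gen = numeric(0)),
    pulses = data.frame(time_gen = numeric(0), from_pop = character(0),
                        into_pop = character(0), proportion = numeric(0)),
    generation_time_years = 28.7), class = "demographic_model")
}

# random small genotype matrix with both alleles present somewhere
random_geno <- function(n_sites, n_hap, seed) {
  set.seed(seed)
  g <- matrix(rbinom(n_sites * n_hap, 1, runif(1, 0.2, 0.6)),
              n_sites, n_hap)
  keep <- rowSums(g) > 0 & rowSums(g) < n_hap
  g[keep, , drop = FALSE]
}
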