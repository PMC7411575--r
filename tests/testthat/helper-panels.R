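# hand-built fixtures used across test files

# panel from an explicit individual x site genotype matrix
toy_panel <- function(geno, populations = rep("P1", nrow(geno)),
                      multiallelic = rep(FALSE, ncol(geno))) {
  geno <- as.matrix(geno)
  genotype_panel(
    geno,
    data.frame(contig = "c1", pos = seq_len(ncol(geno)),
               ref = "A", alt = "T", multiallelic = multiallelic,
               stringsAsFactors = FALSE),
    data.frame(id = paste0("ind", seq_len(nrow(geno))),
               population = populations, stringsAsFactors = FALSE))
}

# random biallelic panel at Hardy-Weinberg equilibrium, common frequencies
# across populations (no differentiation)
hw_panel <- function(n_per_pop, n_loci, pops = c("A", "B"), seed = 1,
                     miss = 0) {
  set.seed(seed)
  p <- runif(n_loci, 0.1, 0.9)
  n <- n_per_pop * length(pops)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (miss > 0) g[runif(length(g)) < miss] <- NA
  toy_panel(g, populations = rep(pops, each = n_per_pop))
}

# genealogy object built by hand (leaves 1..n at time 0)
hand_genealogy <- function(edge, node_time, leaf_deme) {
  structure(list(n = length(leaf_deme), edge = edge, node_time = node_time,
                 leaf_deme = leaf_deme, labels = unique(leaf_deme)),
            class = "genealogy")
}

# single-population constant-size scenario for generator-level checks
single_deme_scenario <- function(n_dip, target_sites, N = 1000,
                                 sites_per_genealogy = 1, miss = 0) {
  sc <- study_scenario(target_sites = target_sites, missing_rate = miss,
                       sites_per_genealogy = sites_per_genealogy)
  sc$demography <- demography(c(Pop = N))
  sc$sample_sizes <- c(Pop = n_dip)
  sc$regions <- c(Pop = "Pop")
  sc
}
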