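#' Study-like simulation scenarios
#'
#' A scenario bundles a generating demography, per-population diploid sample
#' sizes, a target polymorphic site count and a missingness rate -- everything
#' [make_study_like_panel()] needs to produce a panel shaped like a real
#' GBS survey.
#'
#' The `"survey10"` preset emulates a ten-site national survey of an invasive
#' insect: 10 populations in two regions of five ("North": Coromandel,
#' Ruakura, Taranaki, Wellington, Greymouth; "South": Lincoln, Ophir,
#' MararoaDowns, Mossburn, Fortrose), diploid sample sizes
#' 16,16,15,16,16,15,15,16,16,16, ~52k biallelic SNPs with 10% missingness.
#' Its generating demography follows a two-route incursion with founding
#' bottlenecks: each region's populations (N_e = 5000, within-region
#' migration 1e-3, between-region 5e-5) trace back to a regional founder that
#' entered 150 generations ago through a bottleneck (N_e = 2000), and the two
#' founders merge into a large ancestral source (N_e = 1e5) 250 generations
#' ago.
#'
#' @param name preset name; currently `"survey10"`.
#' @param target_sites number of polymorphic biallelic sites to generate.
#' @param missing_rate genotype missingness probability.
#' @param sites_per_genealogy sites sharing one genealogy (a crude stand-in
#'   for GBS linkage blocks; 1 gives fully independent sites).
#' @return an object of class `"study_scenario"`; fields may be modified
#'   before passing to [make_study_like_panel()].
#' @export
study_scenario <- function(name = "survey10", target_sites = NULL,
                           missing_rate = NULL, sites_per_genealogy = NULL) {
  if (!identical(name, "survey10")) stop("unknown scenario preset: ", name)
  pops <- c("Coromandel", "Ruakura", "Taranaki", "Wellington", "Greymouth",
            "Lincoln", "Ophir", "MararoaDowns", "Mossburn", "Fortrose")
  region <- rep(c("North", "South"), each = 5L)
  n_dip <- c(16L, 16L, 15L, 16L, 16L, 15L, 15L, 16L, 16L, 16L)
  nd <- length(pops)
  mig <- matrix(5e-5, nd, nd)
  for (r in unique(region)) {
    i <- which(region == r)
    mig[i, i] <- 1e-3
  }
  diag(mig) <- 0
  events <- list()
  # backward: regional populations collapse into their founders at T_intro,
  # founders sit in a bottleneck, then merge into the ancestral source
  t_intro <- 150; t_anc <- 250
  for (i in 2:5) events <- c(events, list(ev_mass_move(t_intro, pops[i], pops[1L])))
  for (i in 7:10) events <- c(events, list(ev_mass_move(t_intro, pops[i], pops[6L])))
  events <- c(events,
              list(ev_migration(t_intro, c(pops[1L], pops[6L]), 0),
                   ev_resize(t_intro, pops[1L], 2000),
                   ev_resize(t_intro, pops[6L], 2000),
                   ev_mass_move(t_anc, pops[6L], pops[1L]),
                   ev_resize(t_anc, pops[1L], 1e5)))
  dem <- demography(setNames(rep(5000, nd), pops), migration = mig,
                    events = events)
  structure(list(name = name, demography = dem,
                 sample_sizes = setNames(n_dip, pops),
                 regions = setNames(region, pops),
                 target_sites = if (is.null(target_sites)) 52051L else as.integer(target_sites),
                 missing_rate = if (is.null(missing_rate)) 0.10 else missing_rate,
                 sites_per_genealogy = if (is.null(sites_per_genealogy)) 50L
                                       else as.integer(sites_per_genealogy)),
            class = "study_scenario")
}

#' @export
print.study_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d populations, %d diploids, %d target sites, %.0f%% missing\n",
              x$name, length(x$sample_sizes), sum(x$sample_sizes),
              x$target_sites, 100 * x$missing_rate))
  invisible(x)
}

#' Generate a study-like genotype panel
#'
#' Simulates genealogies under the scenario's demography (one genealogy per
#' `sites_per_genealogy` sites), drops infinite-sites mutations until the
#' target polymorphic biallelic site count is reached, pairs haplotypes into
#' diploids and injects missingness. All retained sites are biallelic and
#' polymorphic before missingness by construction. The per-genealogy mutation
#' rate is calibrated from a deterministic pilot batch of tree lengths, so
#' the whole panel is a function of `(scenario, seed)` alone.
#'
#' @param scenario a [study_scenario()].
#' @param seed integer seed.
#' @return a [genotype_panel()] with the scenario stored in
#'   `attr(, "scenario")`.
#' @export
make_study_like_panel <- function(scenario, seed) {
  stopifnot(inherits(scenario, "study_scenario"))
  dem <- scenario$demography
  samp <- 2L * scenario$sample_sizes
  target <- scenario$target_sites
  spg <- scenario$sites_per_genealogy

  # calibrate the per-genealogy mutation rate off pilot tree lengths
  pilot_L <- vapply(1:20, function(r) {
    g <- simulate_genealogy(dem, samp, seed = derive_seed(seed, 100L),
                            replicate = r)
    sum(g$node_time[g$edge[, 1L]] - g$node_time[g$edge[, 2L]])
  }, numeric(1))
  mu_tot <- spg / mean(pilot_L)

  blocks <- list()
  total <- 0L
  g_idx <- 0L
  max_trees <- ceiling(20 * target / spg) + 50L
  while (total < target) {
    g_idx <- g_idx + 1L
    if (g_idx > max_trees)
      stop("failed to reach target site count after ", max_trees, " genealogies")
    gen <- simulate_genealogy(dem, samp, seed = derive_seed(seed, 101L),
                              replicate = g_idx)
    h <- drop_mutations(gen, mu_per_site = mu_tot, n_sites = 1,
                        seed = derive_seed(seed, 200L + g_idx))
    if (nrow(h$haps) == 0L) next
    blocks[[length(blocks) + 1L]] <- h$haps
    total <- total + nrow(h$haps)
    deme_labels <- h$deme
  }
  haps <- do.call(rbind, blocks)[seq_len(target), , drop = FALSE]
  panel <- diploidize(list(haps = haps, deme = deme_labels),
                      seed = derive_seed(seed, 300L))
  panel <- inject_missingness(panel, scenario$missing_rate,
                              seed = derive_seed(seed, 301L))
  attr(panel, "scenario") <- scenario
  panel
}
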