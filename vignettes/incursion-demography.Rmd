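---
title: "Inferring incursion demography from GBS SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring incursion demography from GBS SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incursim)
```

## The problem

A recently introduced pest species — the motivating case is the Argentine
stem weevil (*Listronotus bonariensis*) in New Zealand — leaves a signature
of its invasion history in the site frequency spectrum (SFS) of its present
populations. Given a reduced-representation (GBS) SNP panel from populations
either side of a geographic barrier, we want to know: did the species arrive
once and then spread, or through multiple routes? Was the introduction
accompanied by a strong founding bottleneck? Is there ongoing gene flow
between the regional groups?

`incursim` implements the full analysis chain for this question: a
structured-coalescent simulator, a synthetic-panel generator that emulates
the survey design, the standard genotype QC cascade, diversity and
differentiation statistics, folded-SFS construction with hypergeometric
projection, and Monte-Carlo composite-likelihood fitting of competing
two-population incursion models ranked by delta likelihood and AIC.

## The coalescent engine

The engine simulates the structured coalescent backward in time. Each deme
carries a diploid effective size `N`, so a pair of lineages in it coalesces
at rate `1/(2N)` per generation; lineages migrate between demes at backward
per-lineage rates `m[i,j]`; a time-ordered event list changes sizes, growth
rates and migration, and `mass_move` events relocate lineages (the backward
view of a founding or dispersal event). Exponential growth is parameterized
forward in time: a deme with present size `N` and rate `r` has size
`N * exp(-r * t)` at time `t` before present, and events can re-anchor the
rate. Waiting times are sampled exactly, by inverting the cumulative
coalescent hazard through growth phases — no Euler stepping — and a
demography whose active demes can never share a lineage raises an explicit
"cannot coalesce" error (after `max_time = 1e9` generations at the latest)
instead of hanging.

All randomness flows from one integer seed through a counter-based
splitmix64 stream in compiled code, so every result is bit-reproducible
given `(demography, samples, seed, replicate)`, independent of R's RNG
state. Replicate `r` of a batch run is the same genealogy as
`simulate_genealogy(..., replicate = r)`.

```{r engine}
dem <- demography(c(A = 1000))
g <- simulate_genealogy(dem, c(A = 6), seed = 1)
g
head(branch_length_sfs(g))
```

### Expected SFS and variance reduction

`expected_sfs()` estimates the expected proportion of segregating sites per
frequency class by averaging subtended branch lengths over replicate
genealogies (the infinite-sites identity: a branch under which `i` of `n`
leaves sit contributes its length to unfolded entry `i`). Two layers of
conditional Monte Carlo sharpen the estimate without biasing it:

* **Duration conditioning.** Within any phase where every deme holding two
  or more lineages has zero growth, the time to the next event is
  exponential and independent of which event occurs, so the realized
  inter-event duration is replaced by its conditional expectation given the
  event sequence. During growth phases the realized duration is used.
* **Exchangeable class conditioning.** In a single-deme demography all
  lineages are exchangeable, and a branch among `k` ancestral lineages
  subtends `i` of the `n` leaves with probability
  `choose(n-i-1, k-2) / choose(n-1, k-1)`. Accruing that exact law per
  level removes the topology noise too; for a constant-size deme the
  estimate then coincides with the analytic `1/i` spectrum to floating
  point.

Both layers are controlled by `variance_reduction` (default `TRUE`;
`FALSE` restores plain realized accrual, which the test suite uses to check
that batch estimates agree with per-tree accumulation bit-for-bit).

## The synthetic-data generator

`make_study_like_panel()` turns a demography into a diploid genotype panel:
genealogies are simulated (one per `sites_per_genealogy = 50` sites by
default, a crude stand-in for GBS linkage blocks — it gives LD pruning
something to remove), infinite-sites mutations are dropped with a rate
calibrated from a pilot batch of tree lengths, haplotypes are paired
randomly within deme into 0/1/2 genotypes, and genotypes are masked
missing independently at the scenario's rate. Every site is biallelic and
polymorphic before masking by construction; sites live on one artificial
contig at consecutive positions, and the reference allele is the ancestral
one (real VCFs are treated as unpolarized — all downstream spectra are
folded, so polarization is never needed).

The `"survey10"` preset encodes the study design the package targets: ten
populations in two regions of five, diploid sample sizes
16,16,15,16,16,15,15,16,16,16 (157 individuals), ~52k SNPs, 10%
missingness. Its generating demography is a two-route incursion with
founding bottlenecks: within-region migration `1e-3`, between-region
`5e-5`, per-population `N = 5000`, regional founders entering 150
generations ago through a bottleneck of `N = 2000`, merging into a large
ancestral source (`N = 1e5`) at 250 generations. Those values were chosen
once to produce diversity and differentiation of the magnitude reported for
real surveys of this kind (pairwise F_ST of a few percent, regional F_ST
around 0.01–0.02) and are not tuned thereafter. What the generator does
*not* emulate: genotyping error, allele dropout, depth variation, linkage
*within* the restriction fragment beyond the shared-genealogy
approximation, and selection. Tests passing on these panels therefore
validate the statistical machinery, not the wet-lab realities of GBS.

## QC cascade

`filter_sites()` applies, in this order: remove sites with more than two
alleles; remove sites with pooled minor allele frequency strictly below
0.05 (a site at exactly 0.05 is kept); remove sites missing in strictly
more than 20% of individuals. `filter_individuals()` then removes
individuals missing strictly more than 20% of the retained loci — the
site-then-individual order matters and is exercised by the tests. MAF is
pooled across populations because the filter runs before any
population-level analysis. `ld_prune()` interprets the study's "correlation
threshold of 0.1" as squared Pearson correlation r² on 0/1/2 dosages within
a 50-site window sliding by 10 (the window and step of the usual pruning
tools; both are exposed as parameters since the convention is not
universal). Removal is deterministic: of the worst pair, the site with more
missing genotypes goes, ties broken toward the later position.

## Diversity and differentiation

`heterozygosity_stats()` reports per-population observed and expected
heterozygosity and the multi-locus inbreeding coefficient
`F = 1 - mean(Ho)/mean(He)`. `pairwise_fst()` is Weir & Cockerham's (1984)
theta with the unequal-sample-size variance components, combined across
loci as a ratio of sums (ratio of averages); negative per-locus components
are kept, so panmictic estimates centre on zero and can be slightly
negative. `grouped_fst()` pools populations into groups (e.g. North/South
of a mountain barrier) before the same estimator; whether a published
"group F_ST" is a pooled estimate or a mean of per-locus values is often
unstated — the pooled ratio-of-averages is what this package computes, and
says so.

One subtlety worth knowing when calibrating against island-model theory:
Weir–Cockerham theta references *between-deme* pairs, whereas Wright's
island-model F_ST (e.g. `1/(1+16Nm)` for two demes exchanging lineages at
backward rate `m`) references the *total* population. With two demes the
scales convert exactly by `theta / (2 - theta)`; the calibration tests and
the acceptance script apply that conversion, and at 2,000+ loci the
converted estimates land within a couple of percent of theory.

## Folded SFS and projection

`sfs_from_panel()` tallies alternate-allele counts per site and population
group. Missing data are handled by hypergeometric projection
(`project_to`): each site's contribution is spread over the projected
counts by the expectation of drawing `j` derived alleles in a subsample,
and sites with fewer non-missing haploid calls than the projection size are
dropped. Projected counts are kept real-valued — rounding would bias the
composite likelihood, which accepts fractional cell counts. Folding is by
minor allele; for a joint 2D spectrum cells are combined with their
complement by total minor-allele count across both populations, and
fold-boundary cells are kept un-doubled. The plain-text SFS format (header
line with sizes and `FOLDED`/`UNFOLDED`, then the full count grid including
monomorphic cells, serialized at full double precision) round-trips
bit-stably.

## Demographic models and fitting

Five two-deme topologies cover the incursion hypotheses (single vs multiple
routes, with or without founding bottlenecks, with or without isolated
sources), each with an optional symmetric migration rate active from the
present back to when the two sampled demes cease to exist separately. The
compiler documents one concrete event mapping per topology (the published
figures underlying such analyses give topology only); in particular, in
model ii the North/South split occurs during the small founding phase — a
choice, stated rather than asserted as the only reading.

The composite log-likelihood is multinomial over polymorphic folded cells,
`sum(m_e * log(max(p_e, min_p)))`, natural log, with the floor
`1/(10 * n_sims * n_cells)` sitting below the Monte-Carlo resolution of the
expected probabilities. The saturated bound (`max_observed_log_likelihood`)
uses the observed proportions; its gap to a fitted model is the delta
likelihood used for ranking, with `AIC = 2k - 2 lnL` alongside.

`fit_model()` is cycle-based conditional maximization: log-uniform
initialization (best of a screened pool of 8 candidate starts), then per
cycle a bounded golden-section line search on each free parameter in turn —
sizes and times on log scale — under a cycle-specific simulation seed
shared by all proposals (common random numbers), plus one extra line search
along the *common scale* of all size/time parameters. That extra direction
matters: a normalized SFS is exactly invariant to rescaling all sizes and
times together, so axis-aligned moves stall on the resulting diagonal
ridge. For the same reason, absolute parameter values are only identified
once the scale is anchored externally — fix one parameter (typically the
ancestral size) via `bounds = list(N_A = c(x, x))`, the analogue of
fastsimcoal's known mutation rate. Fixed parameters are excluded from the
search and from `k` in the AIC.

Because the best-ever search value is a maximum over hundreds of noisy
Monte-Carlo evaluations, it is upward-biased, and the bias grows with the
number of parameters searched — enough to corrupt AIC comparisons between
models of different size. The reported `lnl_est` is therefore a final
re-evaluation of the best parameters on a fresh simulation set (20x the
search precision by default, seeded independently of the search path);
the raw best-ever value is kept as `lnl_best_search`, which never
decreases with `n_cycles`. Fitting two models with the same `seed` pairs
their final evaluation streams, sharpening comparisons further.
`compare_models()` aggregates replicate runs per model, excludes (and
flags) runs with non-finite delta likelihood, and ranks by mean delta
likelihood with AIC reported alongside, ties toward fewer parameters.

Default desk-scale settings are `n_sims = 2000`, `n_cycles = 10`; the
study-scale settings (1e6 simulations, 60 cycles) are ordinary argument
values. Search bounds default to sizes 10–1e7 diploids, times 10–1e5
generations, `m` 0–0.1, all overridable.

```{r fit, eval = FALSE}
truth <- list(N_N = 10000, N_S = 5000, T_intro = 1500, N_A = 20000)
sc <- study_scenario(target_sites = 2500, missing_rate = 0,
                     sites_per_genealogy = 5)
sc$demography <- build_model("iv", FALSE, truth)
sc$sample_sizes <- c(N = 10, S = 10)
panel <- make_study_like_panel(sc, seed = 101)
obs <- sfs_from_panel(panel, list(N = "N", S = "S"))
f <- fit_model(obs, model_spec("iv", bounds = list(N_A = c(2e4, 2e4))),
               n_sims = 2000, n_cycles = 10, seed = 11)
f
```

## Numerical and design notes

* **Problem sizes.** The shipped tests and the acceptance script run the
  engine at survey scale (tens of thousands of sites, hundreds of haploid
  genomes) but keep fitting experiments at 2,500-site panels with 10+10
  diploids and desk-scale optimizer settings — sizes chosen so a full run
  is a coffee break on one core while still leaving the statistical
  signals (parameter recovery within tens of percent, correct model
  ranking) clearly resolvable.
* **Mutation model.** Infinite sites, no recombination within a genealogy,
  no back mutation. The mutation assumptions behind published SFS fits of
  this kind are rarely stated; infinite sites is assumed here and said so.
* **Resize semantics.** A `resize` event re-anchors the size and keeps the
  growth rate; `set_growth` re-anchors the rate at the current size. Model
  compilers always pair them explicitly, so no behavior depends on the
  convention.
* **Degenerate inputs.** One-lineage samples give a one-leaf genealogy with
  zero branch length; all-missing populations, empty panels, unassigned
  populations in groupings, already-folded spectra, upward projections and
  sub-2 projections all raise immediate, named errors.
* **Known limitations.** Two sampled demes only in the model compilers; no
  confidence intervals on fitted parameters (a block bootstrap would be the
  natural extension); composite likelihood treats sites as independent,
  which the generator's shared-genealogy blocks deliberately violate —
  as in real GBS data, this inflates likelihood contrasts but leaves point
  estimates consistent.
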