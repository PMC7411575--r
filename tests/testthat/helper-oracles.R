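# independent oracles, written against the published formulas rather than
# the package's code paths

# Weir & Cockerham (1984) theta for two populations, scalar per-locus loop
# (ratio of averages across loci); g1, g2 are individual x site 0/1/2
# matrices with NA for missing
wc84_oracle <- function(g1, g2) {
  num <- den <- 0
  r <- 2
  for (s in seq_len(ncol(g1))) {
    x1 <- g1[, s][!is.na(g1[, s])]
    x2 <- g2[, s][!is.na(g2[, s])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- mean(c(n1, n2))
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    bb <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + bb + cc
  }
  num / den
}

# brute-force SFS projection: average derived-allele tally over every
# subsample of size `to` of a site's non-missing haploid alleles
project_site_oracle <- function(alleles, to) {
  # alleles: 0/1 vector of the site's observed haploid alleles
  n <- length(alleles)
  stopifnot(to <= n)
  subsets <- utils::combn(n, to)
  counts <- numeric(to + 1)
  for (k in seq_len(ncol(subsets))) {
    d <- sum(alleles[subsets[, k]])
    counts[d + 1] <- counts[d + 1] + 1
  }
  counts / ncol(subsets)
}

# mean TMRCA / total branch length for a demography via msprime (test-only
# cross-implementation oracle); demography expressed as python source lines
msprime_stats <- function(dem_py, samples_py, reps, seed) {
  script <- c(
    "import json, msprime",
    dem_py,
    sprintf("reps = %d", reps),
    "tm = tl = 0.0",
    sprintf(paste0("for ts in msprime.sim_ancestry(samples=%s, demography=d,",
                   " ploidy=2, num_replicates=reps, random_seed=%d):"),
            samples_py, seed),
    "    t = ts.first()",
    "    tm += t.time(t.root); tl += t.total_branch_length",
    "print(json.dumps([tm/reps, tl/reps]))")
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("msprime oracle failed: ", paste(out, collapse = "\n"))
  as.numeric(jsonlite::fromJSON(out[length(out)]))
}

# mean TMRCA / total length from the package's simulator
incursim_stats <- function(dem, samp, reps, seed) {
  tm <- tl <- 0
  for (r in seq_len(reps)) {
    g <- simulate_genealogy(dem, samp, seed = seed, replicate = r)
    tm <- tm + max(g$node_time)
    tl <- tl + sum(g$node_time[g$edge[, 1]] - g$node_time[g$edge[, 2]])
  }
  c(tm, tl) / reps
}
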