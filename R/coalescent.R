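#' Simulate one genealogy under the structured coalescent
#'
#' Runs the backward-in-time structured coalescent: within a deme of current
#' size N(t), each pair of lineages coalesces at instantaneous rate 1/(2N(t))
#' per generation; lineages migrate at the configured backward rates; events
#' are applied exactly at their times. Waiting times are sampled exactly
#' (inversion of the cumulative hazard through growth phases), not by time
#' stepping. Identical `(demography, samples, seed, replicate)` give
#' bit-identical trees.
#'
#' @param dem a [demography()].
#' @param samples named integer vector of haploid sample counts per deme
#'   (names are deme labels), all sampled at time 0.
#' @param seed integer seed.
#' @param replicate replicate index (>= 1); replicate r of a batch run (see
#'   [expected_sfs()]) equals `simulate_genealogy(..., replicate = r)`.
#' @return an object of class `"genealogy"`: a binary ultrametric tree with
#'   `edge` (parent, child; nodes 1..n are leaves in sample order, internal
#'   nodes n+1..2n-1 in coalescence order, the root last), `node_time` in
#'   generations, and `leaf_deme` labels.
#' @examples
#' dem <- demography(c(A = 1000))
#' g <- simulate_genealogy(dem, c(A = 4), seed = 1)
#' @export
simulate_genealogy <- function(dem, samples, seed, replicate = 1) {
  stopifnot(inherits(dem, "demography"))
  samp <- resolve_samples(dem, samples)
  n <- sum(samp)
  if (n < 1L) stop("total sample size must be >= 1")
  if (n == 1L) {
    d <- which(samp > 0L)
    return(structure(list(n = 1L, edge = matrix(integer(0), 0, 2),
                          node_time = 0, leaf_deme = dem$labels[d],
                          labels = dem$labels), class = "genealogy"))
  }
  out <- sim_genealogy_cpp(dem_to_cpp(dem), samp, as.integer(seed),
                           as.integer(replicate) - 1L)
  structure(list(n = n, edge = out$edge, node_time = out$node_time,
                 leaf_deme = dem$labels[out$leaf_deme], labels = dem$labels),
            class = "genealogy")
}

resolve_samples <- function(dem, samples) {
  if (any(samples < 0)) stop("sample counts must be >= 0")
  samp <- integer(length(dem$labels))
  if (!is.null(names(samples))) {
    i <- match(names(samples), dem$labels)
    if (anyNA(i)) stop("unknown deme in samples: ",
                       paste(names(samples)[is.na(i)], collapse = ", "))
    samp[i] <- as.integer(samples)
  } else {
    if (length(samples) != length(dem$labels))
      stop("unnamed samples must have one count per deme")
    samp <- as.integer(samples)
  }
  samp
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Coalescent genealogy:", x$n, "leaves, TMRCA =",
      format(max(x$node_time)), "generations\n")
  invisible(x)
}

#' Per-branch contribution to the site frequency spectrum
#'
#' Under the infinite-sites model, a branch subtending i of the n sampled
#' leaves contributes its length to unfolded SFS entry i (or to joint entry
#' (i_1, i_2, ...) per deme when `by_deme`). Every non-root branch contributes
#' its full length to exactly one entry; the root branch (which would subtend
#' all n leaves, i.e. a monomorphic class) is excluded, so the values sum to
#' the total tree length below the root.
#'
#' @param gen a [simulate_genealogy()] result.
#' @param by_deme if TRUE, key entries by comma-separated per-deme leaf counts
#'   (deme order as in the demography); otherwise by the total leaf count.
#' @return named numeric vector mapping SFS entry to total branch length.
#' @export
branch_length_sfs <- function(gen, by_deme = FALSE) {
  stopifnot(inherits(gen, "genealogy"))
  n <- gen$n
  if (n < 2L) return(setNames(numeric(0), character(0)))
  n_nodes <- 2L * n - 1L
  demes <- gen$labels
  cnt <- matrix(0L, n_nodes, length(demes))
  cnt[cbind(seq_len(n), match(gen$leaf_deme, demes))] <- 1L
  # internal nodes are numbered in coalescence (time) order, so accumulating
  # child counts in edge order of increasing child-completion works by
  # processing edges sorted by child index after all children of earlier nodes
  edge <- gen$edge
  ord <- order(edge[, 2L])
  for (e in ord) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    cnt[p, ] <- cnt[p, ] + cnt[ch, ]
  }
  bl <- gen$node_time[edge[, 1L]] - gen$node_time[edge[, 2L]]
  key <- if (by_deme) {
    apply(cnt[edge[, 2L], , drop = FALSE], 1L, paste, collapse = ",")
  } else {
    as.character(rowSums(cnt[edge[, 2L], , drop = FALSE]))
  }
  out <- tapply(bl, key, sum)
  setNames(as.numeric(out), names(out))
}

#' Monte-Carlo expected site frequency spectrum
#'
#' Averages [branch_length_sfs()] over `n_sims` independent genealogies
#' (simulated in compiled code) and normalizes over polymorphic entries to
#' probabilities summing to 1: the expected proportion of segregating sites
#' falling in each frequency class under the demography. With `groups`, a
#' joint 2D spectrum over two population groups is produced. Deterministic
#' given the seed.
#'
#' @inheritParams simulate_genealogy
#' @param n_sims number of replicate genealogies (>= 1).
#' @param groups NULL for a 1D spectrum pooling all demes, or a named list of
#'   two character vectors of deme labels defining the two dimensions of a
#'   joint spectrum. Every deme with samples must be assigned.
#' @param fold if TRUE, fold by total minor-allele count before normalizing.
#' @param variance_reduction replace realized inter-event durations by their
#'   conditional expectations given the event sequence (conditional Monte
#'   Carlo; exact whenever every deme holding two or more lineages has zero
#'   growth, with automatic fallback to realized durations during growth
#'   phases). Unbiased either way; TRUE sharply reduces Monte-Carlo noise.
#' @return an object of class `"expected_sfs"` with entry probabilities over
#'   polymorphic cells (stored as a full `(n1+1) [x (n2+1)]` array indexed
#'   from allele count 0) plus simulation metadata.
#' @export
expected_sfs <- function(dem, samples, n_sims, seed, groups = NULL,
                         fold = FALSE, variance_reduction = TRUE) {
  stopifnot(inherits(dem, "demography"), n_sims >= 1)
  samp <- resolve_samples(dem, samples)
  if (sum(samp) < 2L) stop("need at least 2 sampled lineages")
  grp <- integer(length(dem$labels))
  pops <- "all"
  if (!is.null(groups)) {
    stopifnot(is.list(groups), length(groups) %in% 1:2)
    grp[] <- NA_integer_
    for (gi in seq_along(groups)) {
      i <- match(groups[[gi]], dem$labels)
      if (anyNA(i)) stop("unknown deme in groups")
      grp[i] <- gi - 1L
    }
    if (any(is.na(grp) & samp > 0L))
      stop("every sampled deme must be assigned to a group")
    grp[is.na(grp)] <- 0L
    pops <- names(groups)
    if (is.null(pops)) pops <- paste0("group", seq_along(groups))
  }
  mat <- branch_sfs_batch_cpp(dem_to_cpp(dem), samp, grp,
                              as.integer(n_sims), as.integer(seed),
                              isTRUE(variance_reduction))
  two_d <- ncol(mat) > 1L
  n <- if (two_d) c(sum(samp[grp == 0L]), sum(samp[grp == 1L])) else sum(samp)
  counts <- if (two_d) mat else mat[, 1L]
  if (fold) counts <- fold_array(counts, n)
  mask <- polymorphic_mask(n, folded = fold)
  tot <- sum(counts[mask])
  if (tot <= 0) stop("no polymorphic branch length observed; increase n_sims")
  probs <- counts
  probs[!mask] <- 0
  probs[mask] <- counts[mask] / tot
  structure(list(n = n, probs = probs, folded = fold, pops = pops,
                 n_sims = n_sims, seed = seed),
            class = "expected_sfs")
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat(sprintf("Expected %s SFS (%s), n = %s, %d simulations\n",
              if (length(x$n) == 2L) "joint 2D" else "1D",
              if (x$folded) "folded" else "unfolded",
              paste(x$n, collapse = " x "), x$n_sims))
  invisible(x)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Places mutations on branches as a Poisson process with per-branch mean
#' `branch length x mu_per_site x n_sites` (branch lengths in generations,
#' `mu_per_site` a per-site per-generation rate). Each mutation creates one
#' new biallelic site whose derived carriers are exactly the leaves under
#' that branch, so every site is polymorphic by construction.
#'
#' @param gen a [simulate_genealogy()] result.
#' @param mu_per_site mutation rate per site per generation (>= 0).
#' @param n_sites number of sites the rate applies to (total locus rate is
#'   `mu_per_site * n_sites`).
#' @param seed integer seed.
#' @return a list of class `"haplotypes"`: `haps`, a 0/1 integer matrix
#'   (segregating site x haploid sample), and `deme`, the per-haplotype deme
#'   labels.
#' @export
drop_mutations <- function(gen, mu_per_site, n_sites = 1, seed) {
  stopifnot(inherits(gen, "genealogy"), mu_per_site >= 0, n_sites >= 1)
  n <- gen$n
  empty <- function() structure(list(
    haps = matrix(0L, 0, n, dimnames = list(NULL, NULL)),
    deme = gen$leaf_deme), class = "haplotypes")
  if (n < 2L || mu_per_site == 0) return(empty())
  edge <- gen$edge
  bl <- gen$node_time[edge[, 1L]] - gen$node_time[edge[, 2L]]
  total <- sum(bl) * mu_per_site * n_sites
  res <- with_seed(seed, {
    n_mut <- rpois(1L, total)
    if (n_mut == 0L) NULL else {
      branch <- sample.int(length(bl), n_mut, replace = TRUE, prob = bl)
      leafsets <- descendant_leaves(gen)
      haps <- matrix(0L, n_mut, n)
      for (m in seq_len(n_mut))
        haps[m, leafsets[[edge[branch[m], 2L]]]] <- 1L
      haps
    }
  })
  if (is.null(res)) return(empty())
  structure(list(haps = res, deme = gen$leaf_deme), class = "haplotypes")
}

# list of leaf index vectors per node; node numbering puts children before
# parents, so a single pass over edges sorted by parent index suffices
descendant_leaves <- function(gen) {
  n <- gen$n
  n_nodes <- 2L * n - 1L
  ls <- vector("list", n_nodes)
  for (i in seq_len(n)) ls[[i]] <- i
  edge <- gen$edge
  ord <- order(edge[, 1L])
  for (e in ord) {
    p <- edge[e, 1L]
    ls[[p]] <- c(ls[[p]], ls[[edge[e, 2L]]])
  }
  ls
}
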