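#' Variant filter cascade
#'
#' Removes sites in the fixed order of the standard GBS QC cascade:
#' (1) sites with more than two alleles; (2) sites with pooled minor allele
#' frequency strictly below `maf_min` (computed over non-missing genotypes
#' across all individuals; a site at exactly the threshold is retained);
#' (3) sites missing in a strictly greater fraction than `max_site_missing`
#' of individuals (exactly the threshold is retained). The report records
#' how many sites each rule removed; the rule sets are disjoint because the
#' rules apply in order.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @param max_site_missing per-site missingness threshold (default 0.20).
#' @return list with the filtered `panel` and a `report` (class
#'   `"filter_report"`).
#' @export
filter_sites <- function(panel, maf_min = 0.05, max_site_missing = 0.20) {
  stopifnot(inherits(panel, "genotype_panel"))
  S <- ncol(panel$geno)
  if (S == 0L || nrow(panel$geno) == 0L) stop("empty panel")
  keep <- rep(TRUE, S)

  multi <- panel$sites$multiallelic
  n_multi <- sum(multi)
  keep[multi] <- FALSE

  g <- panel$geno
  nm <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * nm)
  maf <- pmin(p, 1 - p)
  maf[nm == 0L] <- 0  # all-missing or monomorphic-by-absence: MAF 0
  low_maf <- keep & maf < maf_min
  n_maf <- sum(low_maf)
  keep[low_maf] <- FALSE

  miss_frac <- colMeans(is.na(g))
  high_miss <- keep & miss_frac > max_site_missing
  n_miss <- sum(high_miss)
  keep[high_miss] <- FALSE

  report <- structure(list(
    input_sites = S, input_individuals = nrow(g),
    removed_multiallelic = n_multi, removed_maf = n_maf,
    removed_site_missing = n_miss, removed_individuals = 0L,
    retained_sites = sum(keep), retained_individuals = nrow(g)),
    class = "filter_report")
  list(panel = panel_subset(panel, site = which(keep)), report = report)
}

#' Individual filter
#'
#' Removes individuals whose missing fraction across the (already
#' site-filtered) loci strictly exceeds `max_ind_missing`. Run after
#' [filter_sites()]: the cascade order is sites first, then individuals.
#'
#' @param panel a site-filtered [genotype_panel()].
#' @param max_ind_missing per-individual missingness threshold (default 0.20).
#' @return list with the filtered `panel` and a `report`.
#' @export
filter_individuals <- function(panel, max_ind_missing = 0.20) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$geno) == 0L) stop("empty panel")
  miss <- rowMeans(is.na(panel$geno))
  keep <- miss <= max_ind_missing
  if (!any(keep)) stop("all individuals removed by the missingness filter")
  report <- structure(list(
    input_sites = ncol(panel$geno), input_individuals = nrow(panel$geno),
    removed_multiallelic = 0L, removed_maf = 0L, removed_site_missing = 0L,
    removed_individuals = sum(!keep),
    retained_sites = ncol(panel$geno), retained_individuals = sum(keep)),
    class = "filter_report")
  list(panel = panel_subset(panel, ind = which(keep)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:\n")
  cat(sprintf("  input: %d sites x %d individuals\n",
              x$input_sites, x$input_individuals))
  cat(sprintf("  removed sites: %d multi-allelic, %d low MAF, %d high missingness\n",
              x$removed_multiallelic, x$removed_maf, x$removed_site_missing))
  cat(sprintf("  removed individuals: %d\n", x$removed_individuals))
  cat(sprintf("  retained: %d sites x %d individuals\n",
              x$retained_sites, x$retained_individuals))
  invisible(x)
}

#' Linkage-disequilibrium pruning
#'
#' Slides a window of `window` sites (step `step`, within contig, sites in
#' position order) across the panel; within each window, while any retained
#' pair of sites has squared genotype correlation above `r2_threshold`
#' (Pearson r^2 on 0/1/2 dosages over individuals non-missing at both
#' sites), one site of the worst pair is removed. The removal choice is
#' deterministic: the site with more missing genotypes goes; if tied, the
#' later position. Passes repeat until a fixed point, so after completion no
#' window of the *pruned* panel contains a retained pair above the
#' threshold.
#'
#' @param panel a site-filtered [genotype_panel()].
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @param window window size in sites (default 50).
#' @param step step size in sites (default 10).
#' @return list with the pruned `panel` and `removed`, the removed site
#'   indices (relative to the input panel).
#' @export
ld_prune <- function(panel, r2_threshold = 0.1, window = 50, step = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (window < 2) stop("window must span at least 2 sites")
  stopifnot(step >= 1)
  S <- ncol(panel$geno)
  ord <- order(panel$sites$contig, panel$sites$pos)
  removed <- logical(S)
  n_miss <- colSums(is.na(panel$geno))

  # passes repeat until a fixed point: removals compact the retained list,
  # bringing formerly distant sites into a common window, so the guarantee
  # holds for windows over the *pruned* panel, not just the input
  repeat {
    any_removed <- FALSE
    for (ctg in unique(panel$sites$contig)) {
      idx <- ord[panel$sites$contig[ord] == ctg]
      idx <- idx[!removed[idx]]
      if (length(idx) < 2L) next
      starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
      for (st in starts) {
        win <- idx[st:min(st + window - 1L, length(idx))]
        repeat {
          live <- win[!removed[win]]
          if (length(live) < 2L) break
          C <- suppressWarnings(cor(panel$geno[, live, drop = FALSE],
                                    use = "pairwise.complete.obs"))
          r2 <- C^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          mx <- max(r2)
          if (mx <= r2_threshold) break
          pair <- which(r2 == mx, arr.ind = TRUE)[1L, ]
          a <- live[pair[1L]]; b <- live[pair[2L]]
          victim <- if (n_miss[a] > n_miss[b]) a
          else if (n_miss[b] > n_miss[a]) b
          else if (panel$sites$pos[a] > panel$sites$pos[b]) a else b
          removed[victim] <- TRUE
          any_removed <- TRUE
        }
      }
    }
    if (!any_removed) break
  }
  list(panel = panel_subset(panel, site = which(!removed)),
       removed = which(removed))
}
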