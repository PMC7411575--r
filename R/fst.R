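#' Pairwise Weir-Cockerham F_ST
#'
#' Weir & Cockerham's (1984) theta for each pair of populations: per locus,
#' the among-population (a), among-individual (b) and within-individual (c)
#' variance components are computed with the unequal-sample-size formulas
#' (per-locus sample sizes are the non-missing counts), and the multi-locus
#' estimate is the ratio of averages sum(a) / sum(a + b + c). Negative
#' per-locus components are retained, not truncated, so the combined
#' estimate stays unbiased and can be slightly negative under panmixia. Loci
#' monomorphic in a pair (or co-genotyped in fewer than two individuals per
#' side) contribute nothing to that pair; a pair with no usable locus is a
#' flagged missing value, not a silent zero.
#'
#' @param panel a site-filtered [genotype_panel()] with >= 2 populations.
#' @return an object of class `"fst_matrix"`: a symmetric matrix of
#'   multi-locus theta with zero diagonal; the summed numerator and
#'   denominator components are kept in attributes `"num"` and `"den"`.
#' @export
pairwise_fst <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  pops <- unique(panel$individuals$population)
  if (length(pops) < 2L) stop("need >= 2 populations")
  K <- length(pops)
  theta <- matrix(0, K, K, dimnames = list(pops, pops))
  num <- den <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    gi <- panel$geno[panel$individuals$population == pops[i], , drop = FALSE]
    gj <- panel$geno[panel$individuals$population == pops[j], , drop = FALSE]
    comp <- wc_components(gi, gj)
    num[i, j] <- num[j, i] <- comp$num
    den[i, j] <- den[j, i] <- comp$den
    theta[i, j] <- theta[j, i] <-
      if (is.na(comp$den) || comp$den == 0) NA_real_ else comp$num / comp$den
  }
  structure(theta, num = num, den = den, class = c("fst_matrix", "matrix"))
}

# Weir-Cockerham 1984 variance components for two populations, vectorized
# over loci; returns summed numerator (a) and denominator (a + b + c).
wc_components <- function(g1, g2) {
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(g1 == 1L, na.rm = TRUE)
  h2 <- colMeans(g2 == 1L, na.rm = TRUE)

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)  # already / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar  # / (r - 1)
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  use <- n1 >= 2 & n2 >= 2 & nbar > 1 & nc > 0 &
    is.finite(pbar) & pbar > 0 & pbar < 1
  if (!any(use)) return(list(num = NA_real_, den = NA_real_))
  list(num = sum(a[use]), den = sum((a + b + cc)[use]))
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Multi-locus Weir-Cockerham F_ST (ratio of averages):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Grouped F_ST
#'
#' Pools individuals by group (e.g. regions either side of a geographic
#' barrier) and computes [pairwise_fst()] over the groups. A grouping in
#' which each group holds exactly one population reduces to the
#' corresponding pairwise entries.
#'
#' @param panel a site-filtered [genotype_panel()].
#' @param grouping named character vector mapping every population to a
#'   group.
#' @return an `"fst_matrix"` over groups.
#' @export
grouped_fst <- function(panel, grouping) {
  stopifnot(inherits(panel, "genotype_panel"))
  pops <- unique(panel$individuals$population)
  unassigned <- setdiff(pops, names(grouping))
  if (length(unassigned))
    stop("population(s) not assigned to a group: ",
         paste(unassigned, collapse = ", "))
  panel$individuals$population <-
    unname(grouping[panel$individuals$population])
  pairwise_fst(panel)
}
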