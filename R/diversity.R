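#' Per-population heterozygosity and inbreeding statistics
#'
#' For each population and locus: observed heterozygosity Ho is the
#' heterozygote fraction among non-missing individuals; expected
#' heterozygosity He = 2p(1-p) with p the population allele frequency.
#' Population means are taken across loci with at least one non-missing
#' genotype in that population, and the population-level inbreeding
#' coefficient is the multi-locus F = 1 - mean(Ho)/mean(He) (flagged NA where
#' mean He is 0).
#'
#' @param panel a site-filtered [genotype_panel()] with >= 1 individual per
#'   population.
#' @return an object of class `"diversity_table"`: `summary`, a data.frame
#'   (population, n individuals, loci used, ho, he, f), and `per_locus`, a
#'   list of population x locus matrices `ho` and `he` for inspection.
#' @export
heterozygosity_stats <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  pops <- unique(panel$individuals$population)
  S <- ncol(panel$geno)
  ho <- he <- matrix(NA_real_, length(pops), S,
                     dimnames = list(pops, colnames(panel$geno)))
  summ <- data.frame(population = pops, n = NA_integer_, loci = NA_integer_,
                     ho = NA_real_, he = NA_real_, f = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(pops)) {
    g <- panel$geno[panel$individuals$population == pops[k], , drop = FALSE]
    nm <- colSums(!is.na(g))
    if (all(nm == 0L))
      stop("population has no non-missing genotypes: ", pops[k])
    p <- colSums(g, na.rm = TRUE) / (2 * nm)
    ho_k <- colMeans(g == 1L, na.rm = TRUE)
    he_k <- 2 * p * (1 - p)
    ho_k[nm == 0L] <- NA_real_
    he_k[nm == 0L] <- NA_real_
    ho[k, ] <- ho_k
    he[k, ] <- he_k
    mh <- mean(ho_k, na.rm = TRUE)
    mhe <- mean(he_k, na.rm = TRUE)
    summ$n[k] <- nrow(g)
    summ$loci[k] <- sum(nm > 0L)
    summ$ho[k] <- mh
    summ$he[k] <- mhe
    summ$f[k] <- if (mhe > 0) 1 - mh / mhe else NA_real_
  }
  structure(list(summary = summ, per_locus = list(ho = ho, he = he)),
            class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, ...) {
  cat("Per-population diversity (multi-locus means):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
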