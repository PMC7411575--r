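#' Diploid genotype panel
#'
#' The central data container: a genotype matrix (individual x site) coded
#' 0/1/2 (alternate-allele dosage) with NA for missing, site metadata (contig,
#' 1-based position, ref/alt alleles, multi-allelic flag) and individual
#' metadata (identifier, population label).
#'
#' @param geno integer matrix, individuals in rows, sites in columns; values
#'   0, 1, 2 or NA.
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `multiallelic` (logical), one row per site.
#' @param individuals data.frame with columns `id`, `population`, one row per
#'   individual.
#' @return an object of class `"genotype_panel"`.
#' @export
genotype_panel <- function(geno, sites, individuals) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(sites), is.data.frame(individuals),
            nrow(geno) == nrow(individuals), ncol(geno) == nrow(sites),
            all(c("contig", "pos", "ref", "alt", "multiallelic") %in% names(sites)),
            all(c("id", "population") %in% names(individuals)))
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  if (anyNA(individuals$population) || any(!nzchar(individuals$population)))
    stop("every individual must carry a population label")
  if (anyDuplicated(individuals$id)) stop("individual ids must be unique")
  key <- paste(sites$contig, sites$pos)
  if (anyDuplicated(key)) stop("site positions must be unique within contig")
  rownames(geno) <- individuals$id
  structure(list(geno = geno, sites = sites, individuals = individuals),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d sites, %d population(s), %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$individuals$population)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

# subset a panel by individual / site index
panel_subset <- function(panel, ind = NULL, site = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(panel$geno))
  if (is.null(site)) site <- seq_len(ncol(panel$geno))
  genotype_panel(panel$geno[ind, site, drop = FALSE],
                 panel$sites[site, , drop = FALSE],
                 panel$individuals[ind, , drop = FALSE])
}

#' Pair haplotypes into diploid genotypes
#'
#' Haplotypes are paired within their deme (randomly when `shuffle`, else in
#' storage order: 1st with 2nd, 3rd with 4th, ...) and summed into 0/1/2
#' genotypes; the deme label becomes the individual's population label.
#'
#' @param haps a [drop_mutations()] result (or any list with a 0/1 `haps`
#'   site x haplotype matrix and a `deme` label vector).
#' @param seed integer seed for the within-deme pairing.
#' @param shuffle randomize the pairing (default TRUE).
#' @return a [genotype_panel()] with synthetic site metadata (one artificial
#'   contig, consecutive 1-based positions, ref = ancestral allele).
#' @export
diploidize <- function(haps, seed, shuffle = TRUE) {
  demes <- haps$deme
  H <- haps$haps
  tab <- table(demes)
  if (any(tab %% 2L != 0L))
    stop("odd haploid count in deme(s): ",
         paste(names(tab)[tab %% 2L != 0L], collapse = ", "))
  deme_order <- unique(demes)
  pairs <- with_seed(derive_seed(seed, 1L), {
    do.call(rbind, lapply(deme_order, function(d) {
      idx <- which(demes == d)
      if (shuffle) idx <- idx[sample.int(length(idx))]
      matrix(idx, ncol = 2L, byrow = TRUE)
    }))
  })
  n_ind <- nrow(pairs)
  n_site <- nrow(H)
  geno <- matrix(0L, n_ind, n_site)
  if (n_site > 0L)
    geno <- t(H[, pairs[, 1L], drop = FALSE] + H[, pairs[, 2L], drop = FALSE])
  pop <- demes[pairs[, 1L]]
  ids <- paste0(pop, "_", stats::ave(seq_len(n_ind), pop, FUN = seq_along))
  sites <- data.frame(contig = rep("contig_1", n_site),
                      pos = seq_len(n_site),
                      ref = rep("A", n_site), alt = rep("T", n_site),
                      multiallelic = rep(FALSE, n_site),
                      stringsAsFactors = FALSE)
  genotype_panel(geno, sites, data.frame(id = ids, population = pop,
                                         stringsAsFactors = FALSE))
}

#' Inject missing genotypes
#'
#' Sets each genotype to missing independently with probability `rate`,
#' emulating the uneven locus coverage of reduced-representation sequencing.
#' Deterministic given the seed.
#'
#' @param panel a [genotype_panel()].
#' @param rate missingness probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the panel with missing entries added.
#' @export
inject_missingness <- function(panel, rate, seed) {
  stopifnot(inherits(panel, "genotype_panel"), rate >= 0, rate <= 1)
  if (rate == 0) return(panel)
  g <- panel$geno
  mask <- with_seed(derive_seed(seed, 2L),
                    runif(length(g)) < rate)
  g[mask] <- NA_integer_
  panel$geno <- g
  panel
}
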