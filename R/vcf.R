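#' Write a genotype panel as VCF 4.2 (GT only) with a population map
#'
#' Genotypes are serialized unphased (`0/0`, `0/1`, `1/1`) with missing
#' genotypes as `./.` per the VCF standard. The companion population map is a
#' two-column whitespace-separated text file (sample, population).
#'
#' @param panel a [genotype_panel()].
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  sites <- panel$sites
  g <- panel$geno
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt[ok] <- code[g[ok] + 1L]
  body <- paste(sites$contig, sites$pos, ".", sites$ref, sites$alt, ".", ".",
                ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=incursim",
           paste0("##contig=<ID=", unique(sites$contig), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$individuals$id), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @param popmap_path population map path.
#' @export
write_popmap <- function(panel, popmap_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  writeLines(paste(panel$individuals$id, panel$individuals$population,
                   sep = "\t"), popmap_path)
  invisible(popmap_path)
}

#' Read a VCF and population map into a genotype panel
#'
#' Parses the GT field into 0/1/2 alternate-allele dosages. Records with more
#' than one ALT allele are retained and flagged multi-allelic (their removal
#' is the QC cascade's job, see [filter_sites()]); their dosage is the count
#' of any non-reference allele. Any genotype containing `.` is missing. A
#' sample present in the VCF but absent from the population map is an error
#' naming the sample; a GT value that is not `a/b`, `a|b` or `.` alleles is an
#' error naming the record coordinates.
#'
#' @param path VCF path (plain or bgzipped; parsed with vcfR).
#' @param popmap_path two-column whitespace-separated text file mapping
#'   sample to population.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path, popmap_path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)

  pm <- read.table(popmap_path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("id", "population"))
  missing_pop <- setdiff(samples, pm$id)
  if (length(missing_pop))
    stop("sample(s) missing from population map: ",
         paste(missing_pop, collapse = ", "))
  pop <- pm$population[match(samples, pm$id)]

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  # decode each distinct GT string once
  lev <- unique(as.vector(gt_raw))
  lev <- lev[!is.na(lev)]
  dose <- setNames(rep(NA_integer_, length(lev)), lev)
  for (s in lev) {
    al <- strsplit(s, "[/|]")[[1L]]
    if (length(al) != 2L || !all(grepl("^(\\.|[0-9]+)$", al))) {
      bad <- which(gt_raw == s, arr.ind = TRUE)[1L, ]
      stop(sprintf("malformed GT '%s' at %s:%s", s,
                   fix[bad[1L], "CHROM"], fix[bad[1L], "POS"]))
    }
    if (any(al == ".")) next  # stays NA
    dose[s] <- sum(as.integer(al) > 0L)
  }
  g <- matrix(dose[as.vector(gt_raw)], nrow = nrow(gt_raw))
  g[is.na(as.vector(gt_raw))] <- NA_integer_

  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      multiallelic = multi, stringsAsFactors = FALSE)
  genotype_panel(t(g), sites,
                 data.frame(id = samples, population = pop,
                            stringsAsFactors = FALSE))
}
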