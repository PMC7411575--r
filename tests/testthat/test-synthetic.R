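test_that("diploidize sums paired haplotypes within deme", {
  haps <- list(haps = t(matrix(c(1, 0, 1, 1, 0, 0, 0, 1), nrow = 4,
                               byrow = TRUE)),
               deme = rep("A", 4))
  # in-order pairing (1,2), (3,4): genotypes [[2,1],[0,1]]
  p <- diploidize(haps, seed = 1, shuffle = FALSE)
  expect_equal(unname(p$geno), rbind(c(2L, 1L), c(0L, 1L)))
  expect_equal(p$individuals$population, c("A", "A"))
  # shuffled pairing preserves the per-site allele totals
  p2 <- diploidize(haps, seed = 9, shuffle = TRUE)
  expect_equal(colSums(p2$geno), colSums(p$geno))
})

test_that("diploidize rejects odd haploid counts and zero input maps to zero", {
  expect_error(diploidize(list(haps = matrix(0L, 2, 3),
                               deme = c("A", "A", "A")), seed = 1), "odd")
  h <- list(haps = matrix(0L, 3, 4), deme = rep("B", 4))
  expect_true(all(diploidize(h, seed = 1)$geno == 0L))
})

test_that("inject_missingness hits the requested rate and the edge cases", {
  p <- toy_panel(matrix(rep(0:2, length.out = 300), 10, 30))
  expect_identical(inject_missingness(p, 0, seed = 1), p)
  expect_true(all(is.na(inject_missingness(p, 1, seed = 1)$geno)))
  big <- toy_panel(matrix(1L, 100, 1000))
  m <- inject_missingness(big, 0.2, seed = 3)
  frac <- mean(is.na(m$geno))
  sd3 <- 3 * sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(frac - 0.2), sd3)
})

test_that("survey10 panels carry the study's sampling design", {
  sc <- study_scenario("survey10", target_sites = 150)
  p <- make_study_like_panel(sc, seed = 77)
  sizes <- table(p$individuals$population)
  expect_equal(sort(as.integer(sizes)),
               sort(c(16L, 16L, 15L, 16L, 16L, 15L, 15L, 16L, 16L, 16L)))
  expect_equal(length(sizes), 10L)
  expect_equal(ncol(p$geno), 150L)
  # identical seed, identical panel
  p2 <- make_study_like_panel(sc, seed = 77)
  expect_identical(p, p2)
  expect_false(identical(p$geno,
                         make_study_like_panel(sc, seed = 78)$geno))
})

test_that("generated sites are biallelic and polymorphic before missingness", {
  sc <- single_deme_scenario(n_dip = 12, target_sites = 120, miss = 0)
  p <- make_study_like_panel(sc, seed = 5)
  ac <- colSums(p$geno)
  expect_true(all(ac >= 1L & ac <= 2L * nrow(p$geno) - 1L))
  expect_false(any(p$sites$multiallelic))
})

test_that("generator reproduces the analytic folded SFS shape in aggregate", {
  n_dip <- 10; n <- 2 * n_dip
  an <- (1 / (1:(n / 2)) + 1 / (n - 1:(n / 2))) / (1 + (1:(n / 2) == n / 2))
  an <- an / sum(an)
  for (seed in c(2, 3, 4)) {
    sc <- single_deme_scenario(n_dip, target_sites = 2000, miss = 0)
    p <- make_study_like_panel(sc, seed = seed)
    obs <- sfs_from_panel(p, "Pop")
    counts <- obs$counts[polymorphic_mask(obs$n, TRUE)]
    gof <- suppressWarnings(stats::chisq.test(counts, p = an))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("VCF round trip preserves the panel exactly", {
  sc <- single_deme_scenario(4, 40, miss = 0.2)
  sc$demography <- demography(c(Pop = 1000, Out = 1000), migration = 1e-3)
  sc$sample_sizes <- c(Pop = 4, Out = 3)
  p <- make_study_like_panel(sc, seed = 12)
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile()
  write_vcf(p, vcf)
  write_popmap(p, pm)
  q <- read_vcf(vcf, pm)
  expect_equal(unname(q$geno), unname(p$geno))
  expect_equal(q$sites$pos, p$sites$pos)
  expect_equal(q$sites$ref, p$sites$ref)
  expect_equal(q$individuals, p$individuals)
  # missing genotype serialized per the VCF standard
  txt <- readLines(vcf)
  expect_true(any(grepl("\\./\\.", txt)))
  unlink(c(vcf, pm))
})

test_that("read_vcf flags multi-allelic records and names map/GT errors", {
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile()
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("c1", "5", ".", "A", "T", ".", ".", ".", "GT", "0/0", "0/1"),
          collapse = "\t"),
    paste(c("c1", "9", ".", "A", "T,G", ".", ".", ".", "GT", "1/2", "0/0"),
          collapse = "\t")), vcf)
  writeLines(c("s1 popA", "s2 popB"), pm)
  p <- read_vcf(vcf, pm)
  expect_equal(p$sites$multiallelic, c(FALSE, TRUE))
  expect_equal(ncol(p$geno), 2L)  # retained; removal is the QC step's job

  writeLines("s1 popA", pm)
  expect_error(read_vcf(vcf, pm), "s2")

  writeLines(c("s1 popA", "s2 popB"), pm)
  bad <- readLines(vcf)
  bad[4] <- sub("0/1", "0/x", bad[4])
  writeLines(bad, vcf)
  expect_error(read_vcf(vcf, pm), "c1:5")
  unlink(c(vcf, pm))
})
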