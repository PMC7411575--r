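test_that("the MAF rule removes strictly below threshold only", {
  # 10 diploids, one heterozygote: MAF = 1/20 = 0.05 exactly -> retained
  g <- matrix(0L, 10, 1); g[1, 1] <- 1L
  res <- filter_sites(toy_panel(g))
  expect_equal(res$report$retained_sites, 1L)
  expect_equal(res$report$removed_maf, 0L)
  # 13 diploids, one heterozygote: MAF = 1/26 < 0.05 -> removed
  g <- matrix(0L, 13, 1); g[1, 1] <- 1L
  res <- filter_sites(toy_panel(g))
  expect_equal(res$report$retained_sites, 0L)
  expect_equal(res$report$removed_maf, 1L)
})

test_that("the site-missingness rule removes strictly above threshold only", {
  g <- matrix(rep(c(0L, 1L), length.out = 15), 15, 2)
  g[1:3, 1] <- NA  # 3/15 = 0.20 -> retained
  g[1:4, 2] <- NA  # 4/15 ~ 0.267 -> removed
  res <- filter_sites(toy_panel(g))
  expect_equal(res$report$removed_site_missing, 1L)
  expect_equal(res$panel$sites$pos, 1L)
})

test_that("multi-allelic sites go first and rule counts are disjoint", {
  g <- cbind(rep(c(0L, 1L), 5), rep(0L, 10), rep(c(0L, 2L), 5))
  g[1:9, 2] <- NA  # high missingness AND maf 0 -> counted under MAF (rule 2)
  p <- toy_panel(g, multiallelic = c(TRUE, FALSE, FALSE))
  res <- filter_sites(p)
  expect_equal(res$report$removed_multiallelic, 1L)
  expect_equal(res$report$removed_maf, 1L)
  expect_equal(res$report$removed_site_missing, 0L)
  expect_equal(res$report$retained_sites, 1L)
  expect_equal(res$report$removed_multiallelic + res$report$removed_maf +
                 res$report$removed_site_missing + res$report$retained_sites,
               res$report$input_sites)
})

test_that("individuals missing >20% of loci are removed, boundary kept", {
  g <- matrix(rep(c(0L, 1L, 2L), length.out = 10 * 20), 10, 20)
  g[1, 1:5] <- NA  # 25% -> removed
  g[2, 1:4] <- NA  # 20% -> kept
  res <- filter_individuals(toy_panel(g))
  expect_equal(res$report$removed_individuals, 1L)
  expect_false("ind1" %in% res$panel$individuals$id)
  expect_true("ind2" %in% res$panel$individuals$id)
})

test_that("site filtering before individual filtering can rescue individuals", {
  # ind1 and ind2 miss only site 1; site 1 is missing in 2/5 individuals
  # (removed first), after which both are complete
  g <- matrix(rep(c(0L, 1L), length.out = 5 * 4), 5, 4)
  g[1, 1] <- NA; g[2, 1] <- NA
  p <- toy_panel(g)
  s <- filter_sites(p)
  expect_equal(s$report$removed_site_missing, 1L)
  i <- filter_individuals(s$panel)
  expect_equal(i$report$removed_individuals, 0L)
  # reversed order would have removed both (1/4 = 25% missing each)
  expect_equal(filter_individuals(p)$report$removed_individuals, 2L)
})

test_that("filters are idempotent and report zeros when nothing to do", {
  p <- hw_panel(15, 80, seed = 4, miss = 0.1)
  once <- filter_sites(p)
  twice <- filter_sites(once$panel)
  expect_identical(once$panel, twice$panel)
  expect_equal(twice$report$removed_maf + twice$report$removed_site_missing +
                 twice$report$removed_multiallelic, 0L)
  io <- filter_individuals(once$panel)
  expect_identical(io$panel, filter_individuals(io$panel)$panel)
})

test_that("filters are monotone in their thresholds", {
  p <- hw_panel(12, 120, seed = 9, miss = 0.15)
  strict <- filter_sites(p, maf_min = 0.10, max_site_missing = 0.10)
  loose <- filter_sites(p, maf_min = 0.02, max_site_missing = 0.30)
  expect_lte(strict$report$retained_sites, loose$report$retained_sites)
  expect_true(all(strict$panel$sites$pos %in% loose$panel$sites$pos))
})

test_that("a duplicated site column resolves to exactly one retained site", {
  # enough individuals that independent loci sit far below the threshold
  set.seed(31)
  g <- sapply(runif(30, 0.2, 0.8), function(p) rbinom(400, 2, p))
  g <- cbind(g, g[, 5])  # duplicate of site 5 at the end
  res <- ld_prune(toy_panel(g), window = 50, step = 10)
  expect_equal(length(res$removed), 1L)
  expect_true(res$removed %in% c(5L, 31L))
  # deterministic tie-break: equal missingness -> later position removed
  expect_equal(res$removed, 31L)
})

test_that("uncorrelated sites are untouched and tiny windows error", {
  set.seed(8)
  g <- sapply(runif(40, 0.3, 0.7), function(p) rbinom(200, 2, p))
  res <- ld_prune(toy_panel(g))
  expect_equal(length(res$removed), 0L)
  expect_error(ld_prune(toy_panel(g), window = 1), "window")
})

test_that("after pruning no in-window pair exceeds the r2 threshold", {
  sc <- single_deme_scenario(25, 400, sites_per_genealogy = 40, miss = 0.05)
  p <- make_study_like_panel(sc, seed = 3)
  p <- filter_sites(p)$panel
  res <- ld_prune(p, r2_threshold = 0.1, window = 50, step = 10)
  expect_gt(length(res$removed), 0L)
  q <- res$panel
  S <- ncol(q$geno)
  for (st in seq(1, max(1, S - 1), by = 10)) {
    win <- st:min(st + 49, S)
    if (length(win) < 2) next
    C <- suppressWarnings(cor(q$geno[, win], use = "pairwise.complete.obs"))^2
    diag(C) <- 0
    C[!is.finite(C)] <- 0
    expect_lte(max(C), 0.1 + 1e-12)
  }
})

test_that("pruning is invariant to individual order", {
  sc <- single_deme_scenario(20, 200, sites_per_genealogy = 25, miss = 0.05)
  p <- make_study_like_panel(sc, seed = 6)
  p <- filter_sites(p)$panel
  r1 <- ld_prune(p)
  set.seed(1)
  perm <- sample(nrow(p$geno))
  p2 <- genotype_panel(p$geno[perm, ], p$sites, p$individuals[perm, ])
  r2 <- ld_prune(p2)
  expect_equal(r1$removed, r2$removed)
})
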