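test_that("hand tally: two diploids, two sites", {
  # columns [0,1] and [1,1]: alt counts 1 and 2 of n = 4 -> folded {1:1, 2:1}
  p <- toy_panel(cbind(c(0L, 1L), c(1L, 1L)))
  s <- sfs_from_panel(p, "P1")
  expect_true(s$folded)
  expect_equal(s$n, 4L)
  expect_equal(s$counts, c(0, 1, 1, 0, 0))
})

test_that("monomorphic sites contribute nothing to the polymorphic total", {
  p <- toy_panel(cbind(c(0L, 0L), c(2L, 2L), c(1L, 0L)))
  s <- sfs_from_panel(p, "P1")
  expect_equal(sum(s$counts[polymorphic_mask(s$n, TRUE)]), 1)
})

test_that("1D folding matches its definition and preserves totals", {
  x <- sfs_counts(c(5, 3, 2, 1, 7), n = 4)  # unfolded, incl monomorphic
  f <- fold_sfs(x)
  expect_equal(f$counts, c(12, 4, 2, 0, 0))  # {0:5+7, 1:3+1, 2:2}
  expect_equal(sum(f$counts), sum(x$counts))
  expect_error(fold_sfs(f), "already folded")
  # the canonical example [3,2,1] on polymorphic entries -> {1:4, 2:2}
  y <- fold_sfs(sfs_counts(c(0, 3, 2, 1, 0), n = 4))
  expect_equal(y$counts[2:3], c(4, 2))
})

test_that("2D folding equals brute-force cell pairing on a 5x5 grid", {
  set.seed(2)
  m <- matrix(rpois(25, 4), 5, 5)
  f <- fold_sfs(sfs_counts(m, n = c(4L, 4L)))
  # brute force: combine (i,j) with (4-i, 4-j) keyed by smaller total;
  # boundary cells (total = 4) keep one canonical representative
  want <- matrix(0, 5, 5)
  for (i in 0:4) for (j in 0:4) {
    mi <- 4 - i; mj <- 4 - j
    s <- i + j
    canonical <- s < 4 || (s == 4 && (i < mi || (i == mi && j <= mj)))
    if (canonical) {
      want[i + 1, j + 1] <- m[i + 1, j + 1] +
        if (i == mi && j == mj) 0 else m[mi + 1, mj + 1]
    }
  }
  expect_equal(f$counts, want)
  expect_equal(sum(f$counts), sum(m))
  # of each fold pair at most one cell is populated
  pop <- f$counts > 0
  for (i in 0:4) for (j in 0:4) {
    if (i == 4 - i && j == 4 - j) next
    expect_false(pop[i + 1, j + 1] && pop[4 - i + 1, 4 - j + 1])
  }
})

test_that("hypergeometric projection: identity, hand weights, mass, errors", {
  x <- sfs_counts(c(0, 5, 3, 2, 0), n = 4)
  expect_equal(project_sfs(x, 4)$counts, x$counts)
  # P(1 of 2 | i of 4) = 1/2, 2/3, 1/2 for i = 1..3
  pr <- project_sfs(x, 2)
  expect_equal(pr$counts[2], 5 / 2 + 3 * 2 / 3 + 2 / 2)
  expect_equal(sum(pr$counts), sum(x$counts))
  expect_error(project_sfs(x, 1), ">= 2")
  expect_error(project_sfs(x, 5), "project up")
  expect_error(project_sfs(fold_sfs(x), 2), "unfolded")
})

test_that("panel projection equals brute-force subsample enumeration", {
  # 3 diploids (6 haplotypes) with missingness; project to 4
  g <- cbind(c(1L, 0L, 2L), c(NA, 1L, 1L), c(2L, 2L, NA), c(0L, 1L, NA))
  p <- toy_panel(g)
  got <- sfs_from_panel(p, "P1", project_to = 4, fold = FALSE)
  want <- numeric(5)
  for (s in seq_len(ncol(g))) {
    gs <- g[, s][!is.na(g[, s])]
    alleles <- unlist(lapply(gs, function(x) c(rep(1, x), rep(0, 2 - x))))
    if (length(alleles) < 4) next
    want <- want + project_site_oracle(alleles, 4)
  }
  expect_equal(got$counts, want, tolerance = 1e-12)
  # folding after projection equals folding the enumerated spectrum
  expect_equal(sfs_from_panel(p, "P1", project_to = 4)$counts,
               fold_sfs(sfs_counts(want, n = 4))$counts, tolerance = 1e-12)
})

test_that("2D projection applies the hypergeometric per dimension", {
  g <- cbind(c(1L, 0L, 2L, 1L), c(2L, 1L, 0L, NA), c(0L, 1L, 1L, 2L))
  p <- toy_panel(g, populations = c("A", "A", "B", "B"))
  got <- sfs_from_panel(p, list(gA = "A", gB = "B"), project_to = c(2, 2),
                        fold = FALSE)
  want <- matrix(0, 3, 3)
  for (s in seq_len(ncol(g))) {
    ga <- g[1:2, s][!is.na(g[1:2, s])]
    gb <- g[3:4, s][!is.na(g[3:4, s])]
    aa <- unlist(lapply(ga, function(x) c(rep(1, x), rep(0, 2 - x))))
    ab <- unlist(lapply(gb, function(x) c(rep(1, x), rep(0, 2 - x))))
    if (length(aa) < 2 || length(ab) < 2) next
    want <- want + outer(project_site_oracle(aa, 2),
                         project_site_oracle(ab, 2))
  }
  expect_equal(got$counts, want, tolerance = 1e-12)
})

test_that("without projection, incompletely genotyped sites are dropped", {
  g <- cbind(c(1L, 1L), c(NA, 1L))
  s <- sfs_from_panel(toy_panel(g), "P1")
  expect_equal(sum(s$counts[polymorphic_mask(s$n, TRUE)]), 1)
})

test_that("projection size above the available haploid count errors", {
  p <- toy_panel(cbind(c(1L, 0L)))
  expect_error(sfs_from_panel(p, "P1", project_to = 6), "exceeds")
  expect_error(sfs_from_panel(p, "nope"), "unknown")
})

test_that("SFS text serialization is bit-stable both ways", {
  x <- sfs_counts(c(0, 5.25, 3 + 1e-13, 2, 0), n = 4)
  f <- tempfile(fileext = ".sfs")
  write_sfs(x, f)
  y <- read_sfs(f)
  expect_identical(y$counts, x$counts)
  expect_identical(y$folded, FALSE)
  m <- fold_sfs(sfs_counts(matrix(runif(20), 4, 5), n = c(3L, 4L)))
  write_sfs(m, f)
  z <- read_sfs(f)
  expect_identical(z$counts, m$counts)
  expect_true(z$folded)
  expect_equal(z$n, c(3L, 4L))
  unlink(f)
})
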