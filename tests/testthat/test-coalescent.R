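test_that("a single sampled lineage yields a degenerate single-leaf tree", {
  g <- simulate_genealogy(demography(c(A = 1000)), c(A = 1), seed = 1)
  expect_equal(g$n, 1L)
  expect_equal(nrow(g$edge), 0L)
  expect_equal(max(g$node_time), 0)
  expect_length(branch_length_sfs(g), 0L)
})

test_that("isolated demes raise an explicit cannot-coalesce error", {
  dem <- demography(c(A = 100, B = 100))  # m = 0, no merge events
  expect_error(simulate_genealogy(dem, c(A = 2, B = 2), seed = 3),
               "cannot coalesce")
  expect_error(expected_sfs(dem, c(A = 2, B = 2), n_sims = 5, seed = 3),
               "cannot coalesce")
})

test_that("lineages stranded past max_time raise rather than hang", {
  dem <- demography(c(A = 1e6, B = 1e6), migration = 1e-12, max_time = 1e4)
  expect_error(simulate_genealogy(dem, c(A = 2, B = 2), seed = 5),
               "max_time")
})

test_that("identical (demography, samples, seed) give bit-identical trees", {
  dem <- demography(c(A = 500, B = 800), migration = 1e-3,
                    events = list(ev_mass_move(2000, "B", "A"),
                                  ev_resize(2000, "A", 5000)))
  g1 <- simulate_genealogy(dem, c(A = 5, B = 5), seed = 42)
  g2 <- simulate_genealogy(dem, c(A = 5, B = 5), seed = 42)
  expect_identical(g1, g2)
  g3 <- simulate_genealogy(dem, c(A = 5, B = 5), seed = 42, replicate = 2)
  expect_false(identical(g1$node_time, g3$node_time))
})

test_that("mean pairwise TMRCA matches the analytic 2N", {
  dem <- demography(c(A = 1000))
  tm <- vapply(1:5000, function(r)
    max(simulate_genealogy(dem, c(A = 2), seed = 7, replicate = r)$node_time),
    numeric(1))
  expect_lt(abs(mean(tm) / 2000 - 1), 0.05)
})

test_that("branch_length_sfs matches leaf-set enumeration on a hand tree", {
  # 4-leaf caterpillar: ((((1,2),3),4) with node times 0,0,0,0,10,25,60
  edge <- rbind(c(5L, 1L), c(5L, 2L), c(6L, 5L), c(6L, 3L), c(7L, 6L),
                c(7L, 4L))
  g <- hand_genealogy(edge, c(0, 0, 0, 0, 10, 25, 60), rep("A", 4))
  got <- branch_length_sfs(g)
  # brute force: each branch, count subtended leaves, add its length
  leaves_under <- list(1, 2, c(1, 2), 3, c(1, 2, 3), 4)
  bl <- c(10, 10, 15, 25, 35, 60)
  want <- tapply(bl, vapply(leaves_under, length, numeric(1)), sum)
  expect_equal(got[names(want)], setNames(as.numeric(want), names(want)))
  # no monomorphic class: entry "4" absent, total = tree length
  expect_false("4" %in% names(got))
  expect_equal(sum(got), sum(bl))
})

test_that("n = 2 tree maps all length to the singleton class", {
  g <- simulate_genealogy(demography(c(A = 99)), c(A = 2), seed = 11)
  s <- branch_length_sfs(g)
  expect_equal(names(s), "1")
  expect_equal(unname(s), 2 * max(g$node_time))
})

test_that("relabelling samples within a deme leaves the spectrum unchanged", {
  dem <- demography(c(A = 300, B = 300), migration = 5e-3)
  for (seed in 1:5) {
    g <- simulate_genealogy(dem, c(A = 4, B = 4), seed = seed)
    s1 <- branch_length_sfs(g, by_deme = TRUE)
    # permute sample indices within each deme: deme labels are unchanged,
    # so the per-deme subtended counts -- and the spectrum -- must be too
    g2 <- g
    for (d in unique(g$leaf_deme)) {
      i <- which(g$leaf_deme[seq_len(g$n)] == d)
      g2$leaf_deme[i] <- g$leaf_deme[sample(i)]
    }
    expect_identical(branch_length_sfs(g2, by_deme = TRUE), s1)
  }
})

test_that("batch expected SFS agrees with per-tree accumulation", {
  dem <- demography(c(A = 400, B = 600), migration = 2e-3)
  n_rep <- 300
  es <- expected_sfs(dem, c(A = 3, B = 3), n_sims = n_rep, seed = 17,
                     groups = list(gA = "A", gB = "B"),
                     variance_reduction = FALSE)
  acc <- matrix(0, 4, 4)
  for (r in seq_len(n_rep)) {
    g <- simulate_genealogy(dem, c(A = 3, B = 3), seed = 17, replicate = r)
    s <- branch_length_sfs(g, by_deme = TRUE)
    for (k in names(s)) {
      ij <- as.integer(strsplit(k, ",")[[1]])
      acc[ij[1] + 1, ij[2] + 1] <- acc[ij[1] + 1, ij[2] + 1] + s[[k]]
    }
  }
  acc <- acc / sum(acc)
  expect_equal(unname(es$probs), acc, tolerance = 1e-10)
})

test_that("constant-size expected SFS reproduces the 1/i law exactly", {
  dem <- demography(c(A = 1000))
  es <- expected_sfs(dem, c(A = 10), n_sims = 50, seed = 2)
  expect_equal(sum(es$probs), 1)
  want <- (1 / (1:9)) / sum(1 / (1:9))
  expect_equal(unname(es$probs[2:10]), want, tolerance = 1e-9)
  # folded: entry i proportional to (1/i + 1/(n-i)) / (1 + [i = n-i])
  esf <- expected_sfs(dem, c(A = 10), n_sims = 50, seed = 2, fold = TRUE)
  an <- (1 / (1:5) + 1 / (10 - (1:5))) / (1 + ((1:5) == 5))
  expect_equal(unname(esf$probs[2:6]), an / sum(an), tolerance = 1e-9)
})

test_that("two identical demes with symmetric migration give a symmetric joint SFS", {
  dem <- demography(c(A = 500, B = 500), migration = 1e-3)
  es <- expected_sfs(dem, c(A = 6, B = 6), n_sims = 3000, seed = 3,
                     groups = list(gA = "A", gB = "B"))
  m <- unname(es$probs)
  expect_lt(max(abs(m - t(m))), 0.012)
  expect_equal(sum(m), 1)
})

test_that("growth phases shorten coalescence times as expected", {
  # forward growth r > 0 means smaller sizes backward in time, so TMRCA
  # must drop well below the constant-size expectation
  dem_g <- demography(c(A = 1000), growth = 0.01,
                      events = list(ev_resize(500, "A", 5000),
                                    ev_growth(500, "A", 0)))
  tm <- mean(vapply(1:4000, function(r)
    max(simulate_genealogy(dem_g, c(A = 2), seed = 9, replicate = r)$node_time),
    numeric(1)))
  # numeric hazard integration gives E[T2] = 265.7 for this demography
  expect_lt(abs(tm / 265.7 - 1), 0.08)
})
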