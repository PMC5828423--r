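# Coefficient of determination, ACF, NSTD, NSTI, relative deviation,
# NSTD-binned R^2.

test_that("coefficient of determination follows its definition", {
  y <- c(1, 4, 2, 8)
  expect_equal(coefficientOfDetermination(y, y), 1)
  expect_equal(coefficientOfDetermination(y, rep(mean(y), 4)), 0)
  expect_equal(coefficientOfDetermination(c(1, 2, 3), c(3, 2, 1)), -3)
  expect_error(coefficientOfDetermination(c(2, 2, 2), c(1, 2, 3)),
               "zero variance")
  expect_error(coefficientOfDetermination(1:3, 1:4), "equal length")
  # asymmetry: reference is explained by predicted
  a <- c(1, 2, 3, 4)
  b <- c(1.1, 2.2, 2.9, 3.6)
  expect_false(isTRUE(all.equal(coefficientOfDetermination(a, b),
                                coefficientOfDetermination(b, a))))
  expect_equal(pearsonR2(a, b), stats::cor(a, b)^2)
})

test_that("relative deviation is symmetric, zero at equality, bounded by 2", {
  expect_equal(relativeDeviation(3, 3), 0)
  expect_equal(relativeDeviation(2, 4), 2 / 3)
  expect_equal(relativeDeviation(4, 2), 2 / 3)
  expect_lt(relativeDeviation(1e-9, 5), 2)
  expect_gt(relativeDeviation(1e-9, 5), 1.999)
  expect_error(relativeDeviation(0, 1), "positive")
})

test_that("NSTD message passing matches hand-computed and brute-force values", {
  tr <- parseNewick("((A:1,B:1):1,C:2);")
  expect_equal(nstdValues(computeNstd(tr, "A")),
               c(A = 0, B = 2, C = 4))
  expect_equal(unname(nstdValues(computeNstd(tr, c("A", "B", "C")))),
               c(0, 0, 0))
  expect_error(computeNstd(tr, character()), "non-empty")

  set.seed(303)
  for (i in 1:12) {
    trr <- random_tree(50, polytomies = i %% 2 == 0)
    known <- sample(trr$tip.label, sample(1:25, 1))
    got <- nstdValues(computeNstd(trr, known))
    dm <- ape::cophenetic.phylo(trr)
    brute <- apply(dm[, known, drop = FALSE], 1, min)
    expect_equal(got[rownames(dm)], brute, tolerance = 1e-10)
  }
})

test_that("NSTD is monotone under enlargement of the known set", {
  set.seed(42)
  tr <- random_tree(60)
  k1 <- sample(tr$tip.label, 10)
  k2 <- c(k1, sample(setdiff(tr$tip.label, k1), 10))
  n1 <- nstdValues(computeNstd(tr, k1))
  n2 <- nstdValues(computeNstd(tr, k2))
  expect_true(all(n2 <= n1 + 1e-12))
})

test_that("NSTI is the abundance-weighted mean NSTD", {
  expect_equal(computeNsti(c(a = 0, b = 0.2), c(a = 3, b = 1)), 0.05)
  expect_equal(computeNsti(c(a = 0.1, b = 0.3), c(a = 2, b = 2)), 0.2)
  expect_equal(computeNsti(c(a = 0.1, b = 0.3), c(a = 9, b = 0)), 0.1)
  expect_error(computeNsti(c(a = 0.1), c(a = 0)), "positive count")
  # bounded by the extremes of the considered NSTDs
  set.seed(5)
  v <- stats::runif(20)
  names(v) <- paste0("o", 1:20)
  cts <- stats::setNames(stats::rpois(20, 4), names(v))
  cts[1] <- cts[1] + 1
  nsti <- computeNsti(v, cts)
  expect_gte(nsti, min(v[cts > 0]))
  expect_lte(nsti, max(v[cts > 0]))
})

test_that("trait ACF behaves on degenerate and self-pair inputs", {
  d <- small_benchmark()
  # constant trait: every bin undefined
  const <- traitTable(d$tree$tip.label,
                      rep(2, length(d$tree$tip.label)))
  acf0 <- traitAcf(d$tree, const, npairs = 1e4, nbins = 5, seed = 1L)
  expect_true(all(is.na(acfBins(acf0)$correlation)))

  # two known tips: the zero-distance bin holds self-pairs, correlation 1
  two <- traitTable(d$tree$tip.label,
                    c(1, 2, rep(NA, length(d$tree$tip.label) - 2)))
  acf2 <- traitAcf(d$tree, two, npairs = 2e3, nbins = 2, seed = 2L)
  b <- acfBins(acf2)
  expect_equal(b$correlation[1], 1)
  expect_equal(b$mean_distance[1], 0)

  # determinism and pair-count bookkeeping
  a1 <- traitAcf(d$tree, d$masked, npairs = 1e4, nbins = 10, seed = 3L)
  a2 <- traitAcf(d$tree, d$masked, npairs = 1e4, nbins = 10, seed = 3L)
  expect_identical(acfBins(a1), acfBins(a2))
  expect_equal(sum(acfBins(a1)$n_pairs), 1e4)
})

test_that("ensemble tip-pair correlations match the Mk closed form", {
  # direct validation of corr(d) = exp(-r d S/(S-1)): many independent trait
  # draws on one fixed tree, correlation across draws for chosen tip pairs
  set.seed(61)
  tr <- simulateTree(simConfig(seed = 17L, ntips = 40L))
  S <- 2
  q <- calibrateAcfRate(S, 0.5, 0.15)
  R <- 1200
  draws <- vapply(seq_len(R), function(i)
    unname(traitValues(simulateTraitMk(tr, S, q, seed = 7000L + i))),
    numeric(40))
  dm <- tipDistanceMatrix(tr)
  pairs <- list(c(1, 2), c(5, 30), c(10, 40), c(3, 22))
  for (p in pairs) {
    dd <- dm[p[1], p[2]]
    r_hat <- stats::cor(draws[p[1], ], draws[p[2], ])
    r_true <- mkErCorrelation(q, dd, S)
    se <- (1 - r_true^2) / sqrt(R - 3)
    expect_lt(abs(r_hat - r_true), 4 * se)
  }
})

test_that("binned R^2 respects bin width, threshold and degeneracy flags", {
  # all items in one bin, perfect prediction
  ref <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  out <- binR2ByNstd(ref, ref, rep(0.01, 10), binWidth = 0.05)
  expect_equal(nrow(out), 1L)
  expect_equal(out$r2, 1)

  # 9 items fall below the threshold of 10
  out9 <- binR2ByNstd(ref[1:9], ref[1:9], rep(0.01, 9), binWidth = 0.05)
  expect_equal(nrow(out9), 0L)

  # two bins: perfect in the first, reversed (negative R^2) in the second
  ref2 <- rep(c(1, 2, 3), length.out = 12)
  pred_good <- ref2
  pred_bad <- rep(c(3, 2, 1), length.out = 12)
  reference <- c(ref2, ref2)
  predicted <- c(pred_good, pred_bad)
  nstd <- c(rep(0.01, 12), rep(0.08, 12))
  out2 <- binR2ByNstd(reference, predicted, nstd, binWidth = 0.05)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$r2[1], 1)
  expect_lt(out2$r2[2], 0)

  # zero-variance bin flagged NA, not fatal
  outz <- binR2ByNstd(rep(2, 10), stats::runif(10), rep(0.01, 10),
                      binWidth = 0.05)
  expect_true(is.na(outz$r2[1]))
})
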