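# Cross-validation, tool comparison across samples, the NSTI-R^2 trend, and
# abundance correction.

test_that("cross-validation never leaks training tips inside the cutoff", {
  d <- small_benchmark()
  cutoffs <- c(0, 0.05, 0.15)
  cv <- crossvalR2Curve(d$tree, d$masked, "sa", cutoffs,
                        testFraction = 0.05, repeats = 3L, seed = 31L)
  known <- knownTips(d$masked)
  dm <- ape::cophenetic.phylo(d$tree)
  for (rep_i in seq_len(cv@repeats)) {
    test <- cv@testSets[[rep_i]]
    expect_true(all(test %in% known))
    for (ci in seq_along(cutoffs)) {
      # reconstruct the training set by brute force and compare sizes
      pool <- setdiff(known, test)
      d_to_test <- apply(dm[pool, test, drop = FALSE], 1, min)
      train <- pool[d_to_test >= cutoffs[ci]]
      expect_equal(cv@trainSize[rep_i, ci], length(train))
      expect_length(intersect(train, test), 0)
      if (length(train)) expect_true(all(d_to_test[train] >= cutoffs[ci]))
    }
  }
})

test_that("a cutoff beyond the tree diameter is flagged, not computed", {
  d <- small_benchmark()
  cv <- crossvalR2Curve(d$tree, d$masked, "sa", c(0, 99),
                        testFraction = 0.1, seed = 2L)
  expect_true(all(is.na(cv@r2[, 2])))
  expect_true(is.na(cv@meanR2[2]))
  expect_true(all(cv@trainSize[, 2] == 0))
  expect_false(anyNA(cv@r2[, 1]))
  expect_error(crossvalR2Curve(d$tree, d$masked, "sa", 99,
                               testFraction = 0.1, seed = 2L), "skipped")
})

test_that("zero-distance neighbors make cutoff-0 prediction near-perfect", {
  # duplicate every known tip at zero distance (rewrite its newick leaf as
  # a zero-length cherry): each test tip then has an unmasked twin and
  # subtree averaging recovers it exactly
  d <- small_benchmark()
  vals <- traitValues(d$masked)
  known <- names(vals)[!is.na(vals)]
  nwk <- writeNewick(d$tree)
  for (k in known) {
    nwk <- sub(paste0("([(,])", k, ":"),
               sprintf("\\1(%s:0,%s_twin:0):", k, k), nwk)
  }
  tr <- parseNewick(nwk)
  twin_vals <- stats::setNames(vals[known], paste0(known, "_twin"))
  tt <- traitTable(c(names(vals), names(twin_vals)),
                   c(unname(vals), unname(twin_vals)))
  cv <- crossvalR2Curve(tr, tt, "sa", 0, testFraction = 0.05,
                        repeats = 3L, seed = 8L)
  expect_gt(cv@meanR2[1], 0.9)
})

test_that("comparePredictionSets restricts, scores and flags per sample", {
  d <- small_benchmark()
  nstd <- computeNstd(d$tree, knownTips(d$masked))
  pa <- hspPredict(d$tree, d$masked, "sa")
  cmp_self <- comparePredictionSets(pa, pa, d$abundances, nstd)
  expect_true(all(cmp_self$r2[!cmp_self$excluded] == 1))
  expect_true(all(cmp_self$nsti[!cmp_self$excluded] >= 0))

  # a sample with a single eligible OTU is flagged and excluded
  m <- matrix(0L, nrow = ape::Ntip(d$tree), ncol = 2,
              dimnames = list(d$tree$tip.label, c("one", "many")))
  m[1, "one"] <- 10L
  m[1:30, "many"] <- 5L
  ab <- abundanceTable(m)
  cmp <- comparePredictionSets(pa, hspPredict(d$tree, d$masked, "pic"),
                               ab, nstd)
  expect_true(cmp$excluded[cmp$sample == "one"])
  expect_false(cmp$excluded[cmp$sample == "many"])
  expect_equal(cmp$n_otus[cmp$sample == "one"], 1L)
})

test_that("samples dominated by high-NSTD OTUs agree less between tools", {
  # crafted prediction sets: concordant at NSTD 0, discordant at high NSTD
  otus <- paste0("o", 1:40)
  nstd_vals <- c(rep(0, 20), rep(0.5, 20))
  set.seed(10)
  base <- stats::runif(40, 1, 10)
  pa <- new("PredictionSet", tip = otus, value = base, method = "a",
            params = list(), details = list())
  vb <- base
  vb[21:40] <- sample(vb[21:40])  # scramble only the high-NSTD half
  pb <- new("PredictionSet", tip = otus, value = vb, method = "b",
            params = list(), details = list())
  nstd <- new("NSTDMap", tip = otus, nstd = nstd_vals,
              known = nstd_vals == 0)
  m <- matrix(0L, 40, 20, dimnames = list(otus, paste0("s", 1:20)))
  for (j in 1:10) m[sample(1:20, 12), j] <- 50L          # low-NSTD samples
  for (j in 11:20) m[c(sample(1:20, 3), sample(21:40, 9)), j] <- 50L
  ab <- abundanceTable(m, group = rep(c("low", "high"), each = 10))
  cmp <- comparePredictionSets(pa, pb, ab, nstd)
  lo <- cmp[cmp$group == "low" & !cmp$excluded, ]
  hi <- cmp[cmp$group == "high" & !cmp$excluded, ]
  expect_gt(mean(lo$r2), mean(hi$r2))
  expect_lt(mean(lo$nsti), mean(hi$nsti))
})

test_that("the NSTI-R^2 permutation test detects and rejects correctly", {
  # monotone decreasing: strong negative r, small P
  mono <- data.frame(sample = paste0("s", 1:20), group = "g",
                     n_otus = 10L, r2 = seq(0.9, 0.1, length.out = 20),
                     nsti = seq(0.01, 0.4, length.out = 20),
                     excluded = FALSE)
  tr <- nstiR2Trend(mono, group = "g", seed = 3L)
  expect_lt(tr$r, 0)
  expect_lte(tr$pValue, 0.05)
  expect_equal(tr$r2, tr$r^2)

  # null calibration: independent R^2 and NSTI give P > 0.05 most of the time
  set.seed(99)
  nulls <- vapply(1:50, function(i) {
    df <- data.frame(sample = paste0("s", 1:100), group = "g", n_otus = 10L,
                     r2 = stats::rnorm(100), nsti = stats::runif(100),
                     excluded = FALSE)
    nstiR2Trend(df, group = "g", permutations = 200L, seed = i)$pValue
  }, numeric(1))
  expect_gte(mean(nulls > 0.05), 0.9)

  expect_error(nstiR2Trend(mono[1:2, ], group = "g"), "at least 3")
  const <- mono
  const$nsti <- 0.2
  expect_error(nstiR2Trend(const, group = "g"), "constant")
})

test_that("GCN correction divides, renormalizes and validates", {
  m <- matrix(c(6L, 2L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  ab <- abundanceTable(m)
  mk_pred <- function(tips, vals) new("PredictionSet", tip = tips,
                                      value = vals, method = "x",
                                      params = list(), details = list())
  # GCN 1 everywhere: unchanged (unnormalized)
  expect_equal(correctAbundances(ab, mk_pred(c("a", "b"), c(1, 1)),
                                 renormalize = FALSE),
               m / 1, ignore_attr = FALSE)
  # counts {6,2}, GCN {3,2} renormalized: proportions {2/3, 1/3}
  out <- correctAbundances(ab, mk_pred(c("a", "b"), c(3, 2)))
  expect_equal(unname(out[, 1]), c(2 / 3, 1 / 3))
  expect_equal(colSums(out), c(s1 = 1), tolerance = 1e-9)
  # uniform GCN c: identical to renormalized uncorrected table
  out_c <- correctAbundances(ab, mk_pred(c("a", "b"), c(4, 4)))
  expect_equal(unname(out_c[, 1]), c(6, 2) / 8, tolerance = 1e-12)
  # errors: missing prediction, prediction < 1
  expect_error(correctAbundances(ab, mk_pred("a", 2)), "missing")
  expect_error(correctAbundances(ab, mk_pred(c("a", "b"), c(0.5, 2))),
               "< 1")
})

test_that("rank within a sample is conserved under equal GCNs", {
  set.seed(4)
  m <- matrix(stats::rpois(30, 20) + 1L, 10, 3,
              dimnames = list(paste0("o", 1:10), paste0("s", 1:3)))
  ab <- abundanceTable(m)
  ps <- new("PredictionSet", tip = rownames(m), value = rep(2, 10),
            method = "x", params = list(), details = list())
  out <- correctAbundances(ab, ps)
  for (j in 1:3) expect_equal(order(out[, j]), order(m[, j]))
})

test_that("runBenchmark writes a deterministic, complete report", {
  cfg <- simConfig(seed = 13L, ntips = 150L, nsamples = 8L,
                   readsPerSample = 400L)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- runBenchmark(cfg, methods = c("mpr_ae", "sa"),
                      cutoffs = c(0, 0.1), outDir = out1,
                      testFraction = 0.1, acfNpairs = 1e4, acfNbins = 8L)
  expected <- c("tree.nwk", "traits.tsv", "traits_masked.tsv",
                "abundances.tsv", "acf.tsv", "nstd.tsv", "cv_mpr_ae.tsv",
                "cv_sa.tsv", "sample_comparison.tsv", "trend.json",
                "summary.json")
  expect_true(all(file.exists(file.path(out1, expected))))
  # every output opens with the reproducibility header
  for (f in expected) {
    expect_match(readLines(file.path(out1, f), n = 1L), "^[#{]",
                 info = f)
  }
  # rerun with the same seed: byte-identical outputs
  runBenchmark(cfg, methods = c("mpr_ae", "sa"), cutoffs = c(0, 0.1),
               outDir = out2, testFraction = 0.1,
               acfNpairs = 1e4, acfNbins = 8L)
  for (f in expected) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  # different seed: same schema, different values
  out3 <- withr::local_tempdir()
  runBenchmark(simConfig(seed = 14L, ntips = 150L, nsamples = 8L,
                         readsPerSample = 400L),
               methods = c("mpr_ae", "sa"), cutoffs = c(0, 0.1),
               outDir = out3, testFraction = 0.1,
               acfNpairs = 1e4, acfNbins = 8L)
  expect_false(identical(readLines(file.path(out1, "traits.tsv")),
                         readLines(file.path(out3, "traits.tsv"))))
  expect_identical(readLines(file.path(out1, "cv_sa.tsv"), n = 2L)[2],
                   readLines(file.path(out3, "cv_sa.tsv"), n = 2L)[2])
})
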