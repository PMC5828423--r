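# Generators: trees, trait histories, coverage masks, community profiles.

star_tree <- function(n, len) {
  structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 edge.length = rep(len, n),
                 tip.label = paste0("t", seq_len(n)), Nnode = 1L),
            class = "phylo", order = "cladewise")
}

test_that("simulateTree yields labeled binary trees of the right size", {
  tr <- simulateTree(simConfig(seed = 1L, ntips = 10L))
  expect_equal(ape::Ntip(tr), 10L)
  expect_equal(tr$Nnode, 9L)
  expect_setequal(tr$tip.label, paste0("t", 1:10))
  expect_true(all(tr$edge.length > 0))
  expect_equal(max(ape::node.depth.edgelength(tr)), 0.5, tolerance = 1e-9)

  expect_equal(ape::Ntip(simulateTree(simConfig(seed = 1L, ntips = 1L))), 1L)

  # determinism: same config twice is byte-identical
  expect_identical(writeNewick(simulateTree(simConfig(seed = 5L, ntips = 64L))),
                   writeNewick(simulateTree(simConfig(seed = 5L, ntips = 64L))))
  # birth-death model is also supported and conditioned on N
  bd <- simulateTree(simConfig(seed = 3L, ntips = 50L, treeModel = "bd",
                               birth = 1, death = 0.5))
  expect_equal(ape::Ntip(bd), 50L)
})

test_that("Mk trait simulator matches the ER transition closed form", {
  # rate 0: no evolution anywhere
  tr <- simulateTree(simConfig(seed = 2L, ntips = 30L))
  tt0 <- simulateTraitMk(tr, nstates = 5, rate = 0, seed = 9L)
  expect_equal(length(unique(traitValues(tt0))), 1L)

  # single branch, 1e5 independent replicates via a star tree:
  # P(end = start) = 1/S + (1 - 1/S) exp(-r l S/(S-1)) within 3 sigma
  n <- 1e5
  S <- 4
  r <- 1.3
  l <- 0.6
  st <- star_tree(n, l)
  tt <- simulateTraitMk(st, nstates = S, rate = r, seed = 33L,
                        rootPolicy = "fixed", rootState = 2L)
  p_same_hat <- mean(traitValues(tt) == 2)
  p_same <- 1 / S + (1 - 1 / S) * exp(-r * l * S / (S - 1))
  se <- sqrt(p_same * (1 - p_same) / n)
  expect_lt(abs(p_same_hat - p_same), 3 * se)
})

test_that("high-rate Mk trait reaches the uniform stationary distribution", {
  S <- 15
  st <- star_tree(5000, 0.5)
  tt <- simulateTraitMk(st, nstates = S, rate = 100, seed = 4L,
                        rootPolicy = "fixed", rootState = 1L)
  tab <- tabulate(traitValues(tt), nbins = S)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("bounded walk reflects at the boundaries and mixes to uniform", {
  tr <- simulateTree(simConfig(seed = 2L, ntips = 20L))
  expect_equal(length(unique(traitValues(
    simulateTraitWalk(tr, nstates = 6, rate = 0, seed = 1L)))), 1L)

  # long single branch: stationary distribution uniform on 1..S
  S <- 5
  n <- 1e4
  st <- star_tree(n, 50)  # rate * length >> mixing time
  tt <- simulateTraitWalk(st, nstates = S, rate = 1, seed = 8L,
                          rootPolicy = "fixed", rootState = 1L)
  freq <- tabulate(traitValues(tt), nbins = S) / n
  se <- sqrt((1 / S) * (1 - 1 / S) / n)
  expect_true(all(abs(freq - 1 / S) < 3.5 * se))
  expect_true(all(traitValues(tt) >= 1 & traitValues(tt) <= S))
})

test_that("S=2 bounded walk matches Mk-ER at half its event rate", {
  # walk events at rate r propose +/-1 with prob 1/2; at S=2 half are
  # rejected at the boundary, so the realized switch process is ER with
  # total leaving rate r/2: P(switch) = (1 - exp(-r l)) / 2
  n <- 1e5
  r <- 2
  l <- 0.4
  st <- star_tree(n, l)
  tt <- simulateTraitWalk(st, nstates = 2, rate = r, seed = 21L,
                          rootPolicy = "fixed", rootState = 1L)
  p_switch_hat <- mean(traitValues(tt) == 2)
  p_switch <- (1 - exp(-r * l)) / 2
  se <- sqrt(p_switch * (1 - p_switch) / n)
  expect_lt(abs(p_switch_hat - p_switch), 3 * se)
})

test_that("masking policies hit their coverage targets", {
  tr <- simulateTree(simConfig(seed = 6L, ntips = 1000L))
  full <- simulateTraitMk(tr, nstates = 3, rate = 2, seed = 1L)

  expect_equal(length(knownTips(maskKnown(full, tr, "random", 1, seed = 2L))),
               1000L)

  m <- maskKnown(full, tr, "random", 0.5, seed = 3L)
  expect_true(length(knownTips(m)) >= 459 && length(knownTips(m)) <= 541)

  cd <- maskKnown(full, tr, "clade_drop", 0.5, seed = 4L)
  expect_lte(length(knownTips(cd)), 520L)
  expect_gte(length(knownTips(cd)), 1L)
  # masked tips sit at strictly positive NSTD from the known set
  nstd <- nstdValues(computeNstd(tr, knownTips(cd)))
  masked <- setdiff(tr$tip.label, knownTips(cd))
  expect_true(all(nstd[masked] > 0))
})

test_that("abundance simulation conserves reads and is deterministic", {
  cfg <- simConfig(seed = 11L, ntips = 80L, nsamples = 6L,
                   readsPerSample = 2000L)
  tr <- simulateTree(cfg)
  ab <- simulateAbundances(tr, cfg)
  expect_true(all(colSums(abundanceCounts(ab)) == 2000L))
  expect_equal(dim(abundanceCounts(ab)), c(80L, 6L))
  ab2 <- simulateAbundances(tr, cfg)
  expect_identical(abundanceCounts(ab), abundanceCounts(ab2))

  # a single present OTU holds every read
  cfg1 <- simConfig(seed = 12L, ntips = 1L, nsamples = 2L,
                    readsPerSample = 500L)
  ab1 <- simulateAbundances(simulateTree(cfg1), cfg1)
  expect_true(all(abundanceCounts(ab1) == 500L))
})

test_that("the full generator stack is a pure function of the seed", {
  a <- simulateBenchmark(simConfig(seed = 9L, ntips = 120L, nsamples = 4L,
                                   readsPerSample = 300L))
  b <- simulateBenchmark(simConfig(seed = 9L, ntips = 120L, nsamples = 4L,
                                   readsPerSample = 300L))
  expect_identical(writeNewick(a$tree), writeNewick(b$tree))
  expect_identical(traitValues(a$traits), traitValues(b$traits))
  expect_identical(traitValues(a$masked), traitValues(b$masked))
  expect_identical(abundanceCounts(a$abundances),
                   abundanceCounts(b$abundances))
})
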