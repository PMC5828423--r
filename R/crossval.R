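# NSTD-stratified cross-validation of hidden-state-prediction methods.

#' Cross-validated R-squared as a function of the NSTD cutoff
#'
#' Per repeat, a test set (a fraction of the known tips, drawn without
#' replacement) is held out.  For each NSTD cutoff, the training set is the
#' known tips minus the test set minus every known tip whose minimum
#' patristic distance to \emph{any} test tip falls below the cutoff.  The
#' HSP method is run with training labels only, and the coefficient of
#' determination of the true test values explained by the predictions is
#' recorded.  Cutoffs whose training set is empty, or whose test truth is
#' constant, are flagged (NA) and skipped.  Test sets are drawn
#' independently per repeat and shared across cutoffs within a repeat;
#' per-cutoff values are averaged over repeats.
#'
#' @param tree A rooted \code{phylo}.
#' @param traits A partially known \linkS4class{TraitTable}.
#' @param method HSP method code (see \code{\link{hspPredict}}).
#' @param cutoffs Non-negative NSTD cutoff grid (substitutions/site).
#' @param testFraction Fraction of known tips held out per repeat
#'   (default 0.02).
#' @param repeats Number of repeats (default 3).
#' @param seed RNG seed.
#' @param ... Passed to the HSP method.
#' @return A \linkS4class{CVResult}.
#' @export
crossvalR2Curve <- function(tree, traits, method, cutoffs,
                            testFraction = 0.02, repeats = 3L, seed = 1L,
                            ...) {
  .assert(all(cutoffs >= 0), "cutoffs must be >= 0")
  .assert(testFraction > 0 && testFraction < 1,
          "testFraction must be in (0, 1)")
  .assert(repeats >= 1L, "repeats must be >= 1")
  tree <- .check_tree(tree)
  vals <- traitValues(traits)
  vals <- vals[names(vals) %in% tree$tip.label]
  known <- vals[!is.na(vals)]
  ntest <- max(1L, round(testFraction * length(known)))
  .assert(length(known) > ntest,
          "too few known tips for the requested test fraction")

  nr <- as.integer(repeats)
  nc <- length(cutoffs)
  r2 <- matrix(NA_real_, nr, nc)
  test_size <- matrix(0L, nr, nc)
  train_size <- matrix(0L, nr, nc)
  test_sets <- .with_seed(.substream(seed, "cv_tests"), {
    lapply(seq_len(nr), function(i)
      sample(names(known), ntest, replace = FALSE))
  })
  for (rep_i in seq_len(nr)) {
    test <- test_sets[[rep_i]]
    # min distance from every tip to the test set, in one linear-time pass
    dist_to_test <- nstdValues(computeNstd(tree, test))
    for (ci in seq_len(nc)) {
      cut <- cutoffs[ci]
      train <- setdiff(names(known), test)
      train <- train[dist_to_test[train] >= cut]
      test_size[rep_i, ci] <- length(test)
      train_size[rep_i, ci] <- length(train)
      if (length(train) == 0L) next                    # flagged: skipped
      truth <- unname(known[test])
      if (length(truth) < 2L || sd(truth) == 0) next   # flagged: skipped
      masked <- vals
      masked[!(names(masked) %in% train)] <- NA
      tt <- traitTable(names(masked), unname(masked))
      ps <- hspPredict(tree, tt, method, ...)
      pred <- predictedValues(ps)[test]
      r2[rep_i, ci] <- coefficientOfDetermination(truth, unname(pred))
    }
  }
  .assert(!all(is.na(r2)), "every cutoff was skipped; nothing to report")
  meanR2 <- colMeans(r2, na.rm = TRUE)
  meanR2[!is.finite(meanR2)] <- NA_real_
  new("CVResult", method = method, cutoffs = as.numeric(cutoffs), r2 = r2,
      meanR2 = meanR2, testSize = test_size, trainSize = train_size,
      testFraction = testFraction, repeats = nr, seed = as.integer(seed),
      testSets = test_sets)
}
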