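# Headline statistics: coefficient of determination, trait autocorrelation
# function, NSTI, relative deviation, NSTD-binned R^2.
#
# The ACF estimator uses bin-local means in the Pearson computation.  On
# trees of moderate size, bins whose pair mass is dominated by a few deep
# clades therefore shrink toward zero (the bin mean absorbs between-clade
# covariance) — which is also why empirical trait ACFs plateau at zero
# beyond the distance scale where many independent clades exist.  The
# estimator is ensemble-accurate only in bins aggregating many clades; see
# the methods vignette.

#' Coefficient of determination (fraction of explained variance)
#'
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}.  This is the
#' fraction of variance in \code{reference} explained by \code{predicted};
#' it is asymmetric in its arguments and may be negative (predictions worse
#' than the reference mean).  It is \emph{not} the squared Pearson
#' correlation — see \code{\link{pearsonR2}} for that.
#'
#' @param reference Numeric vector being explained (must have variance > 0).
#' @param predicted Numeric vector of predictions (same length).
#' @return A single numeric value \eqn{\le 1}.
#' @export
#' @examples
#' coefficientOfDetermination(c(1, 2, 3), c(3, 2, 1))  # -3
coefficientOfDetermination <- function(reference, predicted) {
  .assert(length(reference) == length(predicted),
          "reference and predicted must have equal length")
  .assert(length(reference) >= 2L, "need at least 2 values")
  .assert(!anyNA(reference) && !anyNA(predicted), "missing values not allowed")
  sstot <- sum((reference - mean(reference))^2)
  if (sstot <= 0)
    stop("undefined R^2: reference values have zero variance", call. = FALSE)
  1 - sum((reference - predicted)^2) / sstot
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length.
#' @return \eqn{r^2} of the Pearson correlation between x and y.
#' @export
pearsonR2 <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  stats::cor(x, y)^2
}

#' Symmetric relative deviation between two predictions
#'
#' \eqn{|A-B| / ((A+B)/2)}: 0 iff A = B, bounded above by 2.
#'
#' @param A,B Positive numeric vectors (recycled to a common length).
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' relativeDeviation(2, 4)  # 2/3
relativeDeviation <- function(A, B) {
  .assert(all(A > 0) && all(B > 0), "inputs must be positive")
  abs(A - B) / ((A + B) / 2)
}

#' Phylogenetic trait autocorrelation function
#'
#' Samples \code{npairs} ordered tip pairs uniformly at random (with
#' replacement) among the known tips, assigns each pair to one of
#' \code{nbins} equal-width patristic-distance bins spanning
#' \eqn{[0, \max d]} over the sampled pairs, and computes within each bin
#' the Pearson correlation over the symmetrized pair set (each pair
#' contributes both orderings).  Bins with zero trait variance carry an
#' \code{NA} correlation (flagged undefined); empty bins report
#' \code{n_pairs = 0}.
#'
#' @param tree A rooted \code{phylo}.
#' @param traits A \linkS4class{TraitTable} with >= 2 known tips.
#' @param npairs Number of sampled pairs (default \code{1e6}).
#' @param nbins Number of distance bins (default 25).
#' @param seed RNG seed for pair sampling.
#' @return An \linkS4class{ACFCurve}.
#' @export
traitAcf <- function(tree, traits, npairs = 1e6, nbins = 25L, seed = 1L) {
  .assert(npairs >= 1, "npairs must be >= 1")
  .assert(nbins >= 1, "nbins must be >= 1")
  tree <- .check_tree(tree)
  vals <- traitValues(traits)
  vals <- vals[names(vals) %in% tree$tip.label]
  known <- vals[!is.na(vals)]
  .assert(length(known) >= 2L, "need at least 2 known tips")
  labs <- names(known)
  dm <- tipDistanceMatrix(tree, labs)
  nk <- length(known)
  .with_seed(seed, {
    i <- sample.int(nk, npairs, replace = TRUE)
    j <- sample.int(nk, npairs, replace = TRUE)
    d <- dm[cbind(i, j)]
    maxd <- max(d)
    if (maxd <= 0) maxd <- .EPSILON_BL
    width <- maxd / nbins
    bin <- pmin(floor(d / width), nbins - 1L) + 1L
    xi <- unname(known[i])
    xj <- unname(known[j])
    lower <- (seq_len(nbins) - 1L) * width
    out <- data.frame(lower = lower, upper = lower + width,
                      mean_distance = NA_real_, correlation = NA_real_,
                      n_pairs = 0)
    for (b in seq_len(nbins)) {
      sel <- bin == b
      n <- sum(sel)
      if (n == 0L) next
      out$n_pairs[b] <- n
      out$mean_distance[b] <- mean(d[sel])
      # symmetrized pair set: both orderings of every pair
      u <- c(xi[sel], xj[sel])
      v <- c(xj[sel], xi[sel])
      if (stats::sd(u) > 0) {
        out$correlation[b] <- min(1, max(-1, stats::cor(u, v)))
      }
    }
    new("ACFCurve", bins = out, npairs = npairs, nbins = as.integer(nbins),
        seed = as.integer(seed))
  })
}

#' Nearest sequenced taxon index of one community sample
#'
#' Abundance-weighted arithmetic mean NSTD over the considered OTUs:
#' \eqn{\sum_i w_i \mathrm{NSTD}_i} with \eqn{w_i = c_i / \sum c}.
#'
#' @param nstd An \linkS4class{NSTDMap}, or a named numeric vector of
#'   per-OTU NSTDs.
#' @param counts Named numeric vector of read counts for one sample; only
#'   OTUs present in \code{nstd} are considered, and at least one must have
#'   a positive count.
#' @return A single non-negative numeric value.
#' @export
#' @examples
#' computeNsti(c(a = 0, b = 0.2), c(a = 3, b = 1))  # 0.05
computeNsti <- function(nstd, counts) {
  v <- if (is(nstd, "NSTDMap")) nstdValues(nstd) else nstd
  .assert(!is.null(names(v)) && !is.null(names(counts)),
          "nstd and counts must be named by OTU")
  common <- intersect(names(v), names(counts))
  cts <- counts[common]
  .assert(length(common) >= 1L && sum(cts) > 0,
          "need at least one positive count among OTUs with an NSTD")
  sum(cts / sum(cts) * v[common])
}

#' R-squared binned by NSTD
#'
#' Items are assigned to equal-width NSTD bins \eqn{[k w, (k+1) w)}; within
#' each bin holding at least \code{minCount} items the coefficient of
#' determination of \code{reference} explained by \code{predicted} is
#' computed.  Bins below the count threshold are omitted; bins whose
#' reference values have zero variance are flagged undefined (NA) rather
#' than aborting.
#'
#' @param reference,predicted Aligned numeric vectors.
#' @param nstd Per-item NSTD values (same length).
#' @param binWidth Bin width in substitutions/site (e.g. 0.10 for
#'   genome-style, 0.05 for OTU-style comparisons).
#' @param minCount Minimum items per reported bin (default 10).
#' @return A data.frame with columns \code{lower}, \code{upper}, \code{n},
#'   \code{r2} (NA where undefined).
#' @export
binR2ByNstd <- function(reference, predicted, nstd, binWidth = 0.05,
                        minCount = 10L) {
  .assert(binWidth > 0, "binWidth must be > 0")
  n <- length(reference)
  .assert(length(predicted) == n && length(nstd) == n,
          "reference, predicted and nstd must be aligned")
  bin <- floor(nstd / binWidth)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    if (sum(sel) < minCount) return(NULL)
    r2 <- tryCatch(coefficientOfDetermination(reference[sel], predicted[sel]),
                   error = function(e) NA_real_)
    data.frame(lower = b * binWidth, upper = (b + 1) * binWidth,
               n = sum(sel), r2 = r2)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(lower = numeric(), upper = numeric(),
                      n = integer(), r2 = numeric())
  }
  rownames(out) <- NULL
  out
}
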