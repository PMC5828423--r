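# Tool-agreement analyses across community samples, the NSTI-R^2 trend with
# its permutation test, and GCN-based read-count correction.

#' Compare two prediction sets across community samples
#'
#' For every sample, restricts to OTUs with at least one read and a
#' prediction from both sets, computes the coefficient of determination of
#' the first tool's predictions explained by the second's, and the sample's
#' NSTI from per-OTU NSTDs weighted by relative abundances.  When the two
#' prediction sets carry different NSTDs for an OTU (different calibration
#' sets), the OTU's NSTD is their arithmetic average.  Samples with fewer
#' than two eligible OTUs, or zero variance in the first tool's predictions,
#' are flagged (\code{excluded = TRUE}) and left out of downstream trends.
#'
#' @param predA,predB \linkS4class{PredictionSet}s from two methods/tools
#'   (A is explained by B).
#' @param abundances An \linkS4class{AbundanceTable}.
#' @param nstdA An \linkS4class{NSTDMap} for tool A's calibration set.
#' @param nstdB Optional \linkS4class{NSTDMap} for tool B (defaults to
#'   \code{nstdA}).
#' @return A data.frame with one row per sample: \code{sample},
#'   \code{group}, \code{n_otus}, \code{r2}, \code{nsti},
#'   \code{mean_pred_a}, \code{mean_pred_b}, \code{excluded}.
#' @export
comparePredictionSets <- function(predA, predB, abundances, nstdA,
                                  nstdB = nstdA) {
  va <- predictedValues(predA)
  vb <- predictedValues(predB)
  na_ <- nstdValues(nstdA)
  nb_ <- nstdValues(nstdB)
  m <- abundanceCounts(abundances)
  groups <- sampleGroups(abundances)
  shared <- intersect(intersect(names(va), names(vb)), rownames(m))
  .assert(length(shared) >= 1L,
          "no OTUs are shared between the prediction sets and the table")
  nstd_avg <- (na_[shared] + nb_[shared]) / 2

  rows <- lapply(colnames(m), function(s) {
    cts <- m[shared, s]
    eligible <- shared[cts >= 1]
    n <- length(eligible)
    r2 <- NA_real_
    nsti <- NA_real_
    excluded <- TRUE
    if (n >= 2L) {
      nsti <- sum(cts[eligible] / sum(cts[eligible]) * nstd_avg[eligible])
      r2 <- tryCatch(
        coefficientOfDetermination(unname(va[eligible]),
                                   unname(vb[eligible])),
        error = function(e) NA_real_)
      excluded <- is.na(r2)
    }
    data.frame(sample = s, group = unname(groups[s]), n_otus = n,
               r2 = r2, nsti = nsti,
               mean_pred_a = if (n) mean(va[eligible]) else NA_real_,
               mean_pred_b = if (n) mean(vb[eligible]) else NA_real_,
               excluded = excluded)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson trend between per-sample R-squared and NSTI, with permutation test
#'
#' Computes the Pearson correlation r (and \eqn{r^2}) between NSTI and
#' \eqn{R^2} across the non-excluded samples of one group, plus a
#' permutation P value: \eqn{P = (b+1)/(m+1)} where b counts permutations
#' (shuffling the \eqn{R^2} vector against NSTI) with
#' \eqn{|r_{perm}| \ge |r_{obs}|}.
#'
#' @param comparisons Output of \code{\link{comparePredictionSets}}.
#' @param group Optional group label to restrict to (default: all samples).
#' @param permutations Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return A list with elements \code{group}, \code{n}, \code{r},
#'   \code{r2}, \code{pValue}, \code{permutations}, \code{slope},
#'   \code{intercept}.
#' @export
nstiR2Trend <- function(comparisons, group = NULL, permutations = 1000L,
                        seed = 1L) {
  df <- comparisons[!comparisons$excluded & !is.na(comparisons$nsti), ]
  if (!is.null(group)) df <- df[!is.na(df$group) & df$group == group, ]
  .assert(nrow(df) >= 3L, "need at least 3 samples in the group")
  x <- df$nsti
  y <- df$r2
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined trend: constant NSTI or constant R^2", call. = FALSE)
  r_obs <- stats::cor(x, y)
  b <- .with_seed(.substream(seed, "nsti_perm"), {
    sum(vapply(seq_len(permutations), function(i) {
      abs(stats::cor(x, sample(y))) >= abs(r_obs)
    }, logical(1)))
  })
  fit <- stats::lm.fit(cbind(1, x), y)$coefficients
  list(group = if (is.null(group)) NA_character_ else group,
       n = nrow(df), r = r_obs, r2 = r_obs^2,
       pValue = (b + 1) / (permutations + 1),
       permutations = as.integer(permutations),
       slope = unname(fit[2L]), intercept = unname(fit[1L]))
}

#' Correct read counts for gene copy number
#'
#' Divides each OTU's read counts by its predicted GCN
#' (\eqn{c_i / \mathrm{GCN}_i}), per sample; with
#' \code{renormalize = TRUE} each sample is then divided by its sum, giving
#' relative cell-abundance estimates that sum to 1.
#'
#' @param abundances An \linkS4class{AbundanceTable}.
#' @param predictions A \linkS4class{PredictionSet}; every OTU with a
#'   positive count must have a prediction \eqn{\ge 1}.
#' @param renormalize Logical (default TRUE).
#' @return A real-valued matrix (OTUs x samples).
#' @export
correctAbundances <- function(abundances, predictions, renormalize = TRUE) {
  m <- abundanceCounts(abundances)
  p <- predictedValues(predictions)
  present <- rownames(m)[rowSums(m) > 0]
  missing <- setdiff(present, names(p))
  if (length(missing)) {
    stop(sprintf("missing GCN prediction for OTU(s) with reads: %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  if (any(p[present] < 1)) {
    stop(sprintf("GCN prediction < 1 for OTU(s): %s",
                 paste(head(present[p[present] < 1], 5L), collapse = ", ")),
         call. = FALSE)
  }
  gcn <- rep(1, nrow(m))
  names(gcn) <- rownames(m)
  gcn[names(p)[names(p) %in% rownames(m)]] <-
    p[names(p) %in% rownames(m)]
  corrected <- m / gcn
  if (renormalize) {
    cs <- colSums(corrected)
    cs[cs == 0] <- 1
    corrected <- sweep(corrected, 2L, cs, "/")
  }
  corrected
}
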