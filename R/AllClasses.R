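# S4 container classes.  Trees themselves are kept as ape 'phylo' objects
# (the field's standard container); these classes hold everything layered on
# top of a tree: trait tables, predictions, NSTD maps, ACF curves,
# cross-validation results, Mk fits, and simulation configurations.

#' TraitTable: tip-to-trait mapping with missing values
#'
#' Maps tip labels to positive-integer trait values (gene copy numbers).
#' Missing values (\code{NA}) mark tips whose trait is unknown — the "hidden
#' states" that hidden-state prediction fills in.
#'
#' @slot tip Character vector of tip labels (unique, non-empty).
#' @slot gcn Numeric vector of trait values; each is \code{NA} or an integer
#'   \eqn{\ge 1}.
#' @export
setClass("TraitTable",
         representation(tip = "character", gcn = "numeric"))

setValidity("TraitTable", function(object) {
  msg <- character()
  if (length(object@tip) != length(object@gcn))
    msg <- c(msg, "tip and gcn must have equal length")
  if (anyDuplicated(object@tip))
    msg <- c(msg, "tip labels must be unique")
  if (length(object@tip) && !all(nzchar(object@tip)))
    msg <- c(msg, "tip labels must be non-empty")
  v <- object@gcn[!is.na(object@gcn)]
  if (length(v) && any(v < 1))
    msg <- c(msg, "all present trait values must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a TraitTable
#'
#' @param tip Character vector of tip labels.
#' @param gcn Numeric vector of trait values (\code{NA} = unknown).
#' @return A \linkS4class{TraitTable}.
#' @export
#' @examples
#' traitTable(c("t1", "t2", "t3"), c(1, NA, 7))
traitTable <- function(tip, gcn) {
  new("TraitTable", tip = as.character(tip), gcn = as.numeric(gcn))
}

#' @describeIn traitTable Tip labels of a TraitTable.
#' @param x A \code{TraitTable}.
#' @export
traitTips <- function(x) x@tip

#' @describeIn traitTable Trait values (named by tip).
#' @export
traitValues <- function(x) stats::setNames(x@gcn, x@tip)

#' @describeIn traitTable Labels of tips with a known (non-missing) value.
#' @export
knownTips <- function(x) x@tip[!is.na(x@gcn)]

setMethod("show", "TraitTable", function(object) {
  n <- length(object@tip)
  k <- sum(!is.na(object@gcn))
  cat(sprintf("TraitTable: %d tips, %d known (%.1f%%)\n",
              n, k, if (n) 100 * k / n else 0))
  if (k) {
    v <- object@gcn[!is.na(object@gcn)]
    cat(sprintf("  known values: range [%g, %g], mean %.3f\n",
                min(v), max(v), mean(v)))
  }
})

#' PredictionSet: per-tip trait predictions from one HSP method
#'
#' @slot tip Character vector of tip labels (covers every tip of the tree it
#'   was computed on).
#' @slot value Numeric predictions (\eqn{\ge 1} for gene copy numbers; not
#'   necessarily integer).
#' @slot method Method name (e.g. \code{"mpr_exp"}).
#' @slot params Named list of method parameters.
#' @slot details List of optional per-tip extras (MPR state sets, posterior
#'   matrices, an \linkS4class{MkFit}).
#' @export
setClass("PredictionSet",
         representation(tip = "character", value = "numeric",
                        method = "character", params = "list",
                        details = "list"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  if (length(object@tip) != length(object@value))
    msg <- c(msg, "tip and value must have equal length")
  if (anyDuplicated(object@tip)) msg <- c(msg, "tip labels must be unique")
  if (anyNA(object@value)) msg <- c(msg, "predictions must be non-missing")
  if (length(msg)) msg else TRUE
})

#' Accessors for PredictionSet
#'
#' @param x A \linkS4class{PredictionSet}.
#' @return \code{predictedValues} returns a named numeric vector;
#'   \code{predictionMethod} the method name string.
#' @export
predictedValues <- function(x) stats::setNames(x@value, x@tip)

#' @rdname predictedValues
#' @export
predictionMethod <- function(x) x@method

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: method '%s', %d tips, values in [%.3g, %.3g]\n",
              object@method, length(object@tip),
              min(object@value), max(object@value)))
})

#' NSTDMap: nearest-sequenced-taxon distances
#'
#' For every tip, the minimum patristic distance to any tip of the designated
#' "known" set (tips with a sequenced genome).  Known tips have NSTD 0.
#'
#' @slot tip Character tip labels.
#' @slot nstd Non-negative distances (substitutions/site).
#' @slot known Logical; membership in the known set.
#' @export
setClass("NSTDMap",
         representation(tip = "character", nstd = "numeric",
                        known = "logical"))

setValidity("NSTDMap", function(object) {
  msg <- character()
  n <- length(object@tip)
  if (length(object@nstd) != n || length(object@known) != n)
    msg <- c(msg, "tip, nstd and known must have equal length")
  if (any(object@nstd < 0)) msg <- c(msg, "NSTD must be >= 0")
  if (any(object@nstd[object@known] != 0))
    msg <- c(msg, "known tips must have NSTD exactly 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn computeNstd NSTD values as a named numeric vector.
#' @param x An \code{NSTDMap}.
#' @export
nstdValues <- function(x) stats::setNames(x@nstd, x@tip)

setMethod("show", "NSTDMap", function(object) {
  cat(sprintf(
    "NSTDMap: %d tips, %d known; NSTD median %.4g, max %.4g subst/site\n",
    length(object@tip), sum(object@known),
    stats::median(object@nstd), max(object@nstd)))
})

#' ACFCurve: phylogenetic trait autocorrelation function
#'
#' Pearson correlation between trait values of randomly sampled tip pairs,
#' binned by patristic distance.
#'
#' @slot bins A data.frame with columns \code{lower}, \code{upper},
#'   \code{mean_distance}, \code{correlation} (NA where undefined),
#'   \code{n_pairs}.
#' @slot npairs Number of sampled pairs.
#' @slot nbins Number of distance bins.
#' @slot seed RNG seed used for pair sampling.
#' @export
setClass("ACFCurve",
         representation(bins = "data.frame", npairs = "numeric",
                        nbins = "integer", seed = "integer"))

setValidity("ACFCurve", function(object) {
  msg <- character()
  b <- object@bins
  need <- c("lower", "upper", "mean_distance", "correlation", "n_pairs")
  if (!all(need %in% names(b)))
    msg <- c(msg, paste("bins must have columns:", paste(need, collapse = ", ")))
  else {
    if (is.unsorted(b$lower)) msg <- c(msg, "bins must be ordered")
    if (any(b$upper <= b$lower)) msg <- c(msg, "bins must have positive width")
    ok <- !is.na(b$correlation)
    if (any(abs(b$correlation[ok]) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (sum(b$n_pairs) > object@npairs)
      msg <- c(msg, "pair counts cannot exceed Npairs")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn traitAcf The per-bin table of an ACFCurve.
#' @param x An \code{ACFCurve}.
#' @export
acfBins <- function(x) x@bins

setMethod("show", "ACFCurve", function(object) {
  def <- !is.na(object@bins$correlation)
  cat(sprintf("ACFCurve: %d bins (%d defined), %g sampled pairs\n",
              nrow(object@bins), sum(def), object@npairs))
  if (any(def)) {
    cat(sprintf("  correlation %.3f at d=%.3g -> %.3f at d=%.3g\n",
                object@bins$correlation[which(def)[1]],
                object@bins$mean_distance[which(def)[1]],
                object@bins$correlation[rev(which(def))[1]],
                object@bins$mean_distance[rev(which(def))[1]]))
  }
})

#' MkFit: maximum-likelihood fit of the equal-rates Mk model
#'
#' @slot rate Estimated total leaving rate \eqn{\hat\lambda \ge 0}.
#' @slot logLik Maximized log-likelihood.
#' @slot rootPrior Root prior vector (empirical known-tip state frequencies).
#' @slot trials Number of optimizer restarts used.
#' @slot boundary TRUE if the rate was pinned at the optimizer's lower bound
#'   (e.g. all known tips identical).
#' @export
setClass("MkFit",
         representation(rate = "numeric", logLik = "numeric",
                        rootPrior = "numeric", trials = "integer",
                        boundary = "logical"))

setValidity("MkFit", function(object) {
  msg <- character()
  if (object@rate < 0) msg <- c(msg, "rate must be >= 0")
  if (!is.finite(object@logLik)) msg <- c(msg, "log-likelihood must be finite")
  if (abs(sum(object@rootPrior) - 1) > 1e-9)
    msg <- c(msg, "root prior must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MkFit", function(object) {
  cat(sprintf(
    "MkFit (ER): rate %.5g, logLik %.4f, %d restarts%s\n",
    object@rate, object@logLik, object@trials,
    if (object@boundary) " [boundary]" else ""))
})

#' CVResult: NSTD-stratified cross-validation of one HSP method
#'
#' @slot method Method name.
#' @slot cutoffs NSTD cutoff grid (substitutions/site).
#' @slot r2 Matrix (repeats x cutoffs) of per-repeat \eqn{R^2}; NA where a
#'   cutoff was skipped (empty training set or constant test truth).
#' @slot meanR2 Per-cutoff mean over non-skipped repeats (NA if all skipped).
#' @slot testSize,trainSize Matrices (repeats x cutoffs) of set sizes.
#' @slot testFraction Fraction of known tips held out per repeat.
#' @slot repeats Number of repeats.
#' @slot seed RNG seed.
#' @slot testSets List (one per repeat) of held-out tip labels, recorded so
#'   the no-leakage contract can be audited.
#' @export
setClass("CVResult",
         representation(method = "character", cutoffs = "numeric",
                        r2 = "matrix", meanR2 = "numeric",
                        testSize = "matrix", trainSize = "matrix",
                        testFraction = "numeric", repeats = "integer",
                        seed = "integer", testSets = "list"))

setValidity("CVResult", function(object) {
  msg <- character()
  if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
  if (ncol(object@r2) != length(object@cutoffs))
    msg <- c(msg, "r2 must have one column per cutoff")
  ok <- !is.na(object@meanR2)
  if (any(object@meanR2[ok] > 1 + 1e-9)) msg <- c(msg, "R^2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn crossvalR2Curve Mean cross-validated R-squared per cutoff.
#' @param x A \code{CVResult}.
#' @export
cvMeanR2 <- function(x) stats::setNames(x@meanR2, format(x@cutoffs))

#' @describeIn crossvalR2Curve NSTD cutoffs of the result grid.
#' @export
cvCutoffs <- function(x) x@cutoffs

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: method '%s', %d repeats x %d cutoffs (test fraction %.3g)\n",
    object@method, object@repeats, length(object@cutoffs),
    object@testFraction))
  print(round(stats::setNames(object@meanR2, format(object@cutoffs)), 3))
})

#' SimConfig: configuration of the synthetic-data generators
#'
#' Bundles every knob of the simulation: tree model, depth rescaling, trait
#' model, masking policy and abundance model.  The default configuration is
#' the "benchmark-small" regime used throughout the package's tests: a
#' 2000-tip pure-birth tree rescaled to depth 0.5 substitutions/site, an
#' equal-rates Mk trait on states 1..15 with its rate calibrated so the trait
#' autocorrelation is 0.5 at patristic distance 0.15, clade-drop masking to
#' 50\% known tips, and log-normal community profiles.
#'
#' @slot seed Master RNG seed.
#' @slot ntips Number of tips N.
#' @slot treeModel "yule" (pure birth) or "bd" (birth-death).
#' @slot birth,death Birth and death rates (death < birth).
#' @slot depth Target root-to-tip depth after rescaling (subst/site).
#' @slot traitModel "mk_er" or "bounded_walk".
#' @slot nstates Number of trait states S.
#' @slot rate Trait evolution rate.
#' @slot rootPolicy "stationary" or "fixed".
#' @slot rootState Root state when rootPolicy = "fixed".
#' @slot maskPolicy "random" or "clade_drop".
#' @slot knownFraction Target fraction of tips with known trait.
#' @slot nsamples Number of community samples.
#' @slot readsPerSample Sequencing depth per sample.
#' @slot logMu,logSigma Log-normal abundance parameters.
#' @slot presentFraction Fraction of tips present per sample.
#' @export
setClass("SimConfig",
         representation(seed = "integer", ntips = "integer",
                        treeModel = "character", birth = "numeric",
                        death = "numeric", depth = "numeric",
                        traitModel = "character", nstates = "integer",
                        rate = "numeric", rootPolicy = "character",
                        rootState = "integer", maskPolicy = "character",
                        knownFraction = "numeric", nsamples = "integer",
                        readsPerSample = "integer", logMu = "numeric",
                        logSigma = "numeric", presentFraction = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@ntips < 1L) msg <- c(msg, "ntips must be >= 1")
  if (!object@treeModel %in% c("yule", "bd"))
    msg <- c(msg, "treeModel must be 'yule' or 'bd'")
  if (object@treeModel == "bd" && object@death >= object@birth)
    msg <- c(msg, "death rate must be < birth rate")
  if (!object@traitModel %in% c("mk_er", "bounded_walk"))
    msg <- c(msg, "traitModel must be 'mk_er' or 'bounded_walk'")
  if (object@nstates < 2L) msg <- c(msg, "nstates must be >= 2")
  if (object@rate < 0 || !is.finite(object@rate))
    msg <- c(msg, "rate must be finite and >= 0")
  if (!object@rootPolicy %in% c("stationary", "fixed"))
    msg <- c(msg, "rootPolicy must be 'stationary' or 'fixed'")
  if (!object@maskPolicy %in% c("random", "clade_drop"))
    msg <- c(msg, "maskPolicy must be 'random' or 'clade_drop'")
  if (object@knownFraction <= 0 || object@knownFraction > 1)
    msg <- c(msg, "knownFraction must be in (0, 1]")
  if (object@presentFraction <= 0 || object@presentFraction > 1)
    msg <- c(msg, "presentFraction must be in (0, 1]")
  if (object@logSigma < 0) msg <- c(msg, "logSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d tips (%s), depth %.3g; trait %s S=%d rate %.4g;\n",
    object@ntips, object@treeModel, object@depth, object@traitModel,
    object@nstates, object@rate))
  cat(sprintf(
    "  mask %s to %.0f%% known; %d samples x %d reads; seed %d\n",
    object@maskPolicy, 100 * object@knownFraction, object@nsamples,
    object@readsPerSample, object@seed))
})
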