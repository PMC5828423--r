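# End-to-end benchmark driver: simulate, analyze, report.

#' Run the full synthetic benchmark
#'
#' Simulates a tree, trait history, coverage mask and community profiles
#' from a \linkS4class{SimConfig}; computes the trait ACF, the NSTD map of
#' the known set, an NSTD-stratified cross-validation curve per method, a
#' two-method community comparison with its NSTI trend; and writes every
#' result as machine-readable TSV/JSON under \code{outDir}.  Fully
#' deterministic given the config seed; partial outputs are removed if any
#' stage fails.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param methods HSP method codes for cross-validation (default
#'   \code{c("mpr_exp", "pic", "sa")}).
#' @param cutoffs NSTD cutoff grid (default \code{seq(0, 0.4, by = 0.05)}).
#' @param outDir Output directory (created if needed).
#' @param compareMethods Two method codes compared across samples (default
#'   the first two of \code{methods}, or \code{c("mpr_ae","sa")} if fewer).
#' @param testFraction Held-out fraction per cross-validation repeat.
#' @param acfNpairs,acfNbins ACF sampling parameters.
#' @return Invisibly, a list with the in-memory results (\code{data},
#'   \code{acf}, \code{nstd}, \code{cv}, \code{comparison}, \code{trend},
#'   \code{files}).
#' @export
runBenchmark <- function(config, methods = c("mpr_exp", "pic", "sa"),
                         cutoffs = seq(0, 0.4, by = 0.05), outDir,
                         compareMethods = NULL, testFraction = 0.02,
                         acfNpairs = 1e6, acfNbins = 25L) {
  validObject(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  hdr <- function(sub) {
    sprintf("phylogcn %s | benchmark/%s | seed=%d",
            as.character(utils::packageVersion("phylogcn")), sub,
            config@seed)
  }
  wfile <- function(name) {
    f <- file.path(outDir, name)
    written <<- c(written, f)
    f
  }

  data <- simulateBenchmark(config)
  writeNewick(data$tree, wfile("tree.nwk"), header = hdr("tree"))
  writeTraitTable(data$traits, wfile("traits.tsv"), header = hdr("traits"))
  writeTraitTable(data$masked, wfile("traits_masked.tsv"),
                  header = hdr("traits_masked"))
  writeAbundanceTable(data$abundances, wfile("abundances.tsv"),
                      header = hdr("abundances"))

  acf <- traitAcf(data$tree, data$masked, npairs = acfNpairs,
                  nbins = acfNbins, seed = .substream(config@seed, "acf"))
  f <- wfile("acf.tsv")
  con <- file(f, "w")
  writeLines(paste0("# ", hdr("acf")), con)
  close(con)
  suppressWarnings(write.table(acfBins(acf), f, sep = "\t", row.names = FALSE,
                               quote = FALSE, append = TRUE))

  nstd <- computeNstd(data$tree, knownTips(data$masked))
  f <- wfile("nstd.tsv")
  con <- file(f, "w")
  writeLines(c(paste0("# ", hdr("nstd")), "tip_id\tnstd\tknown"), con)
  writeLines(paste(nstd@tip, sprintf("%.12g", nstd@nstd),
                   as.integer(nstd@known), sep = "\t"), con)
  close(con)

  cv <- list()
  for (m in methods) {
    res <- crossvalR2Curve(data$tree, data$masked, m, cutoffs,
                           testFraction = testFraction,
                           seed = .substream(config@seed, paste0("cv_", m)))
    cv[[m]] <- res
    f <- wfile(sprintf("cv_%s.tsv", m))
    con <- file(f, "w")
    writeLines(c(paste0("# ", hdr(paste0("cv/", m))),
                 "cutoff\tmean_r2\tmin_train_size\ttest_size"), con)
    writeLines(paste(sprintf("%.12g", res@cutoffs),
                     sprintf("%.12g", res@meanR2),
                     apply(res@trainSize, 2L, min),
                     res@testSize[1L, ], sep = "\t"), con)
    close(con)
  }

  cmp_methods <- compareMethods
  if (is.null(cmp_methods)) {
    cmp_methods <- if (length(methods) >= 2L) methods[1:2] else
      c("mpr_ae", "sa")
  }
  predA <- hspPredict(data$tree, data$masked, cmp_methods[1L])
  predB <- hspPredict(data$tree, data$masked, cmp_methods[2L])
  comparison <- comparePredictionSets(predA, predB, data$abundances, nstd)
  f <- wfile("sample_comparison.tsv")
  con <- file(f, "w")
  writeLines(paste0("# ", hdr(paste("compare", cmp_methods[1L],
                                    cmp_methods[2L]))), con)
  close(con)
  suppressWarnings(write.table(comparison, f, sep = "\t", row.names = FALSE,
                               quote = FALSE, append = TRUE))

  trend <- nstiR2Trend(comparison,
                       seed = .substream(config@seed, "trend"))
  jsonlite::write_json(trend, wfile("trend.json"), auto_unbox = TRUE,
                       digits = NA)

  summary <- list(
    seed = config@seed, ntips = config@ntips,
    known_fraction = length(knownTips(data$masked)) / config@ntips,
    methods = methods, cutoffs = cutoffs,
    mean_r2_by_cutoff = lapply(cv, function(x) unname(x@meanR2)),
    compare_methods = cmp_methods,
    trend_r = trend$r, trend_p = trend$pValue)
  jsonlite::write_json(summary, wfile("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  ok <- TRUE
  invisible(list(data = data, acf = acf, nstd = nstd, cv = cv,
                 comparison = comparison, trend = trend, files = written))
}
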