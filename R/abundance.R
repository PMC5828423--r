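#' AbundanceTable: OTU read counts across community samples
#'
#' A thin wrapper around \link[SummarizedExperiment]{SummarizedExperiment}
#' with rows = OTUs (tree tips), columns = samples, one \code{"counts"}
#' assay of non-negative integer read counts, and an optional per-sample
#' \code{group} label in \code{colData} (e.g. "animal" / "non-animal").
#'
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("must carry a 'counts' assay")
  m <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(m) || any(m < 0)) msg <- c(msg, "counts must be >= 0")
  if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "OTU labels must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "sample labels must be present and unique")
  if (ncol(m) && any(colSums(m) == 0))
    msg <- c(msg, "every retained sample needs at least one positive count")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param counts Integer matrix, OTUs x samples, with dimnames.
#' @param group Optional character vector of per-sample group labels.
#' @return An \linkS4class{AbundanceTable}.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' abundanceTable(m, group = c("animal", "non-animal"))
abundanceTable <- function(counts, group = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  cd <- if (is.null(group)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    .assert(length(group) == ncol(counts),
            "'group' must have one label per sample")
    S4Vectors::DataFrame(group = as.character(group),
                         row.names = colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("AbundanceTable", se)
}

#' @describeIn abundanceTable The counts matrix (OTUs x samples).
#' @param x An \code{AbundanceTable}.
#' @export
abundanceCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn abundanceTable Per-sample group labels (NA if unset).
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% names(cd)) {
    stats::setNames(as.character(cd$group), rownames(cd))
  } else {
    stats::setNames(rep(NA_character_, ncol(x)), colnames(x))
  }
}

setMethod("show", "AbundanceTable", function(object) {
  m <- abundanceCounts(object)
  cat(sprintf(
    "AbundanceTable: %d OTUs x %d samples, %g reads total\n",
    nrow(m), ncol(m), sum(as.numeric(m))))
  g <- sampleGroups(object)
  if (!all(is.na(g))) {
    tb <- table(g, useNA = "no")
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
})
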