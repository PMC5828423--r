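# Newick and TSV input/output.  Parsing and serialization of newick strings
# are delegated to ape; this layer adds the package's validation contract
# (rootedness, unique non-empty tip labels, NA branch lengths read as 0).

#' Parse a newick string into a validated rooted tree
#'
#' Accepts a single newick statement terminated by \code{";"}; supports
#' quoted labels, internal-node labels, missing branch lengths (read as 0)
#' and polytomies.  Internal-node labels are preserved but never used for
#' trait lookup; only leaf labels key trait and abundance tables.
#'
#' @param text A newick string.
#' @return A rooted \code{ape::phylo} object.
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parseNewick <- function(text) {
  .assert(is.character(text) && length(text) == 1L,
          "'text' must be a single character string")
  .assert(grepl(";", text, fixed = TRUE),
          sprintf("newick parse error: no terminating ';' in %s",
                  deparse(substr(text, 1, 60))))
  # balanced parentheses check gives a character offset ape does not report
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at character %d: unbalanced ')'", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' in string", depth),
         call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop(sprintf("newick parse error in %s", deparse(substr(text, 1, 60))),
         call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    .assert(length(tr) == 1L, "expected a single newick statement")
    tr <- tr[[1L]]
  }
  unquote <- function(x) sub("^'(.*)'$", "\\1", x)
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  .check_tree(tr)
}

#' Serialize a tree to newick
#'
#' @param tree A \code{phylo} object.
#' @param path Optional file path; if \code{NULL} the string is returned.
#' @param header Optional comment lines (prefixed \code{"#"}) written before
#'   the newick statement when writing to a file.
#' @return The newick string, invisibly when writing to a file.
#' @export
writeNewick <- function(tree, path = NULL, header = NULL) {
  tree <- .check_tree(tree)
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(s, con)
  invisible(s)
}

#' Read a trait table from TSV
#'
#' Expects a header row and columns \code{tip_id} and \code{gcn} (first two
#' columns are used); missing trait values are encoded as \code{"NA"}.
#' Lines starting with \code{"#"} are treated as comments.
#'
#' @param path Path to a tab-separated file.
#' @return A \linkS4class{TraitTable}.
#' @export
readTraitTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", quote = "", check.names = FALSE,
                   na.strings = character())
  .assert(ncol(df) >= 2L, "trait table needs columns (tip_id, gcn)")
  raw <- df[[2L]]
  bad <- !(raw == "NA" | grepl("^\\s*[0-9]+(\\.[0-9]+)?\\s*$", raw))
  if (any(bad)) {
    stop(sprintf("trait table format error at data line %d: non-numeric GCN %s",
                 which(bad)[1L], deparse(raw[which(bad)[1L]])), call. = FALSE)
  }
  traitTable(df[[1L]], suppressWarnings(as.numeric(raw)))
}

#' Write a trait table to TSV
#'
#' @param x A \linkS4class{TraitTable}.
#' @param path Output path.
#' @param header Optional comment lines written before the header row.
#' @export
writeTraitTable <- function(x, path, header = NULL) {
  stopifnot(is(x, "TraitTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("tip_id\tgcn", con)
  val <- ifelse(is.na(x@gcn), "NA", sprintf("%.12g", x@gcn))
  writeLines(paste(x@tip, val, sep = "\t"), con)
  invisible(path)
}

#' Read an OTU abundance table from TSV
#'
#' First column = OTU id, remaining columns = samples (integer read counts).
#'
#' @param path Path to a tab-separated file.
#' @param group Optional named character vector (or path to a 2-column TSV
#'   \code{sample_id<TAB>group}) assigning group labels to samples.
#' @return An \linkS4class{AbundanceTable}.
#' @export
readAbundanceTable <- function(path, group = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   quote = "", check.names = FALSE)
  .assert(ncol(df) >= 2L, "abundance table needs OTU ids plus >=1 sample")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (any(is.na(m)) || any(m < 0))
    stop("abundance table validation error: counts must be non-negative",
         call. = FALSE)
  rownames(m) <- as.character(df[[1L]])
  if (is.character(group) && length(group) == 1L && file.exists(group)) {
    g <- read.table(group, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character")
    group <- stats::setNames(g[[2L]], g[[1L]])
  }
  if (!is.null(group)) group <- unname(group[colnames(m)])
  abundanceTable(m, group = group)
}

#' Write an abundance (or corrected-abundance) table to TSV
#'
#' @param x An \linkS4class{AbundanceTable} or a numeric matrix
#'   (OTUs x samples) such as the output of \code{\link{correctAbundances}}.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
writeAbundanceTable <- function(x, path, header = NULL) {
  m <- if (is(x, "AbundanceTable")) abundanceCounts(x) else as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("otu_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}
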