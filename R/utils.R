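# Shared internal helpers.

# Branch-length floor used wherever an algorithm divides by a branch length
# (weighted squared-change parsimony, independent contrasts, polytomy
# resolution).  Units: expected nucleotide substitutions per site.
.EPSILON_BL <- 1e-8

#' Branch-length epsilon
#'
#' Zero or missing branch lengths are replaced by this constant
#' (\code{1e-8} expected substitutions per site) in computations that divide
#' by branch length.
#'
#' @return A single numeric value.
#' @export
#' @examples
#' branchLengthEpsilon()
branchLengthEpsilon <- function() .EPSILON_BL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-stream seed from a master seed and a stage label.
# Keeps results below 2^31 so they remain valid R integers.
.substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}

# Validate a tree as the package's substrate: rooted ape::phylo with unique,
# non-empty tip labels and non-negative branch lengths (NA -> 0).
.check_tree <- function(tree) {
  .assert(inherits(tree, "phylo"), "'tree' must be an ape 'phylo' object")
  .assert(length(tree$tip.label) >= 1L, "tree must have at least one tip")
  .assert(!anyDuplicated(tree$tip.label),
          "duplicate tip labels are not allowed")
  .assert(all(nzchar(tree$tip.label)), "tip labels must be non-empty")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  .assert(all(tree$edge.length >= 0), "branch lengths must be >= 0")
  tree
}

# Precompute traversal structures for a phylo object:
#   ntip, nnode, root, parent[], children[[]], edge length per node (0 at
#   root), postorder node sequence (tips first as encountered), preorder.
.tree_index <- function(tree) {
  tree <- .check_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- integer(nnode)
  parent[] <- NA_integer_
  blen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen[tree$edge[, 2L]] <- tree$edge.length
  children <- vector("list", nnode)
  if (nrow(tree$edge) > 0L) {
    ord <- order(tree$edge[, 1L])
    sp <- split(tree$edge[ord, 2L], tree$edge[ord, 1L])
    children[as.integer(names(sp))] <- sp
  }
  # postorder over nodes: children before parents
  po_edges <- reorder(tree, "postorder")$edge
  post <- unique(c(as.vector(t(po_edges[, 2:1, drop = FALSE])), root))
  post <- post[!duplicated(post)]
  # ensure parents come after all children: use edge postorder child column,
  # then root last
  post <- c(po_edges[, 2L], root)
  post <- post[!duplicated(post)]
  pre <- rev(post)
  list(tree = tree, ntip = ntip, nnode = nnode, root = root,
       parent = parent, children = children, blen = blen,
       postorder = post, preorder = pre)
}

# Depth (distance from root) of every node.
.node_depths <- function(idx) {
  depth <- numeric(idx$nnode)
  for (v in idx$preorder) {
    if (!is.na(idx$parent[v])) depth[v] <- depth[idx$parent[v]] + idx$blen[v]
  }
  depth
}

.match_tips <- function(labels, tree, what = "tip") {
  i <- match(labels, tree$tip.label)
  if (anyNA(i)) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(head(labels[is.na(i)], 5L), collapse = ", ")),
         call. = FALSE)
  }
  i
}
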