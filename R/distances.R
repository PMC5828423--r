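# Patristic-distance primitives and nearest-sequenced-taxon distances.

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the unique path between two tips; symmetric,
#' and 0 for a tip against itself.
#'
#' @param tree A rooted \code{phylo} object.
#' @param tip1,tip2 Tip labels.
#' @return A non-negative numeric distance (substitutions/site).
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' patristicDistance(tr, "A", "C")  # 4
patristicDistance <- function(tree, tip1, tip2) {
  idx <- .tree_index(tree)
  i <- .match_tips(c(tip1, tip2), idx$tree)
  if (i[1L] == i[2L]) return(0)
  depth <- .node_depths(idx)
  # ancestor chains to the root
  anc <- function(v) {
    path <- v
    while (!is.na(idx$parent[v])) {
      v <- idx$parent[v]
      path <- c(path, v)
    }
    path
  }
  a1 <- anc(i[1L])
  a2 <- anc(i[2L])
  lca <- a1[a1 %in% a2][1L]
  depth[i[1L]] + depth[i[2L]] - 2 * depth[lca]
}

#' All pairwise patristic distances among a set of tips
#'
#' Prunes the tree to the requested tips (which preserves patristic
#' distances) and returns the cophenetic matrix.  Used for bulk pair queries
#' (ACF sampling, brute-force oracles).
#'
#' @param tree A rooted \code{phylo} object.
#' @param tips Tip labels (default: all tips).
#' @return A symmetric numeric matrix with dimnames = tips.
#' @export
tipDistanceMatrix <- function(tree, tips = tree$tip.label) {
  tree <- .check_tree(tree)
  .match_tips(tips, tree)
  sub <- if (length(tips) < length(tree$tip.label)) {
    ape::keep.tip(tree, tips)
  } else {
    tree
  }
  d <- ape::cophenetic.phylo(sub)
  d[tips, tips, drop = FALSE]
}

#' Nearest-sequenced-taxon distance for every tip
#'
#' For each tip, the minimum patristic distance to any tip of the designated
#' known set, computed in linear time by a two-pass (rootward, then
#' leafward) message-passing sweep.  Known tips map to exactly 0.
#'
#' @param tree A rooted \code{phylo} object.
#' @param known Character vector of known-tip labels (non-empty).
#' @return An \linkS4class{NSTDMap}.
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,C:2);")
#' nstdValues(computeNstd(tr, "A"))  # A=0, B=2, C=4
computeNstd <- function(tree, known) {
  .assert(length(known) >= 1L, "the known tip set must be non-empty")
  idx <- .tree_index(tree)
  ki <- .match_tips(unique(known), idx$tree, "known tip")
  # rootward pass: nearest known tip within each node's own subtree
  down <- rep(Inf, idx$nnode)
  down[ki] <- 0
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch)) down[v] <- min(down[v], down[ch] + idx$blen[ch])
  }
  # leafward pass: nearest known tip outside each node's subtree
  up <- rep(Inf, idx$nnode)
  for (v in idx$preorder) {
    ch <- idx$children[[v]]
    if (length(ch) == 0L) next
    below <- down[ch] + idx$blen[ch]
    if (length(ch) == 1L) {
      best_sib <- Inf
    } else {
      # exclusive min over siblings via prefix/suffix minima
      pre <- cummin(c(Inf, below[-length(below)]))
      suf <- rev(cummin(c(Inf, rev(below)[-length(below)])))
      best_sib <- pmin(pre, suf)
    }
    up[ch] <- idx$blen[ch] + pmin(up[v], best_sib)
  }
  tips <- seq_len(idx$ntip)
  nstd <- pmin(down[tips], up[tips])
  new("NSTDMap", tip = idx$tree$tip.label, nstd = nstd,
      known = idx$tree$tip.label %in% idx$tree$tip.label[ki])
}
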