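# Sankoff maximum-parsimony hidden-state prediction.

#' Transition-cost schemes for Sankoff parsimony
#'
#' Builds the symmetric transition-cost matrix over states 1..S:
#' \code{all_equal} costs 1 for any change; \code{proportional} costs
#' \code{|i-j|}; \code{exponential} costs \code{exp(|i-j|)} for a change.
#' Diagonal costs are 0.
#'
#' @param name One of \code{"all_equal"}, \code{"proportional"},
#'   \code{"exponential"}.
#' @param nstates Number of states S.
#' @return An S x S numeric cost matrix.
#' @export
#' @examples
#' costScheme("proportional", 4)
costScheme <- function(name = c("all_equal", "proportional", "exponential"),
                       nstates) {
  name <- match.arg(name)
  S <- as.integer(nstates)
  .assert(S >= 1L, "nstates must be >= 1")
  d <- abs(outer(seq_len(S), seq_len(S), "-"))
  C <- switch(name,
              all_equal = (d > 0) * 1,
              proportional = d * 1,
              exponential = ifelse(d > 0, exp(d), 0))
  dimnames(C) <- list(seq_len(S), seq_len(S))
  C
}

# Map a (possibly real-valued) known trait vector to integer states 1..S.
.known_states <- function(traits, tree, nstates = NULL) {
  vals <- traitValues(traits)
  vals <- vals[names(vals) %in% tree$tip.label]
  known <- vals[!is.na(vals)]
  .assert(length(known) >= 1L, "at least one known tip is required")
  .assert(all(known == round(known)),
          "discrete-state methods require integer trait values")
  S <- if (is.null(nstates)) as.integer(max(known)) else as.integer(nstates)
  .assert(all(known >= 1 & known <= S),
          sprintf("known states outside 1..%d", S))
  list(known = known, S = S)
}

#' Hidden-state prediction by Sankoff maximum parsimony
#'
#' Dynamic programming over the tree: an up-pass computes each node's
#' per-state subtree cost vector (unknown tips contribute the zero vector),
#' and a down-pass combines it with the cost of the rest of the tree, giving
#' every node's conditional total parsimony cost per state.  For each
#' unknown tip the MPR set is the set of states attaining the minimal
#' conditional total cost; the point prediction is, by default, the
#' arithmetic mean of that set.  Known tips return their own value.
#' Polytomies are handled natively.
#'
#' @param tree A rooted \code{phylo}.
#' @param traits A \linkS4class{TraitTable} with >= 1 known tip; values must
#'   be integers in 1..S.
#' @param scheme Transition-cost scheme name (see \code{\link{costScheme}}).
#' @param nstates State-space upper bound S; defaults to the maximum
#'   observed known state.
#' @param tiePolicy How to turn the MPR set into a point prediction:
#'   \code{"mean"} (default), \code{"min"} or \code{"max"}.
#' @return A \linkS4class{PredictionSet}; \code{details} carries the MPR
#'   set per tip (\code{mpr}) and the conditional total cost matrix over all
#'   nodes (\code{total}, nodes x states, ape node numbering).
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' tt <- traitTable(c("A", "B", "C", "D"), c(1, 1, 1, NA))
#' predictedValues(hspSankoff(tr, tt, "all_equal"))
hspSankoff <- function(tree, traits,
                       scheme = c("all_equal", "proportional", "exponential"),
                       nstates = NULL, tiePolicy = c("mean", "min", "max")) {
  scheme <- match.arg(scheme)
  tiePolicy <- match.arg(tiePolicy)
  idx <- .tree_index(tree)
  ks <- .known_states(traits, idx$tree, nstates)
  S <- ks$S
  C <- costScheme(scheme, S)
  ntip <- idx$ntip
  nnode <- idx$nnode
  known_idx <- .match_tips(names(ks$known), idx$tree)
  known_state <- integer(ntip)
  known_state[known_idx] <- as.integer(ks$known)

  # up-pass: subtree cost vectors and per-node messages to the parent
  Scost <- matrix(0, nnode, S)
  Scost[known_idx, ] <- Inf
  Scost[cbind(known_idx, known_state[known_idx])] <- 0
  msg <- matrix(0, nnode, S)  # msg[v, i]: cost of v's subtree given parent=i
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch)) Scost[v, ] <- colSums(msg[ch, , drop = FALSE])
    p <- idx$parent[v]
    if (!is.na(p)) {
      # msg[v, i] = min_j (C[i, j] + Scost[v, j])
      msg[v, ] <- apply(C + rep(Scost[v, ], each = S), 1L, min)
    }
  }

  # down-pass: cost of the rest of the tree given each node's state
  U <- matrix(0, nnode, S)
  for (v in idx$preorder) {
    ch <- idx$children[[v]]
    if (length(ch) == 0L) next
    for (cc in ch) {
      A <- U[v, ] + Scost[v, ] - msg[cc, ]
      # U[cc, i] = min_j (C[j, i] + A[j]); column-major recycling adds A[j]
      U[cc, ] <- apply(C + A, 2L, min)
    }
  }
  Total <- Scost + U

  pred <- numeric(ntip)
  mpr <- vector("list", ntip)
  names(mpr) <- idx$tree$tip.label
  for (t in seq_len(ntip)) {
    if (known_state[t] > 0L) {
      pred[t] <- traitValues(traits)[[idx$tree$tip.label[t]]]
      mpr[[t]] <- known_state[t]
    } else {
      tot <- Total[t, ]
      m <- min(tot)
      set <- which(tot <= m + 1e-9 * max(1, abs(m)))
      mpr[[t]] <- set
      pred[t] <- switch(tiePolicy,
                        mean = mean(set), min = min(set), max = max(set))
    }
  }
  new("PredictionSet", tip = idx$tree$tip.label, value = pred,
      method = paste0("mpr_", c(all_equal = "ae", proportional = "pr",
                                exponential = "exp")[[scheme]]),
      params = list(scheme = scheme, nstates = S, tiePolicy = tiePolicy),
      details = list(mpr = mpr, total = Total))
}
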