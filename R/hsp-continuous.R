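# Continuous-valued hidden-state prediction: phylogenetic independent
# contrasts, weighted squared-change parsimony, and subtree averaging.

# Walk to the nearest ancestor (including self) with est_ok TRUE.
.nearest_estimated_ancestor <- function(idx, v, est_ok) {
  while (!est_ok[v]) {
    v <- idx$parent[v]
    if (is.na(v)) return(NA_integer_)
  }
  v
}

.prediction_set <- function(idx, pred, method, params, details = list()) {
  new("PredictionSet", tip = idx$tree$tip.label, value = pred,
      method = method, params = params, details = details)
}

#' Hidden-state prediction by phylogenetic independent contrasts
#'
#' An upward Felsenstein-contrasts pass, restricted to subtrees containing
#' known data, assigns each internal node with at least one known descendant
#' a local estimate (the inverse-branch-length-weighted mean of its
#' children's estimates) and an inflated effective branch length.  Each
#' unknown tip is predicted with the estimate of its nearest ancestor that
#' has one; known tips return their own value.  Polytomies are combined
#' directly with the same inverse-length weights — the exact limit of
#' resolving them into zero-length ladders, but independent of child order.
#' Zero branch lengths are floored at \code{\link{branchLengthEpsilon}}.
#'
#' @inheritParams hspSankoff
#' @return A \linkS4class{PredictionSet}; \code{details$nodeValues} holds
#'   the per-node estimates (ape numbering; NA where a node has no known
#'   descendant).
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:3):1,C:1);")
#' tt <- traitTable(c("A", "B", "C"), c(1, 5, NA))
#' predictedValues(hspPic(tr, tt))
hspPic <- function(tree, traits) {
  idx <- .tree_index(tree)
  vals <- traitValues(traits)
  vals <- vals[names(vals) %in% idx$tree$tip.label]
  .assert(sum(!is.na(vals)) >= 1L, "at least one known tip is required")

  est <- numeric(idx$nnode)
  elen <- numeric(idx$nnode)  # effective extra length above the node
  ok <- logical(idx$nnode)
  tipval <- vals[idx$tree$tip.label]
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch) == 0L) {
      if (!is.na(tipval[v])) {
        est[v] <- tipval[v]
        elen[v] <- 0
        ok[v] <- TRUE
      }
      next
    }
    have <- ch[ok[ch]]
    if (length(have) == 0L) next
    w <- 1 / (pmax(idx$blen[have], .EPSILON_BL) + elen[have])
    est[v] <- sum(w * est[have]) / sum(w)
    elen[v] <- 1 / sum(w)
    ok[v] <- TRUE
  }

  pred <- numeric(idx$ntip)
  for (t in seq_len(idx$ntip)) {
    if (!is.na(tipval[t])) {
      pred[t] <- tipval[t]
    } else {
      a <- .nearest_estimated_ancestor(idx, t, ok)
      pred[t] <- est[a]
    }
  }
  nodevals <- ifelse(ok, est, NA_real_)
  .prediction_set(idx, pred, "pic", params = list(),
                  details = list(nodeValues = nodevals))
}

#' Hidden-state prediction by weighted squared-change parsimony
#'
#' Returns the unique minimizer of
#' \eqn{\sum_{edges} (x_{parent} - x_{child})^2 / \ell} over all unlabeled
#' node values with known tip values held fixed — a tree-structured
#' quadratic program solved exactly by a two-pass elimination (upward
#' message accumulation, downward back-substitution).  Unknown tips take
#' their parent's optimum (their own edge term is then zero); known tips
#' return their own value.  Zero branch lengths are floored at
#' \code{\link{branchLengthEpsilon}}; polytomies are handled natively (the
#' quadratic is defined on arbitrary rooted trees).
#'
#' @inheritParams hspSankoff
#' @return A \linkS4class{PredictionSet}; \code{details$nodeValues} holds
#'   the optimal value at every node (ape numbering).
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:3):1,C:1);")
#' tt <- traitTable(c("A", "B", "C"), c(1, 5, NA))
#' predictedValues(hspWscp(tr, tt))
hspWscp <- function(tree, traits) {
  idx <- .tree_index(tree)
  vals <- traitValues(traits)
  vals <- vals[names(vals) %in% idx$tree$tip.label]
  .assert(sum(!is.na(vals)) >= 1L, "at least one known tip is required")
  tipval <- vals[idx$tree$tip.label]
  len <- pmax(idx$blen, .EPSILON_BL)

  # upward: each node sends (w, a): its subtree's contribution behaves as
  # w * (x_parent - a)^2 after eliminating the node's own value
  w_up <- numeric(idx$nnode)
  a_up <- numeric(idx$nnode)
  k_node <- numeric(idx$nnode)
  m_node <- numeric(idx$nnode)
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    is_tip <- length(ch) == 0L
    if (is_tip) {
      if (is.na(tipval[v])) {
        w_up[v] <- 0
      } else {
        w_up[v] <- 1 / len[v]
        a_up[v] <- tipval[v]
      }
      next
    }
    kw <- w_up[ch]
    k <- sum(kw)
    k_node[v] <- k
    if (k > 0) m_node[v] <- sum(kw * a_up[ch]) / k
    if (!is.na(idx$parent[v])) {
      if (k > 0) {
        w_up[v] <- k / (1 + k * len[v])
        a_up[v] <- m_node[v]
      } else {
        w_up[v] <- 0
      }
    }
  }

  # downward back-substitution
  x <- numeric(idx$nnode)
  .assert(k_node[idx$root] > 0, "at least one known tip is required")
  x[idx$root] <- m_node[idx$root]
  for (v in idx$preorder) {
    p <- idx$parent[v]
    if (is.na(p)) next
    if (length(idx$children[[v]]) == 0L) {
      x[v] <- if (is.na(tipval[v])) x[p] else tipval[v]
    } else if (k_node[v] > 0) {
      x[v] <- (x[p] / len[v] + k_node[v] * m_node[v]) /
        (1 / len[v] + k_node[v])
    } else {
      x[v] <- x[p]
    }
  }
  pred <- x[seq_len(idx$ntip)]
  ki <- which(!is.na(tipval))
  pred[ki] <- tipval[ki]
  .prediction_set(idx, pred, "wscp", params = list(),
                  details = list(nodeValues = x))
}

#' Hidden-state prediction by subtree averaging
#'
#' Every node with at least one known descending tip receives the arithmetic
#' mean of the known descendant values; each unknown tip is predicted with
#' the value of its nearest such ancestor.  Known tips return their own
#' value.  Polytomies are handled natively.
#'
#' @inheritParams hspSankoff
#' @return A \linkS4class{PredictionSet}; \code{details$nodeValues} holds
#'   the per-node averages (NA where a node has no known descendant).
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' tt <- traitTable(c("A", "B", "C", "D"), c(2, 4, NA, NA))
#' predictedValues(hspSubtreeAvg(tr, tt))  # C = D = 3
hspSubtreeAvg <- function(tree, traits) {
  idx <- .tree_index(tree)
  vals <- traitValues(traits)
  vals <- vals[names(vals) %in% idx$tree$tip.label]
  .assert(sum(!is.na(vals)) >= 1L, "at least one known tip is required")
  tipval <- vals[idx$tree$tip.label]

  ssum <- numeric(idx$nnode)
  scnt <- numeric(idx$nnode)
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch) == 0L) {
      if (!is.na(tipval[v])) {
        ssum[v] <- tipval[v]
        scnt[v] <- 1
      }
    } else {
      ssum[v] <- sum(ssum[ch])
      scnt[v] <- sum(scnt[ch])
    }
  }
  avg <- ifelse(scnt > 0, ssum / scnt, NA_real_)
  ok <- scnt > 0
  pred <- numeric(idx$ntip)
  for (t in seq_len(idx$ntip)) {
    if (!is.na(tipval[t])) {
      pred[t] <- tipval[t]
    } else {
      a <- .nearest_estimated_ancestor(idx, t, ok)
      pred[t] <- avg[a]
    }
  }
  .prediction_set(idx, pred, "sa", params = list(),
                  details = list(nodeValues = avg))
}

#' Run a hidden-state-prediction method by code
#'
#' Dispatcher over the five algorithms; method codes follow the convention
#' \code{mpr_ae} / \code{mpr_pr} / \code{mpr_exp} (Sankoff parsimony with
#' all-equal, proportional, exponential transition costs), \code{mk_er}
#' (Mk maximum likelihood), \code{pic}, \code{wscp}, \code{sa} (subtree
#' averaging).
#'
#' @inheritParams hspSankoff
#' @param method One of \code{"mpr_ae"}, \code{"mpr_pr"}, \code{"mpr_exp"},
#'   \code{"mk_er"}, \code{"pic"}, \code{"wscp"}, \code{"sa"}.
#' @param ... Passed to the underlying method.
#' @return A \linkS4class{PredictionSet}.
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' tt <- traitTable(c("A", "B", "C", "D"), c(1, 1, 2, NA))
#' predictionMethod(hspPredict(tr, tt, "mpr_exp"))
hspPredict <- function(tree, traits,
                       method = c("mpr_exp", "mpr_pr", "mpr_ae", "mk_er",
                                  "pic", "wscp", "sa"), ...) {
  method <- match.arg(method)
  switch(method,
         mpr_ae = hspSankoff(tree, traits, "all_equal", ...),
         mpr_pr = hspSankoff(tree, traits, "proportional", ...),
         mpr_exp = hspSankoff(tree, traits, "exponential", ...),
         mk_er = hspMkEr(tree, traits, ...)$predictions,
         pic = hspPic(tree, traits),
         wscp = hspWscp(tree, traits),
         sa = hspSubtreeAvg(tree, traits))
}
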