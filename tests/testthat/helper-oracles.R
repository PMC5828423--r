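# Independent oracles and fixture generators used across the suite.
# These deliberately avoid the package's internal traversal code: they work
# from the raw ape edge matrix so that agreement with the package is a real
# cross-check.

# Random rooted tree with optional polytomies and uniform branch lengths.
random_tree <- function(ntips, polytomies = FALSE, min_bl = 0.05,
                        max_bl = 1) {
  tr <- ape::rtree(ntips, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  if (polytomies && ntips >= 4) {
    internal_edges <- which(tr$edge[, 2] > ape::Ntip(tr))
    if (length(internal_edges)) {
      drop <- sample(internal_edges,
                     size = min(length(internal_edges),
                                stats::rbinom(1, length(internal_edges), 0.4)))
      if (length(drop)) {
        tr$edge.length[drop] <- 0
        tr <- ape::di2multi(tr, tol = 1e-12)
        tr$edge.length[tr$edge.length <= 0] <- 0.1
      }
    }
  }
  tr
}

# Basic structure: parent of every node, children lists, branch length per
# child node, root -- straight from the edge matrix.
edge_index <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  blen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  list(ntip = ntip, nnode = nnode, parent = parent, blen = blen, root = root)
}

# Brute-force patristic distance: walk both root paths, subtract the shared
# prefix twice.
brute_patristic <- function(tree, a, b) {
  ei <- edge_index(tree)
  path <- function(v) {
    out <- v
    while (!is.na(ei$parent[v])) {
      v <- ei$parent[v]
      out <- c(out, v)
    }
    out
  }
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  pa <- path(ia)
  pb <- path(ib)
  lca <- pa[pa %in% pb][1]
  dist_up <- function(v, stop_at) {
    s <- 0
    while (v != stop_at) {
      s <- s + ei$blen[v]
      v <- ei$parent[v]
    }
    s
  }
  dist_up(ia, lca) + dist_up(ib, lca)
}

# Exhaustive-enumeration Sankoff: conditional total parsimony cost for every
# node and state.  known: integer vector over tips (NA = unknown).
# Returns an nnode x S matrix (Inf where a known tip's state is fixed
# elsewhere).
sankoff_enum <- function(tree, known, S, C) {
  ei <- edge_index(tree)
  free <- c(which(is.na(known)), (ei$ntip + 1):ei$nnode)
  stopifnot(length(free) <= 9)  # keep enumeration tractable
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(free))))
  states <- matrix(rep(ifelse(is.na(known), 0L, known), each = nrow(grid)),
                   nrow(grid), ei$ntip)
  states <- cbind(states, matrix(0L, nrow(grid), ei$nnode - ei$ntip))
  states[, free] <- grid
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    sp <- states[, tree$edge[e, 1]]
    sc <- states[, tree$edge[e, 2]]
    cost <- cost + C[cbind(sp, sc)]
  }
  out <- matrix(Inf, ei$nnode, S)
  for (v in seq_len(ei$nnode)) {
    for (s in seq_len(S)) {
      sel <- states[, v] == s
      if (any(sel)) out[v, s] <- min(cost[sel])
    }
  }
  out
}

# ER transition probability matrix (closed form, textbook).
er_pmatrix <- function(rate, len, S) {
  E <- exp(-rate * len * S / (S - 1))
  matrix((1 - E) / S, S, S) + diag(E, S)
}

# Exhaustive-enumeration Mk-ER: log-likelihood and marginal posteriors.
# Enumerates joint states of all internal nodes and unknown tips.
mk_enum <- function(tree, known, S, rate) {
  ei <- edge_index(tree)
  prior <- tabulate(known[!is.na(known)], nbins = S)
  prior <- prior / sum(prior)
  free <- c(which(is.na(known)), (ei$ntip + 1):ei$nnode)
  stopifnot(length(free) <= 10)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(free))))
  states <- matrix(rep(ifelse(is.na(known), 0L, known), each = nrow(grid)),
                   nrow(grid), ei$ntip)
  states <- cbind(states, matrix(0L, nrow(grid), ei$nnode - ei$ntip))
  states[, free] <- grid
  w <- prior[states[, ei$root]]
  for (e in seq_len(nrow(tree$edge))) {
    P <- er_pmatrix(rate, tree$edge.length[e], S)
    w <- w * P[cbind(states[, tree$edge[e, 1]], states[, tree$edge[e, 2]])]
  }
  lik <- sum(w)
  post <- matrix(0, ei$nnode, S)
  for (v in seq_len(ei$nnode)) {
    for (s in seq_len(S)) post[v, s] <- sum(w[states[, v] == s]) / lik
  }
  list(logLik = log(lik), posterior = post)
}

# Weighted squared-change objective over all edges, with fixed known tips.
wscp_objective <- function(tree, known, x_free, free_nodes, eps = 1e-8) {
  ei <- edge_index(tree)
  x <- numeric(ei$nnode)
  x[seq_len(ei$ntip)] <- ifelse(is.na(known), 0, known)
  x[free_nodes] <- x_free
  s <- 0
  for (e in seq_len(nrow(tree$edge))) {
    l <- max(tree$edge.length[e], eps)
    s <- s + (x[tree$edge[e, 1]] - x[tree$edge[e, 2]])^2 / l
  }
  s
}

# The 2000-tip benchmark fixture, built once per test run.
benchmark_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateBenchmark(simConfig(seed = 42L))
    cache
  }
})

# Small shared fixture for cheap tests.
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateBenchmark(simConfig(seed = 7L, ntips = 200L,
                                            nsamples = 12L,
                                            readsPerSample = 500L))
    }
    cache
  }
})
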