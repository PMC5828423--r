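# Maximum-likelihood Mk (equal-rates) hidden-state prediction with
# rerooted marginal posteriors (Felsenstein pruning up-pass plus an
# outside-likelihood down-pass, which is algebraically equivalent to
# rerooting at every node).

# ER transition kernel applied to a per-state vector v:
#   (P(l) v)_i = E v_i + (1 - E) mean(v),  E = exp(-rate * l * S/(S-1)).
.er_decay <- function(rate, len, S) exp(-rate * len * S / (S - 1))

# Up-pass partial likelihoods with per-node scaling.
# Returns list(L = nnode x S matrix, msg = per-node message to parent,
#              logscale = accumulated log scaling, loglik).
.mk_uppass <- function(idx, known_idx, known_state, S, rate, prior) {
  nnode <- idx$nnode
  L <- matrix(1, nnode, S)
  L[known_idx, ] <- 0
  L[cbind(known_idx, known_state)] <- 1
  msg <- matrix(1, nnode, S)
  logscale <- 0
  for (v in idx$postorder) {
    ch <- idx$children[[v]]
    if (length(ch)) {
      L[v, ] <- 1
      for (cc in ch) L[v, ] <- L[v, ] * msg[cc, ]
      mx <- max(L[v, ])
      if (mx <= 0) return(list(loglik = -Inf))
      L[v, ] <- L[v, ] / mx
      logscale <- logscale + log(mx)
    }
    p <- idx$parent[v]
    if (!is.na(p)) {
      E <- .er_decay(rate, idx$blen[v], S)
      msg[v, ] <- E * L[v, ] + (1 - E) * mean(L[v, ])
    }
  }
  lik_root <- sum(prior * L[idx$root, ])
  if (lik_root <= 0) return(list(loglik = -Inf))
  list(L = L, msg = msg, logscale = logscale,
       loglik = log(lik_root) + logscale)
}

# Down-pass: outside likelihoods G and marginal posteriors at every node.
.mk_marginals <- function(idx, up, S, rate, prior) {
  nnode <- idx$nnode
  G <- matrix(0, nnode, S)
  G[idx$root, ] <- prior
  for (v in idx$preorder) {
    ch <- idx$children[[v]]
    if (length(ch) == 0L) next
    for (cc in ch) {
      # exclusive product of sibling messages times G at v
      base <- G[v, ] * up$L[v, ] / up$msg[cc, ]
      bad <- !is.finite(base)
      if (any(bad)) {
        # recompute exclusively where a message underflowed to zero
        excl <- G[v, ]
        for (s in setdiff(ch, cc)) excl <- excl * up$msg[s, ]
        base[bad] <- excl[bad]
      }
      E <- .er_decay(rate, idx$blen[cc], S)
      g <- E * base + (1 - E) * mean(base)
      sm <- sum(g)
      G[cc, ] <- if (sm > 0) g / sm else rep(1 / S, S)
    }
  }
  post <- up$L * G
  sw <- rowSums(post)
  sw[sw <= 0] <- 1
  post / sw
}

#' Mk-ER likelihood and marginal posteriors at a fixed rate
#'
#' Evaluates the Felsenstein-pruning log-likelihood of the equal-rates Mk
#' model at a given total leaving rate, with the empirical root prior, and
#' returns the marginal posterior state probabilities at every node
#' (computed by the rerooting-equivalent up/down message passing).  Mainly
#' useful for profiling and validation; \code{\link{hspMkEr}} optimizes the
#' rate and builds predictions.
#'
#' @inheritParams hspSankoff
#' @param rate Total leaving rate (> 0).
#' @return A list with \code{logLik} (numeric) and \code{posterior}
#'   (nodes x states matrix, ape node numbering).
#' @export
mkErLikelihood <- function(tree, traits, nstates = NULL, rate) {
  .assert(rate > 0, "rate must be > 0")
  idx <- .tree_index(tree)
  ks <- .known_states(traits, idx$tree, nstates)
  S <- ks$S
  known_idx <- .match_tips(names(ks$known), idx$tree)
  known_state <- as.integer(ks$known)
  prior <- tabulate(known_state, nbins = S)
  prior <- prior / sum(prior)
  up <- .mk_uppass(idx, known_idx, known_state, S, rate, prior)
  post <- if (is.finite(up$loglik)) {
    .mk_marginals(idx, up, S, rate, prior)
  } else {
    matrix(NA_real_, idx$nnode, S)
  }
  list(logLik = up$loglik, posterior = post)
}

#' Hidden-state prediction by Mk-ER maximum likelihood with rerooting
#'
#' Fits the total leaving rate of the equal-rates Mk model by maximizing the
#' Felsenstein-pruning likelihood with an empirical root prior (state
#' frequencies among known tips), using \code{nlminb} in log-rate space with
#' \code{trials} restarts (the first from a moment heuristic, the rest
#' seeded-random within the bounds).  Marginal posterior state probabilities
#' are then computed at every node and unknown tip; the point prediction is
#' the posterior expectation \eqn{\sum_s s P(s)}.  Known tips return their
#' own value.
#'
#' If all known tips share one state the rate MLE sits at the optimizer's
#' lower bound; the fit is flagged (\code{boundary = TRUE}, with a warning)
#' and every unknown tip is predicted as that state.
#'
#' @inheritParams hspSankoff
#' @param trials Optimizer restarts (default 5).
#' @param seed Seed for the random restarts.
#' @return A list with elements \code{fit} (an \linkS4class{MkFit}) and
#'   \code{predictions} (a \linkS4class{PredictionSet}; \code{details$posterior}
#'   holds the per-node posterior matrix, \code{details$fit} the MkFit).
#' @export
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' tt <- traitTable(c("A", "B", "C", "D"), c(1, 2, 1, NA))
#' res <- hspMkEr(tr, tt, nstates = 2)
#' res$fit
hspMkEr <- function(tree, traits, nstates = NULL, trials = 5L, seed = 1L) {
  idx <- .tree_index(tree)
  ks <- .known_states(traits, idx$tree, nstates)
  S <- ks$S
  known_idx <- .match_tips(names(ks$known), idx$tree)
  known_state <- as.integer(ks$known)
  prior <- tabulate(known_state, nbins = S)
  prior <- prior / sum(prior)

  mean_bl <- mean(idx$blen[-idx$root])
  if (!is.finite(mean_bl) || mean_bl <= 0) mean_bl <- .EPSILON_BL
  lb <- 1e-6 / mean_bl
  ub <- 1e3 / mean_bl

  degenerate <- length(unique(known_state)) < 2L
  if (degenerate) {
    warning("all known tips share one state; Mk rate pinned at lower bound",
            call. = FALSE)
    rate_hat <- lb
    up <- .mk_uppass(idx, known_idx, known_state, S, rate_hat, prior)
    fit <- new("MkFit", rate = rate_hat, logLik = up$loglik,
               rootPrior = prior, trials = 0L, boundary = TRUE)
  } else {
    negll <- function(lr) {
      ll <- .mk_uppass(idx, known_idx, known_state, S, exp(lr), prior)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    # moment heuristic: invert the expected mismatch fraction of known pairs
    starts <- local({
      ki <- known_idx
      m <- min(length(ki), 60L)
      sub <- ki[unique(round(seq(1L, length(ki), length.out = m)))]
      dm <- tipDistanceMatrix(idx$tree, idx$tree$tip.label[sub])
      st <- known_state[sub]
      diffm <- outer(st, st, "!=")
      off <- upper.tri(dm)
      f <- mean(diffm[off])
      dbar <- mean(dm[off])
      Eobs <- max(1e-3, min(0.999, 1 - f / (1 - 1 / S)))
      r0 <- -log(Eobs) * (S - 1) / (S * max(dbar, .EPSILON_BL))
      log(max(lb * 1.01, min(ub * 0.99, r0)))
    })
    starts <- c(starts, .with_seed(.substream(seed, "mk_restarts"),
                                   runif(max(0L, trials - 1L),
                                         log(lb), log(ub))))
    best <- NULL
    for (s0 in starts) {
      o <- tryCatch(nlminb(s0, negll, lower = log(lb), upper = log(ub),
                           control = list(rel.tol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$objective < best$objective))
        best <- o
    }
    rate_hat <- exp(best$par)
    up <- .mk_uppass(idx, known_idx, known_state, S, rate_hat, prior)
    fit <- new("MkFit", rate = rate_hat, logLik = up$loglik,
               rootPrior = prior, trials = as.integer(trials),
               boundary = rate_hat <= lb * 1.001)
  }

  post <- .mk_marginals(idx, up, S, rate_hat, prior)
  vals <- traitValues(traits)
  pred <- as.vector(post[seq_len(idx$ntip), , drop = FALSE] %*% seq_len(S))
  if (degenerate) pred <- rep(known_state[1L], idx$ntip)
  pred[known_idx] <- vals[idx$tree$tip.label[known_idx]]
  ps <- new("PredictionSet", tip = idx$tree$tip.label, value = pred,
            method = "mk_er",
            params = list(nstates = S, trials = as.integer(trials),
                          rate = rate_hat),
            details = list(posterior = post, fit = fit))
  list(fit = fit, predictions = ps)
}
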