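# Synthetic-data generators: trees, trait histories, coverage masks and
# community profiles with the statistical structure the downstream analyses
# assume.  Every output is a pure function of (config, seed).

#' Calibrate the Mk-ER rate from a target trait autocorrelation
#'
#' Under the equal-rates Mk model on S states the correlation between the
#' trait values of two tips at patristic distance d is
#' \eqn{\exp(-\lambda d S/(S-1))}, where \eqn{\lambda} is the total leaving
#' rate.  This solves (by bisection) for the rate at which the correlation
#' equals \code{target} at distance \code{distance}.
#'
#' @param nstates Number of states S (>= 2).
#' @param target Target correlation in (0, 1).
#' @param distance Patristic distance (substitutions/site) at which the
#'   target is attained.
#' @return The calibrated total leaving rate.
#' @export
#' @examples
#' calibrateAcfRate(15, target = 0.5, distance = 0.15)
calibrateAcfRate <- function(nstates, target = 0.5, distance = 0.15) {
  .assert(nstates >= 2, "nstates must be >= 2")
  .assert(target > 0 && target < 1, "target must be in (0, 1)")
  .assert(distance > 0, "distance must be > 0")
  f <- function(r) exp(-r * distance * nstates / (nstates - 1)) - target
  lo <- 0
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Theoretical Mk-ER tip-pair trait correlation
#'
#' @param rate Total leaving rate of the equal-rates Mk process.
#' @param distance Patristic distance(s).
#' @param nstates Number of states S.
#' @return \eqn{\exp(-rate \cdot distance \cdot S/(S-1))}.
#' @export
mkErCorrelation <- function(rate, distance, nstates) {
  exp(-rate * distance * nstates / (nstates - 1))
}

#' Build a simulation configuration
#'
#' Defaults define the "benchmark-small" regime used throughout the package:
#' a pure-birth tree with 2000 tips rescaled to root-to-tip depth 0.5
#' substitutions/site, an equal-rates Mk trait on states 1..15 whose rate is
#' calibrated once so the trait autocorrelation is 0.5 at distance 0.15,
#' clade-drop masking down to 50\% known tips, and 50 log-normal community
#' samples of 2000 reads each.
#'
#' @param seed Master RNG seed.
#' @param ntips Number of tips.
#' @param treeModel "yule" (pure birth) or "bd" (birth-death).
#' @param birth,death Birth/death rates (death < birth; death ignored for
#'   "yule").
#' @param depth Target root-to-tip depth after rescaling, subst/site.
#' @param traitModel "mk_er" or "bounded_walk".
#' @param nstates Number of trait states S.
#' @param rate Trait evolution rate; default calibrated from the ACF target.
#' @param rootPolicy "stationary" (uniform draw) or "fixed".
#' @param rootState Root state used when \code{rootPolicy = "fixed"}.
#' @param maskPolicy "random" or "clade_drop".
#' @param knownFraction Target known-tip fraction in (0, 1].
#' @param nsamples,readsPerSample Community sample count and depth.
#' @param logMu,logSigma Log-normal abundance parameters.
#' @param presentFraction Fraction of tips present per sample.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed = 42L, ntips = 2000L,
                      treeModel = c("yule", "bd"), birth = 1, death = 0,
                      depth = 0.5,
                      traitModel = c("mk_er", "bounded_walk"),
                      nstates = 15L,
                      rate = calibrateAcfRate(nstates, 0.5, 0.15),
                      rootPolicy = c("stationary", "fixed"), rootState = 1L,
                      maskPolicy = c("clade_drop", "random"),
                      knownFraction = 0.5,
                      nsamples = 50L, readsPerSample = 2000L,
                      logMu = 0, logSigma = 2, presentFraction = 0.15) {
  new("SimConfig", seed = as.integer(seed), ntips = as.integer(ntips),
      treeModel = match.arg(treeModel), birth = birth, death = death,
      depth = depth, traitModel = match.arg(traitModel),
      nstates = as.integer(nstates), rate = rate,
      rootPolicy = match.arg(rootPolicy), rootState = as.integer(rootState),
      maskPolicy = match.arg(maskPolicy), knownFraction = knownFraction,
      nsamples = as.integer(nsamples),
      readsPerSample = as.integer(readsPerSample),
      logMu = logMu, logSigma = logSigma,
      presentFraction = presentFraction)
}

#' Simulate a rooted binary tree
#'
#' Pure-birth or birth-death trees conditioned on the number of extant tips
#' (via \code{ape::rphylo}), with branch lengths rescaled so the maximum
#' root-to-tip depth equals \code{config@depth}.  Tips are labeled
#' \code{"t1".."tN"}.  Deterministic given the config seed.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A rooted binary \code{phylo} with \code{config@ntips} tips.
#' @export
simulateTree <- function(config) {
  validObject(config)
  n <- config@ntips
  .with_seed(.substream(config@seed, "tree"), {
    if (n == 1L) {
      tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                           edge.length = config@depth,
                           tip.label = "t1", Nnode = 1L),
                      class = "phylo", order = "cladewise")
    } else {
      d <- if (config@treeModel == "bd") config@death else 0
      tr <- ape::rphylo(n, birth = config@birth, death = d, fossils = FALSE)
      tr$tip.label <- paste0("t", seq_len(n))
      dep <- max(ape::node.depth.edgelength(tr))
      if (dep > 0) tr$edge.length <- tr$edge.length * (config@depth / dep)
      # guard against exactly-zero internal edges from the simulator
      tr$edge.length[tr$edge.length <= 0] <- .EPSILON_BL
    }
    .check_tree(tr)
  })
}

# Draw the root state under the configured policy.
.root_state <- function(nstates, policy, fixed) {
  if (policy == "fixed") {
    .assert(fixed >= 1L && fixed <= nstates, "rootState outside 1..S")
    fixed
  } else {
    sample.int(nstates, 1L)
  }
}

#' Simulate a discrete trait under the equal-rates Mk model
#'
#' Every off-diagonal transition rate is \code{rate/(S-1)} (total leaving
#' rate \code{rate}).  Along a branch of length \eqn{\ell} the end state is
#' drawn from the exact ER transition kernel:
#' \eqn{P(\mathrm{same}) = 1/S + (1-1/S) e^{-rate \cdot \ell S/(S-1)}}.
#'
#' @param tree A rooted \code{phylo}.
#' @param nstates Number of states S (>= 2).
#' @param rate Total leaving rate (>= 0).
#' @param seed RNG seed.
#' @param rootPolicy "stationary" (uniform) or "fixed".
#' @param rootState Root state when fixed.
#' @return A \linkS4class{TraitTable} with every tip known.
#' @export
simulateTraitMk <- function(tree, nstates, rate, seed,
                            rootPolicy = c("stationary", "fixed"),
                            rootState = 1L) {
  .assert(nstates >= 2, "nstates must be >= 2")
  .assert(rate >= 0, "rate must be >= 0")
  rootPolicy <- match.arg(rootPolicy)
  idx <- .tree_index(tree)
  S <- as.integer(nstates)
  .with_seed(seed, {
    state <- integer(idx$nnode)
    state[idx$root] <- .root_state(S, rootPolicy, as.integer(rootState))
    for (v in idx$preorder) {
      p <- idx$parent[v]
      if (is.na(p)) next
      e <- exp(-rate * idx$blen[v] * S / (S - 1))
      p_same <- 1 / S + (1 - 1 / S) * e
      if (runif(1) <= p_same) {
        state[v] <- state[p]
      } else {
        others <- setdiff(seq_len(S), state[p])
        state[v] <- others[sample.int(S - 1L, 1L)]
      }
    }
    traitTable(idx$tree$tip.label, state[seq_len(idx$ntip)])
  })
}

#' Simulate a discrete trait under a reflected ±1 stepwise walk
#'
#' Change events occur at rate \code{rate} along each branch; each event
#' proposes a step of +1 or -1 with equal probability, and proposals leaving
#' the interval [1, S] are rejected (the chain stays put).  This boundary
#' policy makes the uniform distribution on 1..S stationary.
#'
#' @inheritParams simulateTraitMk
#' @return A \linkS4class{TraitTable} with every tip known.
#' @export
simulateTraitWalk <- function(tree, nstates, rate, seed,
                              rootPolicy = c("stationary", "fixed"),
                              rootState = 1L) {
  .assert(nstates >= 2, "nstates must be >= 2")
  .assert(rate >= 0, "rate must be >= 0")
  rootPolicy <- match.arg(rootPolicy)
  idx <- .tree_index(tree)
  S <- as.integer(nstates)
  .with_seed(seed, {
    state <- integer(idx$nnode)
    state[idx$root] <- .root_state(S, rootPolicy, as.integer(rootState))
    for (v in idx$preorder) {
      p <- idx$parent[v]
      if (is.na(p)) next
      s <- state[p]
      nev <- rpois(1L, rate * idx$blen[v])
      if (nev > 0L) {
        steps <- sample(c(-1L, 1L), nev, replace = TRUE)
        for (st in steps) {
          cand <- s + st
          if (cand >= 1L && cand <= S) s <- cand
        }
      }
      state[v] <- s
    }
    traitTable(idx$tree$tip.label, state[seq_len(idx$ntip)])
  })
}

#' Mask a fully known trait table to emulate partial genome coverage
#'
#' \code{policy = "random"}: each tip is independently retained as known
#' with probability \code{fraction}.  \code{policy = "clade_drop"}: entire
#' clades are unlabeled, one random internal node at a time, until the known
#' fraction falls to (or below) the target — producing the long-NSTD regions
#' seen when whole lineages lack sequenced genomes.
#'
#' @param trait A fully (or partially) known \linkS4class{TraitTable}.
#' @param tree The tree the table is bound to.
#' @param policy "random" or "clade_drop".
#' @param fraction Target known fraction in (0, 1].
#' @param seed RNG seed.
#' @return A \linkS4class{TraitTable} with some entries missing; errors if
#'   masking would leave zero known tips.
#' @export
maskKnown <- function(trait, tree, policy = c("random", "clade_drop"),
                      fraction, seed) {
  policy <- match.arg(policy)
  .assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  idx <- .tree_index(tree)
  .match_tips(trait@tip, idx$tree)
  vals <- traitValues(trait)[idx$tree$tip.label]
  ntip <- idx$ntip
  .with_seed(seed, {
    known <- !is.na(vals)
    if (policy == "random") {
      keep <- runif(ntip) < fraction
      known <- known & keep
    } else {
      # tips descending from each internal node
      tipsets <- vector("list", idx$nnode)
      for (v in idx$postorder) {
        ch <- idx$children[[v]]
        if (length(ch) == 0L) {
          tipsets[[v]] <- v
        } else {
          tipsets[[v]] <- unlist(tipsets[ch], use.names = FALSE)
        }
      }
      internals <- setdiff(seq_len(idx$nnode), seq_len(ntip))
      # never drop the root's full tip set, and cap clade size so a single
      # draw cannot overshoot the target badly
      internals <- internals[internals != idx$root]
      sizes <- lengths(tipsets[internals])
      internals <- internals[sizes <= max(2L, ceiling(0.25 * ntip))]
      target_n <- fraction * ntip
      guard <- 0L
      while (sum(known) > target_n && guard < 10L * idx$nnode &&
             length(internals)) {
        guard <- guard + 1L
        v <- internals[sample.int(length(internals), 1L)]
        ts <- tipsets[[v]]
        # keep at least one known tip overall
        if (sum(known) - sum(known[ts]) >= 1L) known[ts] <- FALSE
      }
    }
    .assert(sum(known) >= 1L,
            "masking would leave zero known tips; relax the policy")
    vals[!known] <- NA
    traitTable(idx$tree$tip.label, unname(vals))
  })
}

#' Simulate log-normal community profiles over the tree's tips
#'
#' Per sample: each tip is independently present with probability
#' \code{presentFraction}; present tips receive log-normal weights
#' \eqn{\mathrm{LN}(\mu, \sigma)}; read counts are a multinomial draw of
#' \code{readsPerSample} reads over the present tips.  Deterministic given
#' the config seed.
#'
#' @param tree A rooted \code{phylo}.
#' @param config A \linkS4class{SimConfig} (fields \code{nsamples},
#'   \code{readsPerSample}, \code{logMu}, \code{logSigma},
#'   \code{presentFraction}, \code{seed}).
#' @param group Optional per-sample group labels; default alternates
#'   "animal" / "non-animal".
#' @return An \linkS4class{AbundanceTable} (tips x samples).
#' @export
simulateAbundances <- function(tree, config, group = NULL) {
  validObject(config)
  tree <- .check_tree(tree)
  ntip <- length(tree$tip.label)
  ns <- config@nsamples
  .with_seed(.substream(config@seed, "abundances"), {
    m <- matrix(0L, nrow = ntip, ncol = ns,
                dimnames = list(tree$tip.label,
                                sprintf("s%03d", seq_len(ns))))
    for (j in seq_len(ns)) {
      present <- which(runif(ntip) < config@presentFraction)
      if (length(present) == 0L) present <- sample.int(ntip, 1L)
      w <- rlnorm(length(present), meanlog = config@logMu,
                  sdlog = config@logSigma)
      m[present, j] <- as.integer(
        rmultinom(1L, size = config@readsPerSample, prob = w))
    }
    if (is.null(group)) {
      group <- rep(c("animal", "non-animal"), length.out = ns)
    }
    abundanceTable(m, group = group)
  })
}

#' Run every generator of a configuration
#'
#' Convenience driver producing the tree, the full trait history, the masked
#' trait table and the abundance table of a \linkS4class{SimConfig} in one
#' call.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A list with elements \code{tree}, \code{traits} (all known),
#'   \code{masked} (partially known) and \code{abundances}.
#' @export
simulateBenchmark <- function(config) {
  validObject(config)
  tree <- simulateTree(config)
  sim_trait <- if (config@traitModel == "mk_er") simulateTraitMk
               else simulateTraitWalk
  traits <- sim_trait(tree, config@nstates, config@rate,
                      seed = .substream(config@seed, "trait"),
                      rootPolicy = config@rootPolicy,
                      rootState = config@rootState)
  masked <- maskKnown(traits, tree, policy = config@maskPolicy,
                      fraction = config@knownFraction,
                      seed = .substream(config@seed, "mask"))
  abund <- simulateAbundances(tree, config)
  list(tree = tree, traits = traits, masked = masked, abundances = abund)
}
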