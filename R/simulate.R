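## ---- population simulation under the chain -------------------------------

#' One iteration of the phenotype prevalence dynamics
#'
#' Advances the prevalence vector by one step: mass moves along the recorded
#' source -> destination transitions, i.e.
#' \code{s_k(t+1) = sum_j p_jk s_j(t)} with \code{p_jk} the probability of
#' the j -> k transition. With the row-stochastic convention used here this
#' is \code{t(P) \%*\% s}; the result is renormalized (within 1e-12) to guard
#' against floating-point drift.
#'
#' @param dtmc A [PhenotypeDTMC-class].
#' @param s Prevalence vector over the chain's states (sums to 1).
#' @return The next prevalence vector.
#' @export
dtmcStep <- function(dtmc, s) {
  k <- nrow(dtmc@P)
  if (length(s) != k) stop("prevalence vector does not match the chain")
  out <- as.numeric(crossprod(dtmc@P, s))
  out / sum(out)
}

#' Evolve a population to steady state
#'
#' Iterates [dtmcStep()] until the largest per-state change falls below
#' \code{tol} or \code{maxSteps} is reached, keeping the full trajectory.
#'
#' @inheritParams dtmcStep
#' @param s0 Initial prevalence vector (nonnegative, sums to 1 within 1e-6;
#'   it is renormalized exactly).
#' @param maxSteps Iteration cap (default 1000).
#' @param tol Convergence tolerance on the max-norm change (default 1e-9).
#' @return A [PopulationTrajectory-class]; row t+1 of the prevalence matrix
#'   is the population after t iterations.
#' @export
simulatePopulation <- function(dtmc, s0, maxSteps = 1000, tol = 1e-9) {
  k <- nrow(dtmc@P)
  if (length(s0) != k) stop("initial prevalence does not match the chain")
  if (any(s0 < 0) || abs(sum(s0) - 1) > 1e-6)
    stop("initial prevalences must be nonnegative and sum to 1")
  s <- s0 / sum(s0)
  rows <- list(s)
  converged <- FALSE
  for (t in seq_len(maxSteps)) {
    s2 <- dtmcStep(dtmc, s)
    rows[[t + 1]] <- s2
    if (max(abs(s2 - s)) < tol) { converged <- TRUE; s <- s2; break }
    s <- s2
  }
  new("PopulationTrajectory",
      prevalence = do.call(rbind, rows), converged = converged,
      patterns = dtmc@states@patterns,
      signatureGenes = dtmc@states@signatureGenes)
}

setMethod("show", "PopulationTrajectory", function(object) {
  cat(sprintf("PopulationTrajectory: %d iteration(s) over %d state(s)%s\n",
              nrow(object@prevalence) - 1, ncol(object@prevalence),
              if (object@converged) " (converged)" else ""))
})

## 0/1 membership matrix: genes x states
.patternMembership <- function(patterns, genes) {
  m <- vapply(patterns, function(p) as.integer(strsplit(p, "")[[1]]),
              integer(length(genes)))
  m <- matrix(m, nrow = length(genes), dimnames = list(genes, NULL))
  m
}

#' Per-gene prevalence implied by a state distribution
#'
#' The fraction of the population expressing each signature gene: the summed
#' prevalence of the states whose pattern has that gene on.
#'
#' @param patterns Signature patterns (bit-strings) of the states.
#' @param genes Signature gene order.
#' @param s Prevalence vector over the states.
#' @return Named numeric vector over \code{genes}.
#' @export
geneMarginals <- function(patterns, genes, s) {
  m <- .patternMembership(patterns, genes)
  setNames(as.numeric(m %*% s), genes)
}

## ---- virtual population construction -------------------------------------

#' Marker prevalence targets from an expression summary
#'
#' Converts mean normalized read counts (baseMean) into per-marker prevalence
#' targets: the most expressed signature gene is assigned a random prevalence
#' p* drawn uniformly in [0.5, 1], and every other gene the fraction of p*
#' given by its baseMean ratio to the top gene (clipped to [0, 1]).
#'
#' @param expr data.frame with columns \code{gene_id} and \code{baseMean}
#'   (nonnegative), covering every signature gene.
#' @param sig A [Signature-class] or character vector of gene ids.
#' @return Named numeric vector of prevalence targets over the signature.
#' @export
markerPrevalenceTargets <- function(expr, sig) {
  genes <- if (is(sig, "Signature")) signatureGenes(sig) else sig
  bm <- expr$baseMean[match(genes, expr$gene_id)]
  if (anyNA(bm)) stop("expression table must cover every signature gene")
  if (any(bm < 0)) stop("baseMean values must be nonnegative")
  if (max(bm) <= 0) stop("at least one signature gene must have baseMean > 0")
  pstar <- runif(1, 0.5, 1)
  setNames(pmin(1, pmax(0, pstar * bm / max(bm))), genes)
}

#' Sample a virtual population matching marker prevalence targets
#'
#' Builds a prevalence vector supported on the eligible phenotype states
#' whose per-gene marginals reproduce the targets within \code{tol}. The
#' support is initialized with a random Dirichlet draw and refined by
#' multiplicative marginal fitting (IPF-style): for each gene in turn the
#' states expressing it are rescaled toward the target and the remaining
#' states toward its complement, then the vector is renormalized. Draws that
#' fail to fit within \code{maxTries} restarts raise an explicit error.
#'
#' @param dtmc A [PhenotypeDTMC-class] (or [PhenotypeStateSet-class]).
#' @param targets Named prevalence targets over signature genes (subset of
#'   the signature allowed; only named genes are constrained).
#' @param requireActive Gene ids that must be ON in every supported state
#'   (e.g. the inducer TGFB1), defining the eligible state set.
#' @param tol Absolute marginal tolerance (default 0.05).
#' @param maxTries Random restarts before giving up (default 50).
#' @param fitIter Gene-cycling passes per restart (default 200).
#' @return Prevalence vector over all chain states (zero off-support), with
#'   attribute \code{"marginals"} holding the achieved per-gene marginals.
#' @export
sampleVirtualPopulation <- function(dtmc, targets, requireActive = character(),
                                    tol = 0.05, maxTries = 50, fitIter = 200) {
  states <- if (is(dtmc, "PhenotypeDTMC")) dtmc@states else dtmc
  genes <- states@signatureGenes
  if (!all(names(targets) %in% genes))
    stop("targets name genes outside the signature")
  m <- .patternMembership(states@patterns, genes)
  eligible <- rep(TRUE, numPhenotypes(states))
  for (g in requireActive) {
    if (!g %in% genes) stop("requireActive gene not in the signature: ", g)
    eligible <- eligible & m[g, ] == 1
  }
  if (!any(eligible)) stop("no eligible state satisfies the constraint")
  sub <- m[names(targets), eligible, drop = FALSE]
  ke <- sum(eligible)
  for (try in seq_len(maxTries)) {
    w <- rgamma(ke, shape = 1)
    w <- w / sum(w)
    for (it in seq_len(fitIter)) {
      for (gi in seq_along(targets)) {
        on <- sub[gi, ] == 1
        mg <- sum(w[on])
        tg <- targets[gi]
        if (mg > 0 && mg < 1) {
          w[on] <- w[on] * (tg / mg)
          w[!on] <- w[!on] * ((1 - tg) / (1 - mg))
        } else if (mg == 0 && tg > 0) {
          next  # gene absent from support; cannot raise it multiplicatively
        }
        w <- pmax(w, 0)
        w <- w / sum(w)
      }
      ach <- as.numeric(sub %*% w)
      if (max(abs(ach - targets)) <= tol) break
    }
    ach <- as.numeric(sub %*% w)
    if (max(abs(ach - targets)) <= tol) {
      s <- numeric(numPhenotypes(states))
      s[eligible] <- w
      attr(s, "marginals") <- setNames(ach, names(targets))
      return(s)
    }
  }
  stop("could not fit marginal targets within tolerance ", tol,
       " after ", maxTries, " restarts (targets may be infeasible ",
       "for the eligible states)")
}
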