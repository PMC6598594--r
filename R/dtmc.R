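## ---- phenotype states ----------------------------------------------------

.projectPattern <- function(fullKey, nodeIds, sigGenes) {
  pos <- match(sigGenes, nodeIds)
  if (anyNA(pos)) stop("signature gene(s) absent from the network state: ",
                       paste(sigGenes[is.na(pos)], collapse = ", "))
  paste(strsplit(fullKey, "")[[1]][pos], collapse = "")
}

#' Merge attractors into signature-defined phenotype states
#'
#' Projects every attractor of the network onto the signature genes and
#' groups attractors sharing the same signature bit pattern into one
#' phenotype. This is the state-space reduction that makes the Markov chain
#' tractable: configurations that differ only outside the signature are the
#' same phenotype. Basin weights add up within a group; state ids are
#' assigned in order of decreasing basin weight.
#'
#' @param attrs An [AttractorSet-class] (nonempty).
#' @param sig A [Signature-class] or character vector of signature gene ids,
#'   all present in the network.
#' @return A [PhenotypeStateSet-class].
#' @export
mergeAttractors <- function(attrs, sig) {
  genes <- if (is(sig, "Signature")) signatureGenes(sig) else sig
  if (length(attrs@states) == 0) stop("no attractors to merge")
  pats <- vapply(attrs@states, .projectPattern, "", nodeIds = attrs@nodeIds,
                 sigGenes = genes)
  grp <- split(seq_along(pats), pats)
  weights <- vapply(grp, function(i) sum(attrs@counts[i]), 0)
  ord <- order(-weights, names(grp))
  new("PhenotypeStateSet",
      signatureGenes = genes, nodeIds = attrs@nodeIds,
      patterns = names(grp)[ord], basinWeights = unname(weights[ord]),
      representatives = lapply(grp[ord], function(i) unname(attrs@states[i])))
}

#' @describeIn mergeAttractors Signature patterns of the phenotype states, in
#'   state-id order.
#' @param states A [PhenotypeStateSet-class].
#' @export
phenotypePatterns <- function(states) states@patterns

#' @describeIn mergeAttractors Number of phenotype states.
#' @export
numPhenotypes <- function(states) length(states@patterns)

setMethod("show", "PhenotypeStateSet", function(object) {
  cat(sprintf("PhenotypeStateSet: %d phenotype(s) over signature [%s]\n",
              length(object@patterns),
              paste(object@signatureGenes, collapse = ", ")))
  for (i in head(seq_along(object@patterns), 8))
    cat(sprintf("  #%d %s  (basin %g, %d full state(s))\n", i,
                object@patterns[i], object@basinWeights[i],
                length(object@representatives[[i]])))
  if (length(object@patterns) > 8) cat("  ...\n")
})

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Snap an end state to the nearest known phenotype
#'
#' A perturbation run occasionally lands on a stable configuration whose
#' signature pattern was never seen during the attractor campaign. Such end
#' states are reassigned to the known phenotype whose pattern is closest in
#' Hamming distance (ties broken toward the larger basin weight, then the
#' smaller state id), and the number of differing signature genes is
#' reported.
#'
#' @param end A complete network state (named 0/1 vector), a full-state
#'   bit-string, or a signature-pattern bit-string.
#' @param states A nonempty [PhenotypeStateSet-class].
#' @return list with \code{stateId} and \code{nChanged} (the Hamming distance
#'   on the signature, 0 when the pattern was already known).
#' @export
snapToKnown <- function(end, states) {
  if (numPhenotypes(states) == 0) stop("no known phenotype states")
  if (!is.character(end) || length(end) > 1)
    end <- stateKey(end[states@nodeIds])
  pat <- if (nchar(end) == length(states@signatureGenes)) end
         else .projectPattern(end, states@nodeIds, states@signatureGenes)
  d <- vapply(states@patterns, .hamming, 0, a = pat)
  ord <- order(d, -states@basinWeights, seq_along(d))
  list(stateId = ord[1], nChanged = unname(d[ord[1]]))
}

## ---- transition campaign -------------------------------------------------

#' Perturbation campaign estimating phenotype transitions
#'
#' For each source phenotype, repeatedly perturbs one of its representative
#' full configurations (each gene flipped with the current probability,
#' starting at \code{flipStart}) and relaxes the network back to an
#' attractor. If the run returns to the source phenotype, the flip
#' probability is escalated by \code{flipStep} and the run retried; a run
#' whose probability would exceed 1 without leaving the source is recorded as
#' a failure. End states outside the known phenotype set are snapped to the
#' nearest known pattern ([snapToKnown()]).
#'
#' @param net The [BooleanNetwork-class] the phenotypes belong to.
#' @param states A [PhenotypeStateSet-class].
#' @param nSims Total runs, distributed evenly over source phenotypes
#'   (remainder to the lowest state ids).
#' @param flipStart,flipStep Initial flip probability and escalation step.
#' @param maxIter Sweep cap per relaxation.
#' @param tieMode Majority tie handling, as in [updateNode()].
#' @return data.frame of records: \code{source}, \code{dest} (NA on
#'   failure), \code{iterations}, \code{escalations}, \code{snapped},
#'   \code{snapDistance}, \code{failed}.
#' @export
transitionCampaign <- function(net, states, nSims, flipStart = 0.05,
                               flipStep = 0.05, maxIter = 1e5,
                               tieMode = c("hold", "zero")) {
  tieMode <- match.arg(tieMode)
  stopifnot(numPhenotypes(states) >= 1, nSims >= 1)
  cn <- .compileNetwork(net)
  if (!identical(cn$ids, states@nodeIds))
    stop("network node order does not match the phenotype state set")
  tieHold <- tieMode == "hold"
  k <- numPhenotypes(states)
  per <- rep(nSims %/% k, k)
  if (nSims %% k > 0) per[seq_len(nSims %% k)] <- per[seq_len(nSims %% k)] + 1L
  recs <- vector("list", nSims)
  r <- 0L
  for (i in seq_len(k)) {
    reps <- states@representatives[[i]]
    for (s in seq_len(per[i])) {
      start <- stateFromKey(reps[[sample.int(length(reps), 1)]], cn$ids)
      p <- flipStart
      escal <- 0L
      rec <- NULL
      repeat {
        if (p > 1 + 1e-9) {
          rec <- data.frame(source = i, dest = NA_integer_, iterations = NA_real_,
                            escalations = escal, snapped = FALSE,
                            snapDistance = NA_integer_, failed = TRUE)
          break
        }
        pert <- start
        flip <- runif(cn$n) < min(p, 1)
        pert[flip] <- 1L - pert[flip]
        res <- .runCompiled(cn, pert, maxIter, tieHold)
        if (!res$converged) {
          rec <- data.frame(source = i, dest = NA_integer_, iterations = NA_real_,
                            escalations = escal, snapped = FALSE,
                            snapDistance = NA_integer_, failed = TRUE)
          break
        }
        snap <- snapToKnown(paste(res$end, collapse = ""), states)
        if (snap$stateId == i) {
          p <- p + flipStep
          escal <- escal + 1L
          next
        }
        rec <- data.frame(source = i, dest = snap$stateId,
                          iterations = res$iterations, escalations = escal,
                          snapped = snap$nChanged > 0,
                          snapDistance = snap$nChanged, failed = FALSE)
        break
      }
      r <- r + 1L
      recs[[r]] <- rec
    }
  }
  do.call(rbind, recs)
}

## ---- transition matrix ---------------------------------------------------

#' Build the phenotype transition matrix from campaign records
#'
#' For each recorded transition i -> j the raw weight is
#' \code{(N_ij / N_i) / (d_ij * I_ij)}: the relative transition frequency
#' divided by the signature-Hamming distance between the two phenotypes and
#' by the mean length (in sweeps) of the recorded i -> j runs. The distance
#' factor favors transitions between similar phenotypes without capping how
#' many genes may change; the length factor favors fast transitions, which
#' are the biologically likelier ones. Rows are then renormalized to sum to
#' 1 so that the population simulation conserves mass; sources with no
#' successful exit become explicit absorbing states.
#'
#' @param records Campaign records from [transitionCampaign()].
#' @param states The [PhenotypeStateSet-class] the records refer to.
#' @return A [PhenotypeDTMC-class].
#' @export
buildTransitionMatrix <- function(records, states) {
  k <- numPhenotypes(states)
  ok <- records[!records$failed, , drop = FALSE]
  N <- matrix(0, k, k)
  I <- matrix(NA_real_, k, k)
  if (nrow(ok)) {
    tab <- table(factor(ok$source, levels = seq_len(k)),
                 factor(ok$dest, levels = seq_len(k)))
    N[] <- as.numeric(tab)
    means <- tapply(ok$iterations, list(factor(ok$source, levels = seq_len(k)),
                                        factor(ok$dest, levels = seq_len(k))),
                    mean)
    I[] <- as.numeric(means)
  }
  D <- outer(states@patterns, states@patterns,
             Vectorize(function(a, b) .hamming(a, b)))
  totals <- rowSums(N)
  P <- matrix(0, k, k)
  absorbing <- totals == 0
  for (i in seq_len(k)) {
    if (absorbing[i]) { P[i, i] <- 1; next }
    for (j in seq_len(k)) {
      if (N[i, j] > 0) {
        if (D[i, j] == 0)
          stop("internal error: recorded transition with zero pattern distance")
        P[i, j] <- (N[i, j] / totals[i]) / (D[i, j] * I[i, j])
      }
    }
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  snapFrac <- if (nrow(ok)) mean(ok$snapped) else NA_real_
  new("PhenotypeDTMC", states = states, P = P, counts = N, totals = totals,
      dist = D, meanLength = I, absorbing = absorbing,
      snapFraction = snapFrac)
}

#' @describeIn buildTransitionMatrix The row-stochastic transition matrix.
#' @param dtmc A [PhenotypeDTMC-class].
#' @export
transitionMatrix <- function(dtmc) dtmc@P

#' @describeIn buildTransitionMatrix The underlying phenotype state set.
#' @export
dtmcStates <- function(dtmc) dtmc@states

setMethod("show", "PhenotypeDTMC", function(object) {
  k <- length(object@states@patterns)
  cat(sprintf("PhenotypeDTMC: %d state(s), %d absorbing; snap fraction %s\n",
              k, sum(object@absorbing),
              if (is.na(object@snapFraction)) "NA"
              else sprintf("%.1f%%", 100 * object@snapFraction)))
  cat("  signature:", paste(object@states@signatureGenes, collapse = ", "), "\n")
})
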