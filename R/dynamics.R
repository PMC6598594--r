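## ---- network states ------------------------------------------------------

#' Construct a complete network state
#'
#' A state assigns 0/1 to every node of the network; it is represented as a
#' named integer vector in canonical node order.
#'
#' @param net A [BooleanNetwork-class].
#' @param values Either a single 0/1 used for all nodes, or a named vector
#'   covering every node id.
#' @return Named integer vector over \code{nodeIds(net)}.
#' @export
networkState <- function(net, values = 0L) {
  ids <- nodeIds(net)
  if (length(values) == 1 && is.null(names(values)))
    return(setNames(rep(as.integer(values), length(ids)), ids))
  if (!all(ids %in% names(values)))
    stop("state must cover every network node")
  v <- as.integer(values[ids])
  if (any(is.na(v) | !v %in% c(0L, 1L))) stop("state values must be 0 or 1")
  setNames(v, ids)
}

#' @describeIn networkState Encode a state as a 0/1 bit-string (canonical
#'   node order).
#' @param state Named 0/1 vector.
#' @export
stateKey <- function(state) paste(state, collapse = "")

#' @describeIn networkState Decode a bit-string back into a named state.
#' @param key Bit-string produced by \code{stateKey}.
#' @param ids Node id order.
#' @export
stateFromKey <- function(key, ids) {
  v <- as.integer(strsplit(key, "")[[1]])
  stopifnot(length(v) == length(ids))
  setNames(v, ids)
}

## ---- compiled form used by the simulation kernel -------------------------

## per-node input index lists; avoids data.frame lookups inside sweeps
.compileNetwork <- function(net) {
  ids <- nodeIds(net)
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  from <- idx[net@edges$from]
  to <- idx[net@edges$to]
  sgn <- net@edges$sign
  inputs <- vector("list", n)
  signs <- vector("list", n)
  for (i in idx) {
    sel <- which(to == i)
    inputs[[i]] <- as.integer(from[sel])
    signs[[i]] <- as.numeric(sgn[sel])
  }
  list(ids = ids, n = n, isAND = net@nodes$rule == "AND",
       inputs = inputs, signs = signs)
}

.updateCompiled <- function(cn, v, i, tieHold) {
  ins <- cn$inputs[[i]]
  if (length(ins) == 0L) return(v[i])           # input-free nodes hold
  if (cn$isAND[i]) return(as.integer(all(v[ins] == 1L)))
  delta <- sum(cn$signs[[i]][v[ins] == 1L])     # active inputs only
  if (delta > 0) 1L else if (delta < 0) 0L else if (tieHold) v[i] else 0L
}

## ---- exported dynamics operations ----------------------------------------

#' Update a single node
#'
#' Applies the node's Boolean rule to the current state. AND nodes switch on
#' only when every input is active. MAJ nodes compare active activating
#' inputs against active inhibiting inputs (inactive inputs exert no
#' influence): a strict majority of activators turns the node on, a strict
#' majority of inhibitors turns it off, and a tie -- including the case of no
#' active input -- holds the current value (or forces 0 under
#' \code{tieMode = "zero"}). Input-free nodes always hold, which is what lets
#' a clamped inducer such as TGFB1 stay on for a whole simulation.
#'
#' @param net A [BooleanNetwork-class].
#' @param state Complete named 0/1 state.
#' @param node Node id to update.
#' @param tieMode \code{"hold"} (default) or \code{"zero"}.
#' @return The node's new value (0 or 1).
#' @export
updateNode <- function(net, state, node, tieMode = c("hold", "zero")) {
  tieMode <- match.arg(tieMode)
  if (!node %in% nodeIds(net)) stop("unknown node: ", node)
  cn <- .compileNetwork(net)
  v <- networkState(net, state)
  unname(.updateCompiled(cn, v, match(node, cn$ids), tieMode == "hold"))
}

#' One constrained-asynchronous sweep
#'
#' Updates every node exactly once, sequentially, in a fresh uniformly random
#' permutation, each update seeing the latest values. This is asynchronous
#' update constrained so that all nodes are revised within the same
#' iteration; randomizing the order at every sweep emulates processes with
#' different rates without changing the network's single-state attractors.
#'
#' @inheritParams updateNode
#' @param order Optional explicit update order (integer positions or node
#'   ids); by default a fresh random permutation is drawn from the R RNG.
#' @return The state after the sweep.
#' @export
sweepUpdate <- function(net, state, order = NULL, tieMode = c("hold", "zero")) {
  tieMode <- match.arg(tieMode)
  cn <- .compileNetwork(net)
  v <- networkState(net, state)
  if (is.null(order)) order <- sample.int(cn$n)
  else if (is.character(order)) order <- match(order, cn$ids)
  stopifnot(length(order) == cn$n)
  hold <- tieMode == "hold"
  for (i in order) v[i] <- .updateCompiled(cn, v, i, hold)
  v
}

.runCompiled <- function(cn, v, maxIter, tieHold) {
  iter <- 0L
  converged <- FALSE
  n <- cn$n
  inputs <- cn$inputs
  signs <- cn$signs
  isAND <- cn$isAND
  while (iter < maxIter) {
    iter <- iter + 1L
    old <- v
    for (i in sample.int(n)) {
      ins <- inputs[[i]]
      if (length(ins) == 0L) next
      if (isAND[i]) {
        v[i] <- if (all(v[ins] == 1L)) 1L else 0L
      } else {
        delta <- sum(signs[[i]][v[ins] == 1L])
        if (delta > 0) v[i] <- 1L
        else if (delta < 0) v[i] <- 0L
        else if (!tieHold) v[i] <- 0L
      }
    }
    if (identical(v, old)) { converged <- TRUE; break }
  }
  list(end = v, converged = converged, iterations = iter)
}

#' Run sweeps until a single-state attractor (or the iteration cap)
#'
#' Iterates [sweepUpdate()] until one full sweep leaves the state unchanged
#' -- at which point the state is a fixed point of every individual node
#' update, independent of order -- or until \code{maxIter} sweeps have been
#' performed without convergence.
#'
#' @inheritParams updateNode
#' @param init Complete initial state.
#' @param maxIter Maximum number of sweeps (default 1e5).
#' @return list with \code{end} (final state), \code{converged} (logical) and
#'   \code{iterations} (sweeps performed, including the confirming one).
#' @export
runToAttractor <- function(net, init, maxIter = 1e5, tieMode = c("hold", "zero")) {
  tieMode <- match.arg(tieMode)
  stopifnot(maxIter >= 1)
  cn <- .compileNetwork(net)
  res <- .runCompiled(cn, networkState(net, init), maxIter, tieMode == "hold")
  names(res$end) <- cn$ids
  res
}

#' Random initial state with a given activation probability
#'
#' Each node is set to 1 independently with probability \code{pActive} --
#' the initial-condition scheme used to explore the attractor landscape over
#' an activation grid from 0 to 100%.
#'
#' @inheritParams updateNode
#' @param pActive Activation probability in [0, 1].
#' @return A complete named 0/1 state.
#' @export
randomInitialState <- function(net, pActive = 0.5) {
  stopifnot(pActive >= 0, pActive <= 1)
  ids <- nodeIds(net)
  setNames(as.integer(runif(length(ids)) < pActive), ids)
}

#' Flip each node value with a given probability
#'
#' The perturbation used when probing transitions between attractors: every
#' gene's value is flipped independently with probability \code{flipProb}.
#'
#' @param state Complete named 0/1 state.
#' @param flipProb Flip probability in [0, 1].
#' @return The perturbed state.
#' @export
perturbState <- function(state, flipProb = 0.05) {
  stopifnot(flipProb >= 0, flipProb <= 1)
  flip <- runif(length(state)) < flipProb
  state[flip] <- 1L - state[flip]
  state
}

#' Attractor search campaign over an activation-probability grid
#'
#' Runs \code{nSims} independent simulations from random initial states, the
#' simulations split evenly across the activation-probability grid (any
#' remainder is assigned to the grid point closest to 0.5). Converged end
#' states are deduplicated with occurrence counts, an estimate of relative
#' basin size.
#'
#' @inheritParams updateNode
#' @param nSims Total number of simulations (>= 1).
#' @param pGrid Activation probabilities (default 0 to 1 in 5% steps).
#' @param maxIter Sweep cap per simulation.
#' @return An [AttractorSet-class], states sorted by decreasing count.
#' @export
attractorCampaign <- function(net, nSims, pGrid = seq(0, 1, by = 0.05),
                              maxIter = 1e5, tieMode = c("hold", "zero")) {
  tieMode <- match.arg(tieMode)
  stopifnot(nSims >= 1)
  cn <- .compileNetwork(net)
  tieHold <- tieMode == "hold"
  per <- rep(nSims %/% length(pGrid), length(pGrid))
  per[which.min(abs(pGrid - 0.5))] <- per[which.min(abs(pGrid - 0.5))] +
    nSims %% length(pGrid)
  tallies <- new.env(parent = emptyenv())
  nConv <- 0L
  for (gi in seq_along(pGrid)) {
    p <- pGrid[gi]
    for (s in seq_len(per[gi])) {
      v <- setNames(as.integer(runif(cn$n) < p), cn$ids)
      res <- .runCompiled(cn, v, maxIter, tieHold)
      if (res$converged) {
        nConv <- nConv + 1L
        key <- paste(res$end, collapse = "")
        prev <- if (is.null(tallies[[key]])) 0L else tallies[[key]]
        tallies[[key]] <- prev + 1L
      }
    }
  }
  keys <- ls(tallies)
  counts <- vapply(keys, function(k) tallies[[k]], 0L)
  ord <- order(-counts, keys)
  new("AttractorSet", nodeIds = cn$ids, states = keys[ord],
      counts = as.integer(counts[ord]), nConverged = nConv,
      nTotal = as.integer(nSims))
}

setMethod("show", "AttractorSet", function(object) {
  cat(sprintf("AttractorSet: %d attractor(s) over %d nodes; %d/%d runs converged\n",
              length(object@states), length(object@nodeIds),
              object@nConverged, object@nTotal))
  for (i in head(seq_along(object@states), 6))
    cat(sprintf("  %s  (basin count %d)\n", object@states[i], object@counts[i]))
  if (length(object@states) > 6) cat("  ...\n")
})

#' Exhaustively enumerate the fixed points of a small network
#'
#' Checks all 2^n states node-by-node; a state is a fixed point when every
#' node's update reproduces its current value (an order-independent
#' property). Intended for networks of at most ~20 nodes.
#'
#' @inheritParams updateNode
#' @return Character vector of fixed-point bit-strings in canonical node
#'   order.
#' @export
enumerateFixedPoints <- function(net, tieMode = c("hold", "zero")) {
  tieMode <- match.arg(tieMode)
  cn <- .compileNetwork(net)
  n <- cn$n
  stopifnot(n <= 20)
  tieHold <- tieMode == "hold"
  out <- character()
  for (code in 0:(2^n - 1)) {
    v <- as.integer(bitwAnd(bitwShiftR(code, (n - 1):0), 1L))
    ok <- TRUE
    for (i in seq_len(n)) {
      if (.updateCompiled(cn, v, i, tieHold) != v[i]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, paste(v, collapse = ""))
  }
  out
}
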