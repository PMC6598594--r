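#' Node eccentricity: inverse longest shortest out-path
#'
#' For a node g, the eccentricity is \code{1 / max_d(g)}, where \code{max_d(g)}
#' is the longest of the shortest directed path lengths from g to every node
#' it can reach (unreachable nodes are excluded, self-distance ignored). It
#' summarizes how many direct and indirect downstream interactions a node has:
#' a node whose whole downstream cone is shallow scores high. A node that
#' reaches nothing (a sink) gets eccentricity 0, the limit of 1/infinity.
#'
#' @param net A [BooleanNetwork-class].
#' @param nodes Node ids to evaluate (default: all nodes).
#' @param directed Use directed paths out of the node (default); set
#'   \code{FALSE} to measure on the undirected skeleton.
#' @return Named numeric vector of eccentricities in [0, 1].
#' @export
nodeEccentricity <- function(net, nodes = nodeIds(net), directed = TRUE) {
  bad <- setdiff(nodes, nodeIds(net))
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  g <- .asIgraph(net)
  d <- igraph::distances(g, v = nodes, to = igraph::V(g),
                         mode = if (directed) "out" else "all")
  apply(d, 1, function(row) {
    row <- row[is.finite(row) & row > 0]
    if (length(row) == 0) 0 else 1 / max(row)
  })
}

#' Topological node scores from out-degree and eccentricity ranks
#'
#' Ranks every node by out-degree and by eccentricity (rank 1 = largest, ties
#' share the mean of the tied positions) and combines the two ranks into the
#' score \code{S = -log(R_OD + R_E)}. Using ranks rather than the raw metrics
#' gives both criteria equal weight regardless of their ranges; the negative
#' log makes larger scores correspond to more influential nodes.
#'
#' @param net A [BooleanNetwork-class] (nonempty).
#' @param logBase Base of the logarithm (default natural log).
#' @param directed Passed to [nodeEccentricity()].
#' @return data.frame with one row per node: \code{node}, \code{out_degree},
#'   \code{eccentricity}, \code{rank_out_degree}, \code{rank_eccentricity},
#'   \code{score}; sorted by descending score.
#' @export
scoreNodes <- function(net, logBase = exp(1), directed = TRUE) {
  if (numNodes(net) == 0) stop("cannot score an empty network")
  ids <- nodeIds(net)
  od <- vapply(ids, function(i) sum(net@edges$from == i), 0L)
  ecc <- nodeEccentricity(net, ids, directed = directed)
  r_od <- rank(-od, ties.method = "average")
  r_e <- rank(-ecc, ties.method = "average")
  score <- -log(r_od + r_e, base = logBase)
  out <- data.frame(node = ids, out_degree = unname(od),
                    eccentricity = unname(ecc),
                    rank_out_degree = unname(r_od),
                    rank_eccentricity = unname(r_e),
                    score = unname(score), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the gene signature by score threshold
#'
#' Keeps every node whose combined topological score meets the threshold
#' (the published analysis used -2.5), sorted by descending score, and
#' optionally appends an inducer node (e.g. the EMT trigger TGFB1) that is
#' flagged as added rather than scored.
#'
#' @param scores A score table from [scoreNodes()].
#' @param threshold Minimum score for inclusion (finite).
#' @param inducer Optional node id appended to the signature if not already
#'   selected.
#' @return A [Signature-class]. An empty selection triggers a warning and an
#'   empty (or inducer-only) signature.
#' @export
selectSignature <- function(scores, threshold = -2.5, inducer = NULL) {
  stopifnot(is.finite(threshold))
  keep <- scores[scores$score >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$node), , drop = FALSE]
  if (nrow(keep) == 0)
    warning("no node reaches the score threshold; signature is empty")
  genes <- keep$node
  sc <- keep$score
  ind <- character()
  if (!is.null(inducer) && !inducer %in% genes) {
    genes <- c(genes, inducer)
    sc <- c(sc, NA_real_)
    ind <- inducer
  }
  new("Signature", genes = genes, scores = sc, threshold = threshold,
      inducer = ind)
}

#' @describeIn selectSignature Gene ids of a signature (inducer included).
#' @param sig A [Signature-class].
#' @export
signatureGenes <- function(sig) sig@genes

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature: %d genes (threshold %.3g)%s\n",
              length(object@genes), object@threshold,
              if (length(object@inducer))
                sprintf(", inducer %s appended", object@inducer) else ""))
  cat(" ", paste(object@genes, collapse = ", "), "\n")
})
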