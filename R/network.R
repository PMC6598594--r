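#' Construct a BooleanNetwork
#'
#' Builds and validates a [BooleanNetwork-class] from node and edge tables.
#' Nodes and edges are put in canonical lexicographic order so that two
#' structurally identical networks are identical objects; duplicate parallel
#' edges of equal sign are collapsed.
#'
#' @param nodes data.frame with columns \code{id} and optionally \code{rule}
#'   (default \code{"MAJ"}) and \code{label} (default the id), or a character
#'   vector of node ids.
#' @param edges data.frame with columns \code{from}, \code{to}, \code{sign}
#'   (+1 or -1). May be empty or missing for an edgeless network.
#' @return A validated [BooleanNetwork-class].
#' @examples
#' net <- booleanNetwork(
#'   nodes = c("A", "B", "C"),
#'   edges = data.frame(from = c("A", "B"), to = c("B", "C"), sign = c(1, -1)))
#' net
#' @export
booleanNetwork <- function(nodes, edges = NULL) {
  if (is.character(nodes))
    nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$rule)) nodes$rule <- rep("MAJ", nrow(nodes))
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes <- nodes[, c("id", "rule", "label")]
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges <- edges[, c("from", "to", "sign")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as.integer(edges$sign)
    edges <- unique(edges)
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("BooleanNetwork", nodes = nodes, edges = edges)
}

#' @describeIn booleanNetwork Node identifiers, in canonical order.
#' @param net A [BooleanNetwork-class].
#' @export
nodeIds <- function(net) net@nodes$id

#' @describeIn booleanNetwork Node table (id, rule, label).
#' @export
nodeTable <- function(net) net@nodes

#' @describeIn booleanNetwork Edge table (from, to, sign).
#' @export
edgeTable <- function(net) net@edges

#' @describeIn booleanNetwork Number of nodes.
#' @export
numNodes <- function(net) nrow(net@nodes)

#' @describeIn booleanNetwork Number of edges.
#' @export
numEdges <- function(net) nrow(net@edges)

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork: %d nodes, %d edges (%d AND, %d MAJ; %d inhibitory)\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@nodes$rule == "AND"), sum(object@nodes$rule == "MAJ"),
              sum(object@edges$sign == -1)))
  shown <- head(object@nodes$id, 8)
  cat("  nodes:", paste(shown, collapse = ", "),
      if (nrow(object@nodes) > 8) "..." else "", "\n")
})

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph '%s': %d entries (%d complexes), %d relations\n",
              object@pathwayId, nrow(object@nodes),
              sum(object@nodes$node_class == "complex"), nrow(object@edges)))
})

## igraph view of the network (directed; used for components and distances)
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net@edges[, c("from", "to", "sign")],
    directed = TRUE,
    vertices = net@nodes[, c("id", "rule", "label")])
}

#' Merge Boolean networks on stable node identifiers
#'
#' Unifies nodes that share the same identifier across pathway-derived
#' networks and takes the union of the edges (parallel edges with equal sign
#' collapse to one). When the same node carries rule \code{AND} in one network
#' and \code{MAJ} in another, \code{AND} wins: a node that is a complex
#' anywhere must require all of its components.
#'
#' @param nets A list of [BooleanNetwork-class] objects (or several networks
#'   given as separate arguments).
#' @param ... Further networks when \code{nets} is a single network.
#' @return A single merged [BooleanNetwork-class].
#' @export
mergeNetworks <- function(nets, ...) {
  if (is(nets, "BooleanNetwork")) nets <- c(list(nets), list(...))
  stopifnot(length(nets) >= 1)
  nodes <- do.call(rbind, lapply(nets, nodeTable))
  edges <- do.call(rbind, lapply(nets, edgeTable))
  ## AND anywhere -> AND (complex membership is the stricter constraint)
  rule <- tapply(nodes$rule, nodes$id, function(r) if ("AND" %in% r) "AND" else "MAJ")
  label <- tapply(nodes$label, nodes$id, `[`, 1)
  ids <- sort(unique(nodes$id))
  booleanNetwork(
    data.frame(id = ids, rule = unname(rule[ids]), label = unname(label[ids]),
               stringsAsFactors = FALSE),
    edges)
}

#' Weakly connected components of a Boolean network
#'
#' Components are computed on the undirected skeleton (edge direction ignored
#' for membership) and returned as induced sub-networks sorted by size,
#' largest first; equally sized components are ordered by their
#' lexicographically smallest node id set.
#'
#' @param net A [BooleanNetwork-class].
#' @return A list of [BooleanNetwork-class] objects partitioning \code{net}.
#' @export
connectedComponents <- function(net) {
  if (numNodes(net) == 0) return(list())
  g <- .asIgraph(net)
  comp <- igraph::components(g, mode = "weak")
  member <- split(nodeIds(net), comp$membership[nodeIds(net)])
  ## order: size desc, then smallest sorted id vector lexicographically
  keys <- vapply(member, function(ids) paste(sort(ids), collapse = "\r"), "")
  ord <- order(-lengths(member), keys)
  lapply(unname(member[ord]), function(ids) inducedSubnetwork(net, ids))
}

#' @describeIn connectedComponents The sub-network induced by a node subset.
#' @param ids Character vector of node ids to keep.
#' @export
inducedSubnetwork <- function(net, ids) {
  nd <- net@nodes[net@nodes$id %in% ids, , drop = FALSE]
  ed <- net@edges[net@edges$from %in% ids & net@edges$to %in% ids, , drop = FALSE]
  booleanNetwork(nd, ed)
}

#' @describeIn connectedComponents The largest weakly connected component
#'   (first element of \code{connectedComponents}); errors on an empty
#'   network.
#' @export
largestComponent <- function(net) {
  comps <- connectedComponents(net)
  if (length(comps) == 0) stop("cannot take the largest component of an empty network")
  comps[[1]]
}

#' Read and write the JSON network dialect
#'
#' Networks serialize to a plain JSON document
#' \code{{"nodes":[{"id","rule","label"}],"edges":[{"src","dst","sign"}]}}.
#' The canonical node/edge ordering makes the round trip lossless and
#' byte-stable.
#'
#' @param net A [BooleanNetwork-class].
#' @param path File path.
#' @return \code{readBooleanNetwork} returns a [BooleanNetwork-class];
#'   \code{writeBooleanNetwork} invisibly returns \code{path}.
#' @export
writeBooleanNetwork <- function(net, path) {
  ed <- net@edges
  names(ed) <- c("src", "dst", "sign")
  doc <- list(nodes = net@nodes, edges = ed)
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeBooleanNetwork
#' @export
readBooleanNetwork <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- doc$edges
  if (NROW(edges) > 0) names(edges) <- c("from", "to", "sign")
  booleanNetwork(doc$nodes, edges)
}
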