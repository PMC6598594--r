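## Synthetic fixture generators. Everything here is deterministic under
## set.seed (or the optional seed argument, which scopes the RNG locally so
## fixtures are bit-for-bit reproducible without disturbing the caller's
## stream).

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random Boolean network fixture
#'
#' Erdos-Renyi-style directed network over gene nodes with a controlled
#' inhibitory edge fraction, optional AND complexes, and optional planted
#' hub nodes wired to many targets (so their out-degree dominates the
#' background and they must surface in the topological signature).
#'
#' @param nNodes Number of gene nodes (>= 1).
#' @param edgeDensity Probability of each ordered gene pair being an edge.
#' @param inhibitionFraction Fraction of background edges with sign -1.
#' @param nComplexes Number of two-member AND complexes appended.
#' @param plantedHubs Number of hub nodes (the first node ids), each wired
#'   with +1 edges to \code{hubOut} distinct other genes.
#' @param hubOut Out-degree given to each planted hub (default 10).
#' @param seed Optional seed fixing the fixture bit-for-bit.
#' @return A [BooleanNetwork-class].
#' @export
randomBooleanNetwork <- function(nNodes, edgeDensity = 0.08,
                                 inhibitionFraction = 0.2, nComplexes = 0,
                                 plantedHubs = 0, hubOut = 10, seed = NULL) {
  stopifnot(nNodes >= 1, edgeDensity >= 0, edgeDensity <= 1,
            inhibitionFraction >= 0, inhibitionFraction <= 1,
            plantedHubs == 0 || nNodes > hubOut)
  .withSeed(seed, {
    ids <- sprintf("g%03d", seq_len(nNodes))
    pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    keep <- runif(nrow(pairs)) < edgeDensity
    edges <- pairs[keep, , drop = FALSE]
    if (nrow(edges))
      edges$sign <- ifelse(runif(nrow(edges)) < inhibitionFraction, -1L, 1L)
    else edges$sign <- integer()
    nodes <- data.frame(id = ids, rule = "MAJ", label = ids,
                        stringsAsFactors = FALSE)
    for (h in seq_len(plantedHubs)) {
      hub <- ids[h]
      targets <- sample(setdiff(ids, hub), hubOut)
      edges <- rbind(edges, data.frame(from = hub, to = targets, sign = 1L,
                                       stringsAsFactors = FALSE))
    }
    for (cx in seq_len(nComplexes)) {
      mem <- sort(sample(ids, 2))
      cid <- paste(mem, collapse = "+")
      if (cid %in% nodes$id) next
      nodes <- rbind(nodes, data.frame(id = cid, rule = "AND", label = cid,
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(from = mem, to = cid, sign = 1L,
                                       stringsAsFactors = FALSE))
    }
    booleanNetwork(nodes, edges)
  })
}

#' Planted-attractor network with an enumerable fixed-point set
#'
#' Builds \code{kBasins} disjoint self-reinforcing MAJ loops -- complete
#' positive cliques, every loop node activated by all the others -- coupled
#' by one inhibitory edge from each loop to the next. Each clique is
#' strictly bistable under the majority rule: in a mixed configuration some
#' off node sees at least one net active activator (the single inhibitor can
#' at most cancel one of them) and switches on, so only the all-on and
#' all-off loop levels persist, and the coupling never breaks a level
#' (an active inhibitor at most ties, and ties hold). The fixed points are
#' therefore exactly the \code{2^kBasins} combinations of loop levels,
#' returned alongside the network.
#'
#' @param kBasins Number of loops, 1 to 4.
#' @param loopSize Nodes per loop (>= 3 so that the clique argument holds;
#'   default 3).
#' @param seed Unused randomness guard (construction is deterministic); kept
#'   for interface symmetry with the other generators.
#' @return list with \code{net} (a [BooleanNetwork-class]) and
#'   \code{fixedPoints} (bit-strings in canonical node order).
#' @export
plantedAttractorNetwork <- function(kBasins, loopSize = 3, seed = NULL) {
  stopifnot(kBasins >= 1, kBasins <= 4, loopSize >= 3)
  ids <- as.vector(outer(seq_len(loopSize), seq_len(kBasins),
                         function(i, k) sprintf("L%dn%d", k, i)))
  edges <- do.call(rbind, lapply(seq_len(kBasins), function(k) {
    pr <- expand.grid(i = seq_len(loopSize), j = seq_len(loopSize))
    pr <- pr[pr$i != pr$j, ]
    data.frame(from = sprintf("L%dn%d", k, pr$i),
               to = sprintf("L%dn%d", k, pr$j),
               sign = 1L, stringsAsFactors = FALSE)
  }))
  if (kBasins > 1)
    edges <- rbind(edges, data.frame(
      from = sprintf("L%dn1", seq_len(kBasins)),
      to = sprintf("L%dn1", c(seq_len(kBasins)[-1], 1)),
      sign = -1L, stringsAsFactors = FALSE))
  net <- booleanNetwork(ids, edges)
  combos <- expand.grid(rep(list(c(0L, 1L)), kBasins))
  fixed <- apply(combos, 1, function(levels) {
    st <- setNames(rep(0L, length(ids)), ids)
    for (k in seq_len(kBasins))
      st[sprintf("L%dn%d", k, seq_len(loopSize))] <- levels[k]
    stateKey(st[nodeIds(net)])
  })
  list(net = net, fixedPoints = sort(unique(fixed)))
}

#' Toy KGML documents
#'
#' \code{toyKGML} emits a small, valid KGML pathway exercising every
#' interaction subtype of the conversion vocabulary at least once (complex
#' formation via a group entry), optionally plus an out-of-vocabulary
#' subtype to exercise the unmapped path. \code{kgmlFromNetwork} serializes
#' a MAJ-only Boolean network as a KGML pathway (activation/inhibition
#' relations), which lets synthetic networks drive the full parsing
#' pipeline.
#'
#' @param path Optional file path; when given the XML is written there and
#'   the path returned, otherwise the XML string is returned.
#' @param includeUnknown Also emit a relation with subtype
#'   \code{"state change"}, which is not in the vocabulary.
#' @return XML string, or \code{path} if written.
#' @export
toyKGML <- function(path = NULL, includeUnknown = FALSE) {
  entries <- paste0(
    '  <entry id="1" name="hsa:101" type="gene"/>\n',
    '  <entry id="2" name="hsa:102" type="gene"/>\n',
    '  <entry id="3" name="hsa:103" type="gene"/>\n',
    '  <entry id="4" name="hsa:104" type="gene"/>\n',
    '  <entry id="5" name="hsa:105" type="gene"/>\n',
    '  <entry id="6" name="hsa:106" type="gene"/>\n',
    '  <entry id="7" name="undefined" type="group">\n',
    '    <component id="1"/>\n    <component id="2"/>\n  </entry>\n')
  rel <- function(a, b, sub)
    sprintf('  <relation entry1="%s" entry2="%s" type="PPrel">\n    <subtype name="%s" value="?"/>\n  </relation>\n',
            a, b, sub)
  rels <- paste0(
    rel(1, 3, "activation"), rel(2, 3, "inhibition"),
    rel(3, 4, "expression"), rel(4, 5, "binding/association"),
    rel(5, 6, "dissociation"), rel(1, 6, "missing interaction"),
    rel(2, 6, "remove"),
    if (includeUnknown) rel(3, 6, "state change") else "")
  xml <- paste0('<?xml version="1.0"?>\n',
                '<pathway name="path:toy01" org="hsa" number="00001" title="toy">\n',
                entries, rels, "</pathway>\n")
  if (is.null(path)) return(xml)
  writeLines(xml, path)
  invisible(path)
}

#' @rdname toyKGML
#' @param net A [BooleanNetwork-class] with only MAJ nodes.
#' @param pathwayId Pathway name attribute.
#' @export
kgmlFromNetwork <- function(net, pathwayId = "path:syn01", path = NULL) {
  if (any(net@nodes$rule != "MAJ"))
    stop("only MAJ-only networks can be serialized as plain KGML relations")
  ids <- nodeIds(net)
  eid <- setNames(seq_along(ids), ids)
  entries <- paste(sprintf('  <entry id="%d" name="hsa:%s" type="gene"/>',
                           eid, ids), collapse = "\n")
  ed <- net@edges
  rels <- if (nrow(ed)) paste(sprintf(
    '  <relation entry1="%d" entry2="%d" type="PPrel">\n    <subtype name="%s" value="?"/>\n  </relation>',
    eid[ed$from], eid[ed$to],
    ifelse(ed$sign == 1, "activation", "inhibition")), collapse = "\n")
    else ""
  xml <- paste0('<?xml version="1.0"?>\n<pathway name="', pathwayId,
                '" org="hsa" number="00000" title="synthetic">\n',
                entries, "\n", rels, "\n</pathway>\n")
  if (is.null(path)) return(xml)
  writeLines(xml, path)
  invisible(path)
}

#' Synthetic expression summary table
#'
#' Emulates a baseMean expression summary over the signature genes.
#' \code{"graded"} gives strictly halving values (top gene 100), so the
#' prevalence-target ratios are exactly checkable; \code{"uniform"} gives
#' all genes the same level; \code{"sparse"} is graded with the last gene
#' silenced (baseMean 0).
#'
#' @param sig A [Signature-class] or character vector of gene ids.
#' @param profile \code{"graded"}, \code{"uniform"} or \code{"sparse"}.
#' @return data.frame with columns \code{gene_id}, \code{baseMean}.
#' @export
syntheticExpressionTable <- function(sig,
                                     profile = c("graded", "uniform", "sparse")) {
  profile <- match.arg(profile)
  genes <- if (is(sig, "Signature")) signatureGenes(sig) else sig
  n <- length(genes)
  bm <- switch(profile,
               graded = 100 * 2^-(seq_len(n) - 1),
               uniform = rep(100, n),
               sparse = c(100 * 2^-(seq_len(n - 1) - 1), 0))
  data.frame(gene_id = genes, baseMean = bm, stringsAsFactors = FALSE)
}

#' Construct a phenotype chain directly from patterns and a matrix
#'
#' Assembles a [PhenotypeDTMC-class] from an explicit state list and
#' row-stochastic matrix, bypassing the simulation campaigns. Intended for
#' hand-solvable chains in examples and tests of the population dynamics.
#'
#' @param patterns Bit-string patterns over \code{genes}, one per state.
#' @param P Row-stochastic matrix (row = source state).
#' @param genes Signature gene order (default synthetic names).
#' @param basinWeights Optional weights (default 1 per state).
#' @return A [PhenotypeDTMC-class].
#' @export
phenotypeDTMC <- function(patterns, P,
                          genes = sprintf("m%d", seq_len(nchar(patterns[1]))),
                          basinWeights = rep(1, length(patterns))) {
  P <- as.matrix(P)
  k <- length(patterns)
  states <- new("PhenotypeStateSet", signatureGenes = genes,
                nodeIds = genes, patterns = patterns,
                basinWeights = basinWeights,
                representatives = as.list(patterns))
  D <- outer(patterns, patterns, Vectorize(function(a, b) .hamming(a, b)))
  new("PhenotypeDTMC", states = states, P = P,
      counts = matrix(0, k, k), totals = rep(0, k), dist = D,
      meanLength = matrix(NA_real_, k, k),
      absorbing = vapply(seq_len(k), function(i) P[i, i] == 1, TRUE),
      snapFraction = NA_real_)
}

#' Random phenotype chain fixture
#'
#' Distinct random signature patterns plus Dirichlet-distributed rows.
#'
#' @param nStates Number of states (>= 2).
#' @param nGenes Signature size (default enough to host the states).
#' @param seed Optional local seed.
#' @return A [PhenotypeDTMC-class].
#' @export
randomChain <- function(nStates, nGenes = max(3, ceiling(log2(nStates)) + 1),
                        seed = NULL) {
  stopifnot(nStates >= 2, 2^nGenes >= nStates)
  .withSeed(seed, {
    codes <- sample.int(2^nGenes, nStates) - 1L
    patterns <- vapply(codes, function(cd)
      paste(bitwAnd(bitwShiftR(cd, (nGenes - 1):0), 1L), collapse = ""), "")
    P <- matrix(rgamma(nStates^2, shape = 1), nStates)
    P <- P / rowSums(P)
    phenotypeDTMC(patterns, P)
  })
}
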