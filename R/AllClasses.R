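#' @import methods
#' @importFrom stats runif rgamma sd setNames
#' @importFrom utils head read.delim write.table
NULL

#' PathwayGraph: a parsed KEGG pathway
#'
#' Intermediate representation of a single KGML pathway document: the gene and
#' complex (group) entries, and the relations between them with their KEGG
#' interaction subtype preserved verbatim.
#'
#' @slot pathwayId Pathway identifier (the KGML \code{name} attribute).
#' @slot nodes data.frame with columns \code{entry_id} (character),
#'   \code{node_class} (\code{"gene"} or \code{"complex"}) and \code{genes}
#'   (list column of character identifier vectors).
#' @slot edges data.frame with columns \code{from}, \code{to} (entry ids) and
#'   \code{kegg_type} (relation subtype name, kept even when it maps to no
#'   Boolean operation).
#'
#' @seealso [parseKGML()], [pathwayToBoolean()]
#' @export
setClass("PathwayGraph",
  representation(pathwayId = "character", nodes = "data.frame",
                 edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("entry_id", "node_class", "genes") %in% names(nd)))
    msg <- c(msg, "nodes must have columns entry_id, node_class, genes")
  else {
    if (anyDuplicated(nd$entry_id))
      msg <- c(msg, "entry ids must be unique within a pathway")
    if (!all(nd$node_class %in% c("gene", "complex")))
      msg <- c(msg, "node_class must be 'gene' or 'complex'")
  }
  if (!all(c("from", "to", "kegg_type") %in% names(ed)))
    msg <- c(msg, "edges must have columns from, to, kegg_type")
  else if (nrow(ed) > 0 &&
           !all(c(ed$from, ed$to) %in% nd$entry_id))
    msg <- c(msg, "every relation endpoint must be a declared entry")
  if (length(msg)) msg else TRUE
})

#' BooleanNetwork: a signed regulatory network with per-node update rules
#'
#' Directed signed graph over genes and complexes. Each node carries an update
#' rule: \code{MAJ} (majority -- the node switches on when its active
#' activating inputs outnumber its active inhibiting inputs) or \code{AND}
#' (complex formation -- on only when every component is present). Edges carry
#' a sign, +1 for activation and -1 for inhibition. AND nodes admit only +1
#' inputs. Nodes and edges are kept in canonical (lexicographic) order so that
#' structurally equal networks compare equal and serialize identically.
#'
#' @slot nodes data.frame with columns \code{id}, \code{rule}, \code{label}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{sign}.
#'
#' @seealso [booleanNetwork()], [mergeNetworks()], [connectedComponents()],
#'   [runToAttractor()]
#' @export
setClass("BooleanNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("BooleanNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msg <- character()
  if (!all(c("id", "rule", "label") %in% names(nd)))
    return("nodes must have columns id, rule, label")
  if (!all(c("from", "to", "sign") %in% names(ed)))
    return("edges must have columns from, to, sign")
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicate node ids")
  if (!all(nd$rule %in% c("MAJ", "AND")))
    msg <- c(msg, "rules must be MAJ or AND")
  if (nrow(ed) > 0) {
    if (!all(ed$sign %in% c(-1, 1)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (!all(c(ed$from, ed$to) %in% nd$id))
      msg <- c(msg, "edge endpoints must reference existing nodes")
    and_nodes <- nd$id[nd$rule == "AND"]
    if (any(ed$sign == -1 & ed$to %in% and_nodes))
      msg <- c(msg, "AND nodes admit only +1 incoming edges")
    if (anyDuplicated(ed[, c("from", "to", "sign")]))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Signature: genes selected by topological score
#'
#' Ordered gene list retained by thresholding the combined out-degree /
#' eccentricity score, optionally completed with an externally supplied
#' inducer node (e.g. TGFB1 for EMT) that is flagged as added rather than
#' scored.
#'
#' @slot genes Character vector of node ids, sorted by descending score; an
#'   appended inducer comes last.
#' @slot scores Scores aligned to \code{genes} (\code{NA} for an appended
#'   inducer).
#' @slot threshold The score threshold used for selection.
#' @slot inducer The appended inducer id, or \code{character(0)}.
#'
#' @seealso [selectSignature()]
#' @export
setClass("Signature",
  representation(genes = "character", scores = "numeric",
                 threshold = "numeric", inducer = "character"))

setValidity("Signature", function(object) {
  if (length(object@genes) != length(object@scores))
    return("genes and scores must be aligned")
  if (anyDuplicated(object@genes)) return("duplicate signature genes")
  scored <- setdiff(object@genes, object@inducer)
  sc <- object@scores[match(scored, object@genes)]
  if (length(sc) && any(is.na(sc))) return("scored genes must have scores")
  if (length(sc) && any(sc < object@threshold - 1e-12))
    return("all scored signature genes must meet the threshold")
  TRUE
})

#' AttractorSet: deduplicated single-state attractors with basin counts
#'
#' Result of an attractor search campaign: the distinct converged end states
#' (fixed points), each with the number of simulations that reached it -- an
#' estimate of relative basin size.
#'
#' @slot nodeIds Node order used for the state bit-strings.
#' @slot states Character vector of 0/1 bit-strings, one per attractor,
#'   sorted by decreasing count.
#' @slot counts Integer occurrence counts aligned to \code{states}.
#' @slot nConverged Number of simulations that converged.
#' @slot nTotal Total number of simulations run.
#'
#' @seealso [attractorCampaign()]
#' @export
setClass("AttractorSet",
  representation(nodeIds = "character", states = "character",
                 counts = "integer", nConverged = "integer",
                 nTotal = "integer"))

setValidity("AttractorSet", function(object) {
  if (length(object@states) != length(object@counts))
    return("states and counts must be aligned")
  if (anyDuplicated(object@states)) return("attractor states must be distinct")
  if (length(object@states) &&
      any(nchar(object@states) != length(object@nodeIds)))
    return("state bit-strings must cover every node")
  if (sum(object@counts) > object@nConverged)
    return("counts cannot exceed the number of converged runs")
  TRUE
})

#' PhenotypeStateSet: attractors merged by signature pattern
#'
#' The states of the phenotype Markov chain. Full-network attractors are
#' projected onto the signature genes and grouped by exact pattern; each group
#' is one phenotype, weighted by the summed basin counts of its members and
#' keeping those members as representative full configurations.
#'
#' @slot signatureGenes Signature gene order used for the patterns.
#' @slot nodeIds Full-network node order used for the representatives.
#' @slot patterns Character 0/1 bit-strings over the signature genes, one per
#'   phenotype, ordered by decreasing basin weight (state id = position).
#' @slot basinWeights Summed attractor counts per phenotype.
#' @slot representatives List (one element per phenotype) of full-network
#'   bit-strings that project onto the phenotype's pattern.
#'
#' @seealso [mergeAttractors()], [snapToKnown()]
#' @export
setClass("PhenotypeStateSet",
  representation(signatureGenes = "character", nodeIds = "character",
                 patterns = "character", basinWeights = "numeric",
                 representatives = "list"))

setValidity("PhenotypeStateSet", function(object) {
  k <- length(object@patterns)
  if (anyDuplicated(object@patterns)) return("phenotype patterns must be unique")
  if (length(object@basinWeights) != k || length(object@representatives) != k)
    return("patterns, basinWeights and representatives must be aligned")
  if (k && any(nchar(object@patterns) != length(object@signatureGenes)))
    return("pattern length must equal the signature size")
  TRUE
})

#' PhenotypeDTMC: discrete-time Markov chain over phenotypes
#'
#' Row-stochastic transition matrix over signature-defined phenotype states,
#' estimated from perturbation simulations. Each off-diagonal probability is
#' the relative transition frequency corrected by the Hamming distance between
#' the two patterns and the mean simulation length of the recorded runs, then
#' renormalized per row; sources with no recorded exit become absorbing.
#'
#' @slot states The underlying [PhenotypeStateSet-class].
#' @slot P Row-stochastic transition matrix (row = source phenotype).
#' @slot counts Raw transition counts N_ij.
#' @slot totals Row totals N_i (successful exits per source).
#' @slot dist Signature-Hamming distances d_ij between patterns.
#' @slot meanLength Mean iteration counts I_ij of the recorded i -> j runs.
#' @slot absorbing Logical per-state flag: no successful exit was recorded.
#' @slot snapFraction Fraction of runs whose end state had to be snapped to a
#'   known phenotype.
#'
#' @seealso [buildTransitionMatrix()], [transitionCampaign()], [dtmcStep()]
#' @export
setClass("PhenotypeDTMC",
  representation(states = "PhenotypeStateSet", P = "matrix",
                 counts = "matrix", totals = "numeric", dist = "matrix",
                 meanLength = "matrix", absorbing = "logical",
                 snapFraction = "numeric"))

setValidity("PhenotypeDTMC", function(object) {
  k <- length(object@states@patterns)
  if (!all(dim(object@P) == c(k, k)))
    return("P must be square over the phenotype states")
  if (any(object@P < -1e-15)) return("transition probabilities must be >= 0")
  rs <- rowSums(object@P)
  if (any(abs(rs - 1) > 1e-12))
    return("every row of P must sum to 1")
  TRUE
})

#' PopulationTrajectory: time course of phenotype prevalences
#'
#' Deterministic evolution of a prevalence vector under the phenotype chain:
#' one row per iteration (row 1 = initial condition), one column per
#' phenotype state; every row sums to 1.
#'
#' @slot prevalence Numeric matrix, iterations x states.
#' @slot converged Whether the stopping tolerance was reached before
#'   \code{maxSteps}.
#' @slot patterns Signature patterns of the states (column order).
#' @slot signatureGenes Signature gene order for the patterns.
#'
#' @seealso [simulatePopulation()], [weightedJND()]
#' @export
setClass("PopulationTrajectory",
  representation(prevalence = "matrix", converged = "logical",
                 patterns = "character", signatureGenes = "character"))

setValidity("PopulationTrajectory", function(object) {
  if (ncol(object@prevalence) != length(object@patterns))
    return("one column per phenotype state required")
  if (nrow(object@prevalence) &&
      any(abs(rowSums(object@prevalence) - 1) > 1e-9))
    return("prevalences must sum to 1 at every iteration")
  TRUE
})
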