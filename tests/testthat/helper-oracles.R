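# Independent oracles used against the package implementation. These work
# straight off node/edge tables and never call the package's simulation or
# graph internals.

# shorthand network builder: edges as "A->B:+" / "A-|B" strings
makeNet <- function(edgeSpec = character(), nodes = NULL, andNodes = character()) {
  parse1 <- function(s) {
    sign <- if (grepl("-\\|", s)) -1L else 1L
    parts <- strsplit(s, "->|-\\|", perl = TRUE)[[1]]
    c(from = parts[1], to = parts[2], sign = sign)
  }
  ed <- if (length(edgeSpec)) {
    m <- t(vapply(edgeSpec, parse1, c(from = "", to = "", sign = "")))
    data.frame(from = m[, 1], to = m[, 2], sign = as.integer(m[, 3]),
               stringsAsFactors = FALSE)
  } else NULL
  ids <- unique(c(nodes, if (!is.null(ed)) c(ed$from, ed$to)))
  booleanNetwork(data.frame(id = ids,
                            rule = ifelse(ids %in% andNodes, "AND", "MAJ"),
                            stringsAsFactors = FALSE), ed)
}

# single-node update computed directly from the edge table
oracleUpdate <- function(net, state, node, tieHold = TRUE) {
  ed <- edgeTable(net)
  nd <- nodeTable(net)
  ins <- ed[ed$to == node, , drop = FALSE]
  if (nrow(ins) == 0) return(state[[node]])
  if (nd$rule[nd$id == node] == "AND")
    return(as.integer(all(state[ins$from] == 1L)))
  delta <- sum(ins$sign[state[ins$from] == 1L])
  if (delta > 0) 1L else if (delta < 0) 0L
  else if (tieHold) state[[node]] else 0L
}

oracleIsFixed <- function(net, state, tieHold = TRUE) {
  all(vapply(nodeIds(net), function(nd)
    oracleUpdate(net, state, nd, tieHold) == state[[nd]], TRUE))
}

# brute-force 2^n fixed-point enumeration via oracleUpdate only
oracleFixedPoints <- function(net, tieHold = TRUE) {
  ids <- nodeIds(net)
  n <- length(ids)
  stopifnot(n <= 14)
  keys <- character()
  for (code in 0:(2^n - 1)) {
    v <- setNames(as.integer(bitwAnd(bitwShiftR(code, (n - 1):0), 1L)), ids)
    if (oracleIsFixed(net, v, tieHold)) keys <- c(keys, paste(v, collapse = ""))
  }
  keys
}

# vectorized brute-force fixed-point enumeration: plain matrix algebra on
# the edge table (independent of the package's simulation internals)
oracleFixedPointsFast <- function(net, tieHold = TRUE) {
  ids <- nodeIds(net)
  n <- length(ids)
  stopifnot(n <= 14)
  ed <- edgeTable(net)
  nd <- nodeTable(net)
  A <- matrix(0, n, n, dimnames = list(ids, ids))   # signed adjacency
  if (nrow(ed)) A[cbind(ed$from, ed$to)] <- ed$sign
  Apos <- (A > 0) * 1
  indeg <- colSums(A != 0)
  isAND <- nd$rule == "AND"
  S <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  delta <- S %*% A            # per state, net active input per node
  onAll <- S %*% Apos         # active positive inputs per node
  newS <- S
  for (j in seq_len(n)) {
    if (indeg[j] == 0) next                       # input-free: hold
    if (isAND[j]) newS[, j] <- as.integer(onAll[, j] == indeg[j])
    else newS[, j] <- ifelse(delta[, j] > 0, 1L,
                      ifelse(delta[, j] < 0, 0L,
                             if (tieHold) S[, j] else 0L))
  }
  fixed <- rowSums(newS != S) == 0
  apply(S[fixed, , drop = FALSE], 1, paste, collapse = "")
}

# union-find connected components over the undirected skeleton
oracleComponents <- function(net) {
  ids <- nodeIds(net)
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  ed <- edgeTable(net)
  for (i in seq_len(nrow(ed))) {
    a <- find(ed$from[i]); b <- find(ed$to[i])
    if (a != b) parent[[a]] <- b
  }
  split(ids, vapply(ids, find, ""))
}

# longest-shortest-path eccentricity by hand-rolled BFS on the edge table
oracleEccentricity <- function(net, node) {
  ed <- edgeTable(net)
  dist <- setNames(rep(Inf, numNodes(net)), nodeIds(net))
  dist[node] <- 0
  frontier <- node
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(ed$to[ed$from %in% frontier])
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  reach <- dist[is.finite(dist) & dist > 0]
  if (length(reach) == 0) 0 else 1 / max(reach)
}

# random 0/1 pattern matrix with gene column names
randomPatternMatrix <- function(nPat, genes) {
  m <- matrix(sample(0:1, nPat * length(genes), replace = TRUE), nPat)
  colnames(m) <- genes
  rownames(m) <- as.character(seq_len(nPat))
  m
}
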