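test_that("KGML parsing captures entries, groups and relation subtypes", {
  f <- withr::local_tempfile(fileext = ".xml")
  toyKGML(f, includeUnknown = TRUE)
  pg <- parseKGML(f)
  expect_s4_class(pg, "PathwayGraph")
  expect_equal(nrow(pg@nodes), 7)
  expect_equal(sum(pg@nodes$node_class == "complex"), 1)
  # the group holds both member gene ids
  grp <- pg@nodes$genes[[which(pg@nodes$node_class == "complex")]]
  expect_setequal(grp, c("101", "102"))
  # all 8 relations captured with subtype verbatim, incl. the unmapped one
  expect_equal(nrow(pg@edges), 8)
  expect_true("state change" %in% pg@edges$kegg_type)
  expect_true(all(c("missing interaction", "remove") %in% pg@edges$kegg_type))
})

test_that("KGML parse errors are structural, not silent", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway name='x'><entry id='1' name='hsa:1' type='gene'>", f)
  expect_error(parseKGML(f), "malformed")
  writeLines(paste0("<pathway name='x'><entry id='1' name='hsa:1' type='gene'/>",
                    "<relation entry1='1' entry2='9' type='PPrel'>",
                    "<subtype name='activation' value='?'/></relation></pathway>"), f)
  expect_error(parseKGML(f), "absent")
})

test_that("interaction types map to the documented Boolean operations", {
  mk <- function(sub) {
    f <- withr::local_tempfile(fileext = ".xml")
    writeLines(sprintf(paste0(
      '<pathway name="p"><entry id="1" name="hsa:1" type="gene"/>',
      '<entry id="2" name="hsa:2" type="gene"/>',
      '<relation entry1="1" entry2="2" type="PPrel">',
      '<subtype name="%s" value="?"/></relation></pathway>'), sub), f)
    pathwayToBoolean(parseKGML(f))
  }
  # activation -> +1 into a MAJ node
  net <- mk("activation")
  expect_equal(edgeTable(net), data.frame(from = "1", to = "2", sign = 1L))
  expect_true(all(nodeTable(net)$rule == "MAJ"))
  # inhibition -> -1 into a MAJ node
  net <- mk("inhibition")
  expect_equal(edgeTable(net)$sign, -1L)
  # expression behaves like activation
  expect_equal(edgeTable(mk("expression"))$sign, 1L)
  # binding/association -> AND complex fed by both participants
  net <- mk("binding/association")
  nd <- nodeTable(net)
  expect_true("1+2" %in% nd$id)
  expect_equal(nd$rule[nd$id == "1+2"], "AND")
  ed <- edgeTable(net)
  expect_setequal(ed$from[ed$to == "1+2"], c("1", "2"))
  expect_true(all(ed$sign == 1L))
  # dissociation uses the same complex construction
  expect_true("1+2" %in% nodeTable(mk("dissociation"))$id)
  # dropped rows of the vocabulary produce no edge but are counted
  for (sub in c("missing interaction", "remove")) {
    net <- mk(sub)
    expect_equal(numEdges(net), 0)
    expect_equal(unname(attr(net, "conversionLog")[sub]), 1L)
  }
  # out-of-vocabulary subtype skipped and logged
  net <- mk("state change")
  expect_equal(numEdges(net), 0)
  expect_equal(unname(attr(net, "conversionLog")["state change"]), 1L)
})

test_that("conversion never produces a -1 edge into an AND node", {
  f <- withr::local_tempfile(fileext = ".xml")
  # inhibition targeting a group entry must not violate the AND invariant
  writeLines(paste0(
    '<pathway name="p"><entry id="1" name="hsa:1" type="gene"/>',
    '<entry id="2" name="hsa:2" type="gene"/>',
    '<entry id="3" name="hsa:3" type="gene"/>',
    '<entry id="4" name="undefined" type="group">',
    '<component id="1"/><component id="2"/></entry>',
    '<relation entry1="3" entry2="4" type="PPrel">',
    '<subtype name="inhibition" value="?"/></relation></pathway>'), f)
  net <- pathwayToBoolean(parseKGML(f))
  expect_true(validObject(net))
  ed <- edgeTable(net)
  nd <- nodeTable(net)
  and_ids <- nd$id[nd$rule == "AND"]
  expect_false(any(ed$sign == -1 & ed$to %in% and_ids))
  # the inhibition was redirected onto the complex members
  expect_setequal(ed$to[ed$sign == -1], c("1", "2"))
})

test_that("toy KGML exercises the whole vocabulary and round-trips", {
  voc <- kgmlVocabulary()
  expect_equal(nrow(voc), 8)
  pg <- parseKGML(toyKGML())
  expect_setequal(unique(pg@edges$kegg_type),
                  setdiff(voc$kegg_type, "complex"))  # complex = group entry
  net <- pathwayToBoolean(pg)
  expect_gt(numNodes(net), 0)
  f <- withr::local_tempfile(fileext = ".json")
  writeBooleanNetwork(net, f)
  net2 <- readBooleanNetwork(f)
  attr(net, "conversionLog") <- NULL
  expect_equal(net, net2)
})

test_that("network merge unifies ids, collapses edges, resolves rules", {
  n1 <- makeNet(c("A->B"))
  n2 <- makeNet(c("C->D"))
  expect_equal(numNodes(mergeNetworks(list(n1, n2))), 4)
  # same edge twice collapses
  m <- mergeNetworks(list(n1, makeNet(c("A->B"))))
  expect_equal(numEdges(m), 1)
  expect_equal(numNodes(m), 2)
  # rule conflict: complex membership (AND) wins over MAJ regulation
  nMaj <- makeNet(c("A->X"))
  nAnd <- makeNet(c("P->X", "Q->X"), andNodes = "X")
  m <- mergeNetworks(list(nMaj, nAnd))
  nd <- nodeTable(m)
  expect_equal(nd$rule[nd$id == "X"], "AND")
  expect_equal(sum(edgeTable(m)$to == "X"), 3)  # both edge sets retained
})

test_that("merged size is bounded by the input sums, equal iff disjoint", {
  set.seed(11)
  for (rep in 1:5) {
    n1 <- randomBooleanNetwork(8, 0.2)
    n2 <- randomBooleanNetwork(8, 0.2)
    m <- mergeNetworks(list(n1, n2))
    expect_lte(numNodes(m), numNodes(n1) + numNodes(n2))
    expect_lte(numEdges(m), numEdges(n1) + numEdges(n2))
  }
  # disjoint ids: exact sum
  a <- makeNet(c("A->B", "B->C"))
  b <- makeNet(c("X->Y"))
  m <- mergeNetworks(list(a, b))
  expect_equal(numNodes(m), 5)
  expect_equal(numEdges(m), 3)
})

test_that("components partition the network and match union-find", {
  net <- makeNet(c("A->B", "B->C"), nodes = "D")
  comps <- connectedComponents(net)
  expect_equal(lengths(lapply(comps, nodeIds)), c(3, 1))
  expect_equal(nodeIds(largestComponent(net)), c("A", "B", "C"))
  # one fully connected toy
  expect_length(connectedComponents(makeNet(c("A->B", "B->A"))), 1)
  # random fixture vs union-find oracle
  set.seed(5)
  big <- randomBooleanNetwork(50, 0.02)
  comps <- connectedComponents(big)
  got <- lapply(comps, function(cc) sort(nodeIds(cc)))
  want <- unname(lapply(oracleComponents(big), sort))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
  # partition: disjoint and exhaustive, union reconstructs the input
  allIds <- sort(unlist(lapply(comps, nodeIds)))
  expect_equal(allIds, sort(nodeIds(big)))
  expect_equal(sum(vapply(comps, numEdges, 0L)), numEdges(big))
})

test_that("largest-component ties break on the smallest id set", {
  net <- makeNet(c("B->C", "A->Z"))  # two components of size 2
  expect_equal(nodeIds(largestComponent(net)), c("A", "Z"))
  # single node network is its own largest component
  single <- makeNet(nodes = "solo")
  expect_equal(nodeIds(largestComponent(single)), "solo")
  expect_error(largestComponent(booleanNetwork(character())), "empty")
})
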