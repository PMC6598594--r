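#' KEGG interaction vocabulary and its Boolean mapping
#'
#' The correspondence between KEGG relation subtypes and the Boolean update
#' operations used when converting a pathway to a [BooleanNetwork-class]:
#' activation and expression become +1 inputs of a majority (MAJ) node,
#' inhibition a -1 input of a MAJ node; binding/association, complex
#' (KGML group entries) and dissociation produce an AND node whose inputs are
#' the participants; "missing interaction" and "remove" are deliberately
#' dropped. Any subtype not listed here is recorded as unmapped and skipped.
#'
#' @return data.frame with columns \code{kegg_type}, \code{operation}
#'   (\code{"MAJ"}, \code{"AND"} or \code{"drop"}) and \code{sign}.
#' @export
kgmlVocabulary <- function() {
  data.frame(
    kegg_type = c("activation", "binding/association", "complex",
                  "dissociation", "expression", "inhibition",
                  "missing interaction", "remove"),
    operation = c("MAJ", "AND", "AND", "AND", "MAJ", "MAJ", "drop", "drop"),
    sign = c(1L, 1L, 1L, 1L, 1L, -1L, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE)
}

## strip the organism prefix from a KEGG name token: "hsa:5594" -> "5594"
.keggToken <- function(x) sub("^[a-zA-Z]+:", "", x)

#' Parse a KGML pathway document
#'
#' Reads a KEGG Markup Language file into a [PathwayGraph-class]. Gene-like
#' entries become \code{gene} nodes (all identifiers in the entry name are
#' kept; the organism prefix is stripped); \code{group} entries become
#' \code{complex} nodes holding the union of their components' identifiers.
#' Every relation is captured, one edge per subtype, with the subtype name
#' preserved verbatim -- including subtypes outside the conversion vocabulary,
#' which are flagged later rather than silently dropped.
#'
#' @param path Path to a KGML XML file (or anything [xml2::read_xml()]
#'   accepts).
#' @return A [PathwayGraph-class].
#' @export
parseKGML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed KGML document: ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document: missing <pathway> root")
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- "unnamed"

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  genes <- lapply(seq_along(entries), function(i) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "component"), "id")
      unique(unlist(lapply(comp, function(cid) {
        e <- entries[match(cid, entry_id)]
        if (length(e) == 0 || is.na(match(cid, entry_id)))
          stop("group component references unknown entry '", cid, "'")
        .keggToken(strsplit(xml2::xml_attr(e[[1]], "name"), "\\s+")[[1]])
      })))
    } else {
      .keggToken(strsplit(xml2::xml_attr(entries[[i]], "name"), "\\s+")[[1]])
    }
  })
  nodes <- data.frame(entry_id = entry_id,
                      node_class = ifelse(entry_type == "group", "complex", "gene"),
                      stringsAsFactors = FALSE)
  nodes$genes <- genes

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  edge_list <- lapply(rels, function(r) {
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "subtype"), "name")
    if (length(subs) == 0) subs <- NA_character_
    data.frame(from = xml2::xml_attr(r, "entry1"),
               to = xml2::xml_attr(r, "entry2"),
               kegg_type = subs, stringsAsFactors = FALSE)
  })
  edges <- if (length(edge_list)) do.call(rbind, edge_list) else
    data.frame(from = character(), to = character(), kegg_type = character(),
               stringsAsFactors = FALSE)
  missing <- setdiff(c(edges$from, edges$to), nodes$entry_id)
  if (length(missing))
    stop("relation references entries absent from the document: ",
         paste(missing, collapse = ", "))
  new("PathwayGraph", pathwayId = pid, nodes = nodes, edges = edges)
}

## stable identifier for an entry: first gene id for genes, sorted joined
## member set for complexes (so the same complex merges across pathways)
.entryStableId <- function(pg) {
  vapply(seq_len(nrow(pg@nodes)), function(i) {
    g <- pg@nodes$genes[[i]]
    if (pg@nodes$node_class[i] == "complex")
      paste(sort(g), collapse = "+")
    else g[1]
  }, "")
}

#' Convert a parsed pathway to a Boolean network
#'
#' Applies the [kgmlVocabulary()] mapping: activation/expression relations
#' become +1 edges into MAJ nodes, inhibition a -1 edge; binding/association
#' and dissociation relations materialize a complex node (rule AND, id =
#' sorted member identifiers joined by \code{"+"}) with +1 edges from both
#' participants; KGML group entries likewise become AND nodes fed by their
#' members. Regulatory (MAJ-type) relations that target a complex node are
#' redirected onto its member nodes, so AND nodes only ever receive +1
#' component edges. "Missing interaction", "remove" and any unmapped subtype
#' are skipped; their counts are attached to the result as the
#' \code{"conversionLog"} attribute.
#'
#' @param pg A [PathwayGraph-class].
#' @return A [BooleanNetwork-class] with a \code{conversionLog} attribute
#'   (named counts of skipped/unmapped relation subtypes).
#' @export
pathwayToBoolean <- function(pg) {
  validObject(pg)
  voc <- kgmlVocabulary()
  sid <- .entryStableId(pg)
  names(sid) <- pg@nodes$entry_id
  is_complex <- pg@nodes$node_class == "complex"
  names(is_complex) <- pg@nodes$entry_id
  label <- vapply(pg@nodes$genes, paste, "", collapse = "+")

  nodes <- data.frame(id = sid, rule = ifelse(is_complex, "AND", "MAJ"),
                      label = label, stringsAsFactors = FALSE)
  members <- list()  # complex id -> member stable ids
  for (i in which(is_complex))
    members[[sid[i]]] <- sort(pg@nodes$genes[[i]])

  edges <- list()
  skipped <- integer()
  addEdge <- function(from, to, sign)
    edges[[length(edges) + 1L]] <<- data.frame(from = from, to = to,
                                               sign = sign, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pg@edges))) {
    ty <- pg@edges$kegg_type[i]
    src <- sid[[pg@edges$from[i]]]
    dst <- sid[[pg@edges$to[i]]]
    row <- match(ty, voc$kegg_type)
    if (is.na(row) || voc$operation[row] == "drop") {
      key <- if (is.na(ty)) "(no subtype)" else ty
      skipped[key] <- (if (key %in% names(skipped)) skipped[key] else 0L) + 1L
      next
    }
    if (voc$operation[row] == "MAJ") {
      ## redirect regulation of a complex onto its members (keeps AND pure)
      targets <- if (dst %in% names(members)) members[[dst]] else dst
      for (tg in targets) addEdge(src, tg, voc$sign[row])
    } else {
      ## binding/association or dissociation: materialize the complex
      cid <- paste(sort(c(src, dst)), collapse = "+")
      nodes <- rbind(nodes, data.frame(id = cid, rule = "AND", label = cid,
                                       stringsAsFactors = FALSE))
      addEdge(src, cid, 1L)
      addEdge(dst, cid, 1L)
    }
  }
  ## component edges of group entries
  for (cid in names(members))
    for (m in members[[cid]]) {
      if (!m %in% nodes$id)
        nodes <- rbind(nodes, data.frame(id = m, rule = "MAJ", label = m,
                                         stringsAsFactors = FALSE))
      addEdge(m, cid, 1L)
    }
  ## first occurrence wins; complexes are added before plain member rows
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  net <- booleanNetwork(nodes, if (length(edges)) do.call(rbind, edges))
  attr(net, "conversionLog") <- skipped
  net
}
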