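#' Directed metabolic pathway graph
#'
#' A small directed acyclic graph of metabolites: nodes carry an optional
#' molecular formula and an optional panel id (linking the node to a
#' quantified metabolite); edges are labelled reactions flagged
#' `established` or `proposed`. Proposed edges must carry a reaction label
#' derivable from the parent/child mass delta (see [proposeStep()]).
#'
#' @slot nodes `data.frame` with columns `node`, `formula`, `panel_id`.
#' @slot edges `data.frame` with columns `parent`, `child`, `label`,
#'   `status`.
#' @export
setClass("PathwayGraph", representation(nodes = "data.frame",
                                        edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
  ed <- object@edges
  nd <- object@nodes
  if (!all(c("parent", "child", "label", "status") %in% names(ed)))
    return("edges need parent, child, label, status columns")
  if (!all(c("node", "formula", "panel_id") %in% names(nd)))
    return("nodes need node, formula, panel_id columns")
  if (!all(c(ed$parent, ed$child) %in% nd$node))
    return("edge endpoints must be declared nodes")
  if (!all(ed$status %in% c("established", "proposed")))
    return("edge status must be 'established' or 'proposed'")
  if (any(ed$status == "proposed" & !nzchar(ed$label)))
    return("proposed edges must carry a reaction label")
  g <- igraph::graph_from_data_frame(ed[c("parent", "child")],
                                     vertices = nd$node)
  if (!igraph::is_dag(g)) return("pathway graph must be acyclic")
  TRUE
})

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (",
      sum(object@edges$status == "proposed"), "proposed )\n")
})

#' @describeIn PathwayGraph-class node table accessor
#' @param x A `PathwayGraph`.
#' @export
pathwayNodes <- function(x) x@nodes

#' @describeIn PathwayGraph-class edge table accessor
#' @export
pathwayEdges <- function(x) x@edges

.igraphOf <- function(graph) {
  igraph::graph_from_data_frame(graph@edges[c("parent", "child")],
                                vertices = graph@nodes$node)
}

#' Read a pathway graph from edge/node tables
#'
#' @param edges Path to a delimited edge list (`parent`, `child`, `label`,
#'   `status`).
#' @param nodes Path to a delimited node table (`node`, optional `formula`,
#'   optional `panel_id`).
#' @return A [PathwayGraph-class].
#' @export
readPathwayGraph <- function(edges, nodes) {
  for (p in c(edges, nodes))
    if (!file.exists(p)) stop("no such file: ", sQuote(p))
  ed <- utils::read.delim(edges, stringsAsFactors = FALSE)
  nd <- utils::read.delim(nodes, stringsAsFactors = FALSE, fill = TRUE)
  for (col in c("formula", "panel_id")) {
    if (!col %in% names(nd)) nd[[col]] <- ""
    nd[[col]][is.na(nd[[col]])] <- ""
  }
  new("PathwayGraph", nodes = nd, edges = ed)
}

#' Packaged defense-metabolite pathway graphs
#'
#' `benzoxazinoidPathway()` returns the benzoxazinoid biosynthesis graph:
#' the core BX enzymatic route (indole to DIMBOA-glucoside, enzyme names as
#' edge labels only) plus the eight detected glycosides, with the
#' single-step glycosylation/acetylation extensions flagged as proposed.
#' `flavonoidPathway()` returns the flavonoid route at subclass resolution
#' (naringenin through apigenin/luteolin/tricetin/tricin/trimethoxytricetin,
#' the flavonol and anthocyanin branches, and generic O-/C-glycoside
#' extensions).
#'
#' @return A [PathwayGraph-class].
#' @export
benzoxazinoidPathway <- function() {
  readPathwayGraph(
    system.file("extdata", "benzoxazinoid_pathway_edges.tsv",
                package = "cerealmet", mustWork = TRUE),
    system.file("extdata", "benzoxazinoid_pathway_nodes.tsv",
                package = "cerealmet", mustWork = TRUE))
}

#' @rdname benzoxazinoidPathway
#' @export
flavonoidPathway <- function() {
  readPathwayGraph(
    system.file("extdata", "flavonoid_pathway_edges.tsv",
                package = "cerealmet", mustWork = TRUE),
    system.file("extdata", "flavonoid_pathway_nodes.tsv",
                package = "cerealmet", mustWork = TRUE))
}

#' Default single-step modification delta catalog
#'
#' Named list of molecular-formula deltas for common single-enzyme
#' modifications: hexosylation (+C6H10O5), pentosylation (+C5H8O4),
#' rhamnosylation (+C6H10O4), acetylation (+C2H2O), methylation (+CH2) and
#' hydroxylation (+O). Hexose and rhamnose (deoxyhexose) additions are
#' distinguished by their exact elemental delta.
#'
#' @return Named list of [MolecularFormula-class] objects.
#' @export
deltaCatalog <- function() {
  lapply(c(hexosylation = "C6H10O5", pentosylation = "C5H8O4",
           rhamnosylation = "C6H10O4", acetylation = "C2H2O",
           methylation = "CH2", hydroxylation = "O"), parseFormula)
}

#' Infer a single-step modification reaction from a mass delta
#'
#' If the elemental difference child minus parent equals exactly one
#' catalog delta, the corresponding reaction label is returned; otherwise
#' `NA` (including when the difference has negative element counts — the
#' deltas are additions, so a proposed label in one direction implies none
#' in the reverse).
#'
#' @param parent,child Molecular formulas ([MolecularFormula-class] or
#'   strings).
#' @param catalog Named list of formula deltas (default [deltaCatalog()]).
#' @return Reaction label, or `NA_character_` if no catalog delta matches.
#' @export
proposeStep <- function(parent, child, catalog = deltaCatalog()) {
  if (is.character(parent)) parent <- parseFormula(parent)
  if (is.character(child)) child <- parseFormula(child)
  delta <- tryCatch(child - parent, error = function(e) NULL)
  if (is.null(delta)) return(NA_character_)
  for (nm in names(catalog))
    if (identical(delta@counts, catalog[[nm]]@counts)) return(nm)
  NA_character_
}

#' Re-derive proposed edges of a graph from node formulas
#'
#' Checks that every `proposed` edge's label is reproduced by
#' [proposeStep()] on the parent/child formulas.
#'
#' @param graph A [PathwayGraph-class].
#' @param catalog Delta catalog.
#' @return `TRUE`, or an error naming the first irreproducible edge.
#' @export
validateProposedEdges <- function(graph, catalog = deltaCatalog()) {
  nd <- pathwayNodes(graph)
  forms <- stats::setNames(nd$formula, nd$node)
  ed <- pathwayEdges(graph)
  for (i in which(ed$status == "proposed")) {
    pf <- forms[[ed$parent[i]]]; cf <- forms[[ed$child[i]]]
    if (!nzchar(pf) || !nzchar(cf))
      stop("proposed edge ", ed$parent[i], " -> ", ed$child[i],
           " lacks node formulas")
    lbl <- proposeStep(pf, cf, catalog)
    if (is.na(lbl) || lbl != ed$label[i])
      stop("proposed edge ", ed$parent[i], " -> ", ed$child[i],
           " label ", sQuote(ed$label[i]),
           " not reproduced by the delta catalog (got ", lbl, ")")
  }
  TRUE
}

#' Nodes reachable downstream of a metabolite
#'
#' All nodes reachable by directed edges from `node`, with the minimum
#' number of reaction steps to each.
#'
#' @param graph A [PathwayGraph-class].
#' @param node Node name.
#' @return `data.frame` with columns `node`, `steps`, sorted by steps then
#'   name; zero rows for a leaf.
#' @export
downstreamOf <- function(graph, node) {
  if (!node %in% pathwayNodes(graph)$node)
    stop("unknown node: ", sQuote(node))
  g <- .igraphOf(graph)
  d <- igraph::distances(g, v = node, mode = "out")[1, ]
  d <- d[is.finite(d) & d > 0]
  out <- data.frame(node = names(d), steps = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$steps, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map panel abundances onto pathway nodes
#'
#' Joins quantified pathway nodes (via their `panel_id`, or an explicit
#' mapping) to the panel and summarizes per-species abundance, reporting
#' the species attaining the maximum (ties reported together,
#' `+`-separated).
#'
#' @param graph A [PathwayGraph-class].
#' @param panel A [PanelMatrix-class].
#' @param idMap Optional named character vector node -> panel id;
#'   defaults to the graph's `panel_id` column.
#' @return `data.frame` with columns `node`, `panel_id`, one abundance
#'   column per species, and `max_species`; attribute `"unmapped"` lists
#'   quantifiable nodes without a panel match.
#' @export
mapAbundance <- function(graph, panel, idMap = NULL) {
  nd <- pathwayNodes(graph)
  if (is.null(idMap)) {
    idMap <- stats::setNames(nd$panel_id, nd$node)
    idMap <- idMap[nzchar(idMap)]
  }
  ab <- abundances(panel)
  mapped <- names(idMap)[idMap %in% rownames(ab)]
  unmapped <- setdiff(names(idMap), mapped)
  if (length(unmapped))
    message("mapAbundance: ", length(unmapped), " node(s) not on the panel")
  rows <- lapply(mapped, function(nm) {
    a <- ab[idMap[[nm]], ]
    top <- paste(colnames(ab)[a == max(a)], collapse = "+")
    cbind(data.frame(node = nm, panel_id = idMap[[nm]],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(a), check.names = FALSE),
          data.frame(max_species = top, stringsAsFactors = FALSE))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(0), panel_id = character(0),
               max_species = character(0))
  attr(out, "unmapped") <- unmapped
  out
}
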