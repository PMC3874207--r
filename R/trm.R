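## internal: loop-free traversal copy of a PPI graph
.traversalGraph <- function(g) {
    igraph::delete_edges(g, igraph::E(g)[igraph::which_loop(g)])
}

.allShortestPaths <- function(g, from, to) {
    res <- igraph::all_shortest_paths(g, from = from, to = to)
    paths <- res$vpaths %||% res$res
    lapply(paths, function(p) igraph::as_ids(p))
}

#' All shortest paths between two proteins
#'
#' Returns every minimal-length path between \code{u} and \code{v} as a
#' node sequence including both endpoints, so directly connected proteins
#' yield paths of exactly two nodes (network distance 1). Self-loops are
#' never traversed. A disconnected pair yields an empty list.
#'
#' @param graph a [PPIGraph-class].
#' @param u,v gene ids; must be present in the graph.
#' @return list of character vectors (node paths).
#' @export
shortestPathNodes <- function(graph, u, v) {
    stopifnot(is(graph, "PPIGraph"))
    g <- .traversalGraph(graph@graph)
    vn <- igraph::V(g)$name
    if (!(u %in% vn) || !(v %in% vn))
        stop("node(s) absent from graph: ",
             paste(setdiff(c(u, v), vn), collapse = ", "), call. = FALSE)
    if (u == v) return(list(u))
    d <- igraph::distances(g, v = u, to = v)[1, 1]
    if (!is.finite(d)) return(list())
    suppressWarnings(.allShortestPaths(g, u, v))
}

.emptyModule <- function(targets, queries) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = character())
    new("TRModule", graph = g, roles = setNames(character(), character()),
        targets = targets, queries = queries, isEmpty = TRUE)
}

#' Reconstruct a transcriptional regulatory module
#'
#' Local search around the target TF(s) on the expression-restricted PPI
#' network. For every (target, query) pair whose shortest-path distance is
#' at most \code{maxBridge + 1} edges (i.e. at most \code{maxBridge + 2}
#' nodes on the path; the default \code{maxBridge = 1} admits paths of at
#' most three nodes, allowing one bridge protein), all shortest paths are
#' computed and their nodes pooled. The module is the PPI subgraph induced
#' on that node pool, so query-query and bridge-bridge interactions
#' present in the network are retained. Node roles are assigned with
#' precedence target > enriched > bridge.
#'
#' Only minimal-length paths per pair contribute; longer detours that
#' would still fit the bound are not included. Targets or queries absent
#' from the PPI network are dropped with a warning; if no admissible pair
#' remains the result is a valid empty module with \code{isEmpty = TRUE}
#' (a real outcome for some target TFs), never an error.
#'
#' @param graph a [PPIGraph-class] (normally expression-restricted).
#' @param targets gene id(s) of the ChIP-seq-profiled target TF(s).
#' @param queries candidate (motif-enriched, expressed) TF gene ids;
#'   genes listed in both sets are treated as targets.
#' @param maxBridge maximum number of bridge proteins on a path (>= 0).
#' @param includeNeighbors also keep direct PPI neighbors of the target
#'   TFs that sit on no admissible path (a looser, neighborhood-centric
#'   variant; default FALSE keeps the strict path-based rule).
#' @param targetPairs also connect target pairs to each other (default
#'   TRUE; both endpoints are TFs of interest).
#' @return a [TRModule-class].
#' @examples
#' rec <- data.frame(gene_a = c("T", "B", "T", "Q"),
#'                   gene_b = c("B", "Q", "X", "Y"),
#'                   system_type = "physical", source_line = 1:4)
#' g <- buildPPIGraph(rec)
#' findTRM(g, targets = "T", queries = "Q")
#' @export
findTRM <- function(graph, targets, queries, maxBridge = 1,
                    includeNeighbors = FALSE, targetPairs = TRUE) {
    stopifnot(is(graph, "PPIGraph"))
    if (!is.numeric(maxBridge) || length(maxBridge) != 1L || maxBridge < 0)
        stop("maxBridge must be >= 0", call. = FALSE)
    targets <- unique(as.character(targets))
    queries <- setdiff(unique(as.character(queries)), targets)
    g0 <- graph@graph
    g <- .traversalGraph(g0)
    vn <- igraph::V(g)$name

    absent <- setdiff(c(targets, queries), vn)
    if (length(absent))
        warning("not found in the PPI network: ",
                paste(absent, collapse = ", "), call. = FALSE)
    presentT <- intersect(targets, vn)
    presentQ <- intersect(queries, vn)
    if (!length(presentT)) {
        warning("no target present in the PPI network; ",
                "a TRM could not be built", call. = FALSE)
        return(.emptyModule(targets, queries))
    }

    maxEdges <- maxBridge + 1
    nodes <- character()
    for (t in presentT) {
        others <- presentQ
        if (targetPairs) others <- union(others, setdiff(presentT, t))
        if (!length(others)) next
        d <- igraph::distances(g, v = t, to = others)[1, ]
        adm <- others[is.finite(d) & d >= 1 & d <= maxEdges]
        if (!length(adm)) next
        paths <- suppressWarnings(.allShortestPaths(g, t, adm))
        keep <- vapply(paths, function(p)
            length(p) >= 2 && length(p) <= maxEdges + 1, logical(1))
        nodes <- union(nodes, unlist(paths[keep], use.names = FALSE))
    }

    if (includeNeighbors && length(nodes)) {
        nb <- unique(unlist(lapply(presentT, function(t)
            igraph::as_ids(igraph::neighbors(g, t))), use.names = FALSE))
        nodes <- union(nodes, nb)
    }

    if (!length(nodes)) return(.emptyModule(targets, queries))

    sub <- igraph::induced_subgraph(g0, nodes)
    vnames <- igraph::V(sub)$name
    roles <- setNames(rep("bridge", length(vnames)), vnames)
    roles[vnames %in% queries] <- "enriched"
    roles[vnames %in% targets] <- "target"
    new("TRModule", graph = sub, roles = roles, targets = targets,
        queries = queries, isEmpty = FALSE)
}

#' Summary statistics for a reconstructed module
#'
#' Node counts by role and the recovered-target fraction: how many of a
#' designated set of TFs (e.g. every TF profiled in the study) ended up in
#' this module.
#'
#' @param module a [TRModule-class].
#' @param allTargets character vector of designated TF gene ids.
#' @return list: n_nodes, n_edges, role counts, recovered_targets,
#'   recovered_fraction (NA when \code{allTargets} is empty).
#' @export
moduleStats <- function(module, allTargets = character()) {
    stopifnot(is(module, "TRModule"))
    roles <- moduleRoles(module)
    tab <- table(factor(roles, levels = c("target", "enriched", "bridge")))
    rec <- intersect(nodeNames(module), allTargets)
    frac <- if (length(allTargets)) length(rec) / length(allTargets)
            else NA_real_
    list(n_nodes = igraph::vcount(module@graph),
         n_edges = igraph::ecount(module@graph),
         n_target = as.integer(tab[["target"]]),
         n_enriched = as.integer(tab[["enriched"]]),
         n_bridge = as.integer(tab[["bridge"]]),
         recovered_targets = rec,
         recovered_fraction = frac)
}

#' Combine single-target modules into one unified module
#'
#' Union graph across member modules, with \code{freq} node and edge
#' attributes counting in how many members each node/edge appears (the
#' usual basis for scaling node and edge sizes when plotting a combined
#' module). Roles are merged with precedence target > enriched > bridge.
#'
#' @param modules list of [TRModule-class] objects (>= 1; empty members
#'   are allowed and contribute nothing).
#' @return a [CombinedTRM-class].
#' @export
combineTRMs <- function(modules) {
    if (!length(modules)) stop("no modules to combine", call. = FALSE)
    stopifnot(all(vapply(modules, is, logical(1), "TRModule")))
    nodeCount <- list()
    roleBest <- list()
    edgeCount <- list()
    edgeMult <- list()
    prec <- c(target = 3, enriched = 2, bridge = 1)
    for (m in modules) {
        roles <- moduleRoles(m)
        for (v in names(roles)) {
            nodeCount[[v]] <- (nodeCount[[v]] %||% 0L) + 1L
            if (is.null(roleBest[[v]]) ||
                prec[[roles[[v]]]] > prec[[roleBest[[v]]]])
                roleBest[[v]] <- roles[[v]]
        }
        et <- edgeTable(m)
        for (i in seq_len(nrow(et))) {
            k <- .edgeKey(et$gene_a[i], et$gene_b[i])
            edgeCount[[k]] <- (edgeCount[[k]] %||% 0L) + 1L
            edgeMult[[k]] <- max(edgeMult[[k]] %||% 0L, et$multiplicity[i])
        }
    }
    nodes <- sort(names(nodeCount))
    keys <- sort(names(edgeCount))
    if (!length(nodes)) {
        g <- igraph::make_empty_graph(0, directed = FALSE)
        g <- igraph::set_vertex_attr(g, "name", value = character())
        return(new("CombinedTRM", graph = g,
                   roles = setNames(character(), character()),
                   nModules = length(modules)))
    }
    if (length(keys)) {
        parts <- strsplit(keys, "|", fixed = TRUE)
        edf <- data.frame(
            from = vapply(parts, `[`, character(1), 1L),
            to = vapply(parts, `[`, character(1), 2L),
            freq = as.integer(unlist(edgeCount[keys])),
            multiplicity = as.integer(unlist(edgeMult[keys])),
            stringsAsFactors = FALSE)
        g <- igraph::graph_from_data_frame(edf, directed = FALSE,
            vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    } else {
        g <- igraph::make_empty_graph(0, directed = FALSE) +
            igraph::vertices(nodes)
    }
    g <- igraph::set_vertex_attr(g, "freq",
        value = as.integer(unlist(nodeCount[igraph::V(g)$name])))
    new("CombinedTRM", graph = g,
        roles = setNames(unlist(roleBest[nodes]), nodes),
        nModules = length(modules))
}
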