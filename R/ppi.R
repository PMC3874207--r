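#' Read protein-protein interaction records (BioGRID TAB-style TSV)
#'
#' Column names are configurable and default to the BioGRID TAB3 headers.
#' When an organism filter is given, a row is kept only when both
#' interactors belong to that organism. Rows with an empty interactor id
#' are dropped with a warning.
#'
#' @param path TSV path.
#' @param organism optional organism id; both interactors must match.
#' @param colA,colB interactor gene id columns (Entrez or symbol column,
#'   per the caller's choice of gene identity).
#' @param colSystem experimental system type column
#'   (\code{physical} / \code{genetic}).
#' @param colOrgA,colOrgB organism id columns.
#' @return data.frame: gene_a, gene_b, system_type, source_line.
#' @export
readInteractions <- function(path, organism = NULL,
                             colA = "Entrez Gene Interactor A",
                             colB = "Entrez Gene Interactor B",
                             colSystem = "Experimental System Type",
                             colOrgA = "Organism ID Interactor A",
                             colOrgB = "Organism ID Interactor B") {
    tab <- .readTsv(path)
    need <- c(colA, colB, colSystem)
    if (!is.null(organism)) need <- c(need, colOrgA, colOrgB)
    if (!all(need %in% names(tab)))
        stop(path, ": missing column(s) ",
             paste(setdiff(need, names(tab)), collapse = ", "),
             call. = FALSE)
    rec <- data.frame(gene_a = as.character(tab[[colA]]),
                      gene_b = as.character(tab[[colB]]),
                      system_type = tolower(as.character(tab[[colSystem]])),
                      source_line = seq_len(nrow(tab)),
                      stringsAsFactors = FALSE)
    if (!is.null(organism)) {
        keep <- as.character(tab[[colOrgA]]) == as.character(organism) &
            as.character(tab[[colOrgB]]) == as.character(organism)
        rec <- rec[keep, , drop = FALSE]
    }
    empty <- !nzchar(rec$gene_a) | !nzchar(rec$gene_b) |
        is.na(rec$gene_a) | is.na(rec$gene_b) | rec$gene_a == "-" |
        rec$gene_b == "-"
    if (any(empty)) {
        warning(path, ": dropped ", sum(empty),
                " record(s) with empty interactor id", call. = FALSE)
        rec <- rec[!empty, , drop = FALSE]
    }
    rownames(rec) <- NULL
    rec
}

#' Keep only physical interactions
#'
#' Genetic interactions are removed; unknown system-type labels are
#' dropped as well (conservatively), with a warning.
#'
#' @param records interaction records from [readInteractions()].
#' @return filtered records.
#' @export
filterPhysical <- function(records) {
    known <- records$system_type %in% c("physical", "genetic")
    if (any(!known))
        warning("dropped ", sum(!known),
                " record(s) with unknown system type", call. = FALSE)
    out <- records[known & records$system_type == "physical", ,
                   drop = FALSE]
    if (!nrow(out))
        warning("no physical interactions remain", call. = FALSE)
    rownames(out) <- NULL
    out
}

#' Remove records touching excluded proteins
#'
#' By default removes the ubiquitination and sumoylation moieties (Ubc,
#' Sumo1, Sumo2, Sumo3), which connect promiscuously and would otherwise
#' short-circuit path searches.
#'
#' @param records interaction records.
#' @param excluded character vector of gene ids/symbols to drop.
#' @return filtered records.
#' @export
removeExcludedNodes <- function(records,
                                excluded = c("Ubc", "Sumo1", "Sumo2",
                                             "Sumo3")) {
    keep <- !(records$gene_a %in% excluded | records$gene_b %in% excluded)
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Collapse interaction records into a simple undirected PPI graph
#'
#' Records for the same unordered protein pair (A-B and B-A alike) are
#' collapsed to a single edge whose \code{multiplicity} attribute records
#' the original number of supporting records. Self-records (A-A) are
#' stored as flagged self-loop edges but never traversed by the module
#' search.
#'
#' @param records interaction records (normally already physical-filtered).
#' @return a [PPIGraph-class].
#' @export
buildPPIGraph <- function(records) {
    if (!nrow(records)) {
        g <- igraph::make_empty_graph(0, directed = FALSE)
        g <- igraph::set_vertex_attr(g, "name", value = character())
        return(new("PPIGraph", graph = g))
    }
    key <- .edgeKey(records$gene_a, records$gene_b)
    mult <- table(key)
    parts <- strsplit(names(mult), "|", fixed = TRUE)
    a <- vapply(parts, `[`, character(1), 1L)
    b <- vapply(parts, `[`, character(1), 2L)
    g <- igraph::graph_from_data_frame(
        data.frame(from = a, to = b,
                   multiplicity = as.integer(mult),
                   is_loop = a == b, stringsAsFactors = FALSE),
        directed = FALSE)
    new("PPIGraph", graph = g)
}

#' Restrict a PPI graph to expressed genes
#'
#' Induced subgraph on the nodes whose genes are expressed in the cell
#' type under study; edge multiplicities are preserved. Idempotent.
#'
#' @param graph a [PPIGraph-class].
#' @param expressed character vector of expressed gene ids.
#' @return a [PPIGraph-class].
#' @export
restrictToExpressed <- function(graph, expressed) {
    stopifnot(is(graph, "PPIGraph"))
    g <- graph@graph
    keep <- intersect(igraph::V(g)$name, expressed)
    new("PPIGraph",
        graph = igraph::induced_subgraph(g, keep))
}

#' Export a PPI graph or module graph
#'
#' Writes an edge-list TSV (gene_a, gene_b, multiplicity) and, when
#' \code{graphml} is given, a GraphML file with all attributes.
#'
#' @param x a [PPIGraph-class], [TRModule-class] or [CombinedTRM-class].
#' @param path edge-list TSV path.
#' @param graphml optional GraphML path.
#' @return \code{path}, invisibly.
#' @export
writeGraph <- function(x, path, graphml = NULL) {
    et <- edgeTable(x)
    write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(graphml))
        igraph::write_graph(ppiGraph(x), graphml, format = "graphml")
    invisible(path)
}
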