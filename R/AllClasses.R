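#' PWMCollection: a library of position weight matrices
#'
#' Holds position weight matrices (PWMs) from one or more motif databases.
#' Each matrix is a 4 x L numeric matrix of nonnegative counts or
#' frequencies with rows fixed in A, C, G, T order; columns are positions.
#' Matrices are stored exactly as read: no pseudocounts are added because
#' the package never scans sequence, it only resolves motifs to genes.
#'
#' @slot matrices named list of 4 x L numeric matrices, keyed by motif id.
#' @slot info data.frame with one row per motif: \code{motif_id},
#'   \code{source} (one of jaspar, uniprobe, htselex, custom),
#'   \code{species}, \code{width}.
#'
#' @seealso [readPWMCollection()], [mergePWMCollections()], [pwmSummary()]
#' @export
setClass("PWMCollection",
    representation(matrices = "list", info = "data.frame"))

setValidity("PWMCollection", function(object) {
    msgs <- character()
    ids <- names(object@matrices)
    if (length(ids) != nrow(object@info))
        msgs <- c(msgs, "matrices and info disagree in length")
    if (anyDuplicated(ids))
        msgs <- c(msgs, "duplicated motif ids")
    if (nrow(object@info) && !identical(ids, object@info$motif_id))
        msgs <- c(msgs, "info rows not keyed like matrices")
    for (id in ids) {
        m <- object@matrices[[id]]
        if (!is.matrix(m) || nrow(m) != 4L ||
            !identical(rownames(m), c("A", "C", "G", "T")))
            msgs <- c(msgs, sprintf("motif '%s': not a 4-row A,C,G,T matrix", id))
        else if (ncol(m) < 1L || any(m < 0))
            msgs <- c(msgs, sprintf("motif '%s': empty or negative entries", id))
    }
    if (length(msgs)) msgs else TRUE
})

#' CandidateSet: expression-filtered candidate transcription factors
#'
#' The product of the candidate-selection stage for one ChIP-seq library:
#' the genes of TFs whose motifs passed the replicate enrichment consensus,
#' matched the PWM library, mapped to the target species and are expressed
#' in the cell type under study.
#'
#' @slot genes character vector of candidate gene ids.
#' @slot provenance named list mapping each gene to the library motif ids
#'   that supported it.
#' @slot expressionRule label recording the expression cutoff applied.
#' @slot unmatchedMotifs consensus motifs that had no surviving library
#'   match (kept for reporting).
#' @slot species target species label.
#'
#' @seealso [selectCandidates()]
#' @export
setClass("CandidateSet",
    representation(genes = "character", provenance = "list",
                   expressionRule = "character",
                   unmatchedMotifs = "character", species = "character"))

setValidity("CandidateSet", function(object) {
    msgs <- character()
    if (length(object@provenance) &&
        !all(names(object@provenance) %in% object@genes))
        msgs <- c(msgs, "provenance keys must be a subset of genes")
    if (anyDuplicated(object@genes))
        msgs <- c(msgs, "duplicated candidate genes")
    if (length(msgs)) msgs else TRUE
})

#' PPIGraph: an undirected physical protein-protein interaction network
#'
#' Wraps an undirected igraph object in which parallel interaction records
#' have been collapsed to single edges carrying a \code{multiplicity} edge
#' attribute (the number of supporting records). Self-loops (homodimers)
#' are retained and flagged but never traversed by the module search.
#'
#' @slot graph an igraph object (undirected, no parallel edges,
#'   \code{multiplicity} edge attribute).
#'
#' @seealso [buildPPIGraph()], [restrictToExpressed()], [findTRM()]
#' @export
setClass("PPIGraph", representation(graph = "ANY"))

setValidity("PPIGraph", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
    msgs <- character()
    if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
    if (igraph::any_multiple(g)) msgs <- c(msgs, "parallel edges must be collapsed")
    if (is.null(igraph::vertex_attr(g, "name")))
        msgs <- c(msgs, "vertices must be named")
    mult <- igraph::edge_attr(g, "multiplicity")
    if (igraph::ecount(g) > 0 && (is.null(mult) || any(mult < 1)))
        msgs <- c(msgs, "every edge needs multiplicity >= 1")
    if (length(msgs)) msgs else TRUE
})

#' TRModule: a reconstructed transcriptional regulatory module
#'
#' The subgraph of the PPI network induced on all nodes lying on admissible
#' target-query shortest paths, with a role for every node: \code{target}
#' (the immunoprecipitated TF), \code{enriched} (motif-supported query TF)
#' or \code{bridge} (a connector with no motif evidence of its own).
#' An empty module (no admissible path, or targets absent from the PPI
#' network) is a valid result and carries \code{isEmpty = TRUE}.
#'
#' @slot graph igraph subgraph with inherited \code{multiplicity}.
#' @slot roles named character vector over module nodes.
#' @slot targets target gene ids as requested (present or not).
#' @slot queries query gene ids as requested.
#' @slot isEmpty flag for the no-module outcome.
#'
#' @seealso [findTRM()], [moduleStats()], [combineTRMs()]
#' @export
setClass("TRModule",
    representation(graph = "ANY", roles = "character",
                   targets = "character", queries = "character",
                   isEmpty = "logical"))

setValidity("TRModule", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
    msgs <- character()
    vn <- igraph::V(g)$name
    if (!setequal(names(object@roles), vn))
        msgs <- c(msgs, "roles must cover exactly the module nodes")
    if (!all(object@roles %in% c("target", "enriched", "bridge")))
        msgs <- c(msgs, "roles must be target/enriched/bridge")
    if (object@isEmpty && igraph::vcount(g) > 0)
        msgs <- c(msgs, "empty module must have no nodes")
    if (length(msgs)) msgs else TRUE
})

#' CombinedTRM: union of several single-target modules
#'
#' Union graph over member modules, with per-node and per-edge presence
#' counts (how many member modules contain each node/edge) and roles merged
#' under the precedence target > enriched > bridge.
#'
#' @slot graph union igraph with \code{freq} vertex and edge attributes.
#' @slot roles merged role per node.
#' @slot nModules number of member modules.
#'
#' @seealso [combineTRMs()]
#' @export
setClass("CombinedTRM",
    representation(graph = "ANY", roles = "character", nModules = "integer"))

setValidity("CombinedTRM", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
    msgs <- character()
    nf <- igraph::vertex_attr(g, "freq")
    ef <- igraph::edge_attr(g, "freq")
    if (igraph::vcount(g) > 0 &&
        (is.null(nf) || any(nf < 1) || any(nf > object@nModules)))
        msgs <- c(msgs, "node freq must lie in [1, nModules]")
    if (igraph::ecount(g) > 0 &&
        (is.null(ef) || any(ef < 1) || any(ef > object@nModules)))
        msgs <- c(msgs, "edge freq must lie in [1, nModules]")
    if (length(msgs)) msgs else TRUE
})

#' AnnotationTable: term-to-gene annotation sets
#'
#' Gene annotation for enrichment testing, e.g. mouse knockout phenotype
#' terms from the Mouse Genome Database mapped to the genes whose deletion
#' produces them.
#'
#' @slot termGenes named list: term id -> character vector of genes.
#' @slot termNames named character vector: term id -> human-readable name.
#'
#' @seealso [readAnnotationTable()], [enrichTerms()], [countAnnotated()]
#' @export
setClass("AnnotationTable",
    representation(termGenes = "list", termNames = "character"))

setValidity("AnnotationTable", function(object) {
    msgs <- character()
    if (any(lengths(object@termGenes) == 0))
        msgs <- c(msgs, "every term needs at least one gene")
    if (is.null(names(object@termGenes)) || anyDuplicated(names(object@termGenes)))
        msgs <- c(msgs, "terms must be uniquely named")
    if (length(msgs)) msgs else TRUE
})

## ---- accessors ----

#' @describeIn PWMCollection number of motifs
#' @param x object
#' @export
setMethod("nMotifs", "PWMCollection", function(x) length(x@matrices))

#' @describeIn PWMCollection named list of matrices
#' @export
setMethod("pwmMatrices", "PWMCollection", function(x) x@matrices)

#' @describeIn PWMCollection per-motif metadata table
#' @export
setMethod("pwmInfo", "PWMCollection", function(x) x@info)

#' @describeIn PWMCollection motif count per source database
#' @export
setMethod("perSourceCounts", "PWMCollection", function(x) {
    if (!nrow(x@info)) return(integer())
    tab <- table(x@info$source)
    setNames(as.integer(tab), names(tab))
})

#' @describeIn CandidateSet candidate gene ids
#' @param x object
#' @export
setMethod("candidateGenes", "CandidateSet", function(x) x@genes)

#' @describeIn CandidateSet supporting motifs per gene
#' @export
setMethod("provenance", "CandidateSet", function(x) x@provenance)

#' @describeIn PPIGraph underlying igraph object
#' @param x object
#' @export
setMethod("ppiGraph", "PPIGraph", function(x) x@graph)

#' @describeIn TRModule underlying igraph object
#' @export
setMethod("ppiGraph", "TRModule", function(x) x@graph)

#' @describeIn CombinedTRM underlying igraph object
#' @export
setMethod("ppiGraph", "CombinedTRM", function(x) x@graph)

#' @describeIn PPIGraph vertex names
#' @export
setMethod("nodeNames", "PPIGraph", function(x) igraph::V(x@graph)$name)

#' @describeIn TRModule vertex names
#' @export
setMethod("nodeNames", "TRModule", function(x) igraph::V(x@graph)$name)

#' @describeIn CombinedTRM vertex names
#' @export
setMethod("nodeNames", "CombinedTRM", function(x) igraph::V(x@graph)$name)

.edgeTable <- function(g, extra = "multiplicity") {
    if (igraph::ecount(g) == 0) {
        out <- data.frame(gene_a = character(), gene_b = character())
        for (at in extra) out[[at]] <- numeric()
        return(out)
    }
    ends <- igraph::as_edgelist(g)
    a <- pmin(ends[, 1], ends[, 2])
    b <- pmax(ends[, 1], ends[, 2])
    out <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
    for (at in extra) {
        v <- igraph::edge_attr(g, at)
        if (!is.null(v)) out[[at]] <- v
    }
    out
}

#' @describeIn PPIGraph edge list with multiplicities
#' @export
setMethod("edgeTable", "PPIGraph", function(x) .edgeTable(x@graph))

#' @describeIn TRModule edge list with multiplicities
#' @export
setMethod("edgeTable", "TRModule", function(x) .edgeTable(x@graph))

#' @describeIn CombinedTRM edge list with presence counts
#' @export
setMethod("edgeTable", "CombinedTRM",
    function(x) .edgeTable(x@graph, extra = c("freq")))

#' @describeIn PPIGraph multiplicity per edge, named "a|b"
#' @export
setMethod("edgeMultiplicity", "PPIGraph", function(x) {
    et <- .edgeTable(x@graph)
    setNames(et$multiplicity, paste(et$gene_a, et$gene_b, sep = "|"))
})

#' @describeIn TRModule node roles
#' @export
setMethod("moduleRoles", "TRModule", function(x) x@roles)

#' @describeIn CombinedTRM merged node roles
#' @export
setMethod("moduleRoles", "CombinedTRM", function(x) x@roles)

#' @describeIn TRModule requested target genes
#' @export
setMethod("targetGenes", "TRModule", function(x) x@targets)

#' @describeIn TRModule requested query genes
#' @export
setMethod("queryGenes", "TRModule", function(x) x@queries)

#' @describeIn TRModule TRUE when no admissible path produced a module
#' @export
setMethod("isEmptyModule", "TRModule", function(x) x@isEmpty)

#' @describeIn CombinedTRM node presence counts across member modules
#' @export
setMethod("nodeFreq", "CombinedTRM", function(x)
    setNames(igraph::vertex_attr(x@graph, "freq"), igraph::V(x@graph)$name))

#' @describeIn CombinedTRM edge presence counts across member modules
#' @export
setMethod("edgeFreq", "CombinedTRM", function(x) {
    et <- .edgeTable(x@graph, extra = "freq")
    setNames(et$freq, paste(et$gene_a, et$gene_b, sep = "|"))
})

#' @describeIn AnnotationTable term -> genes list
#' @param x object
#' @export
setMethod("termGenes", "AnnotationTable", function(x) x@termGenes)

#' @describeIn AnnotationTable term -> display name
#' @export
setMethod("termNames", "AnnotationTable", function(x) x@termNames)

## ---- show methods ----

setMethod("show", "PWMCollection", function(object) {
    cat("PWMCollection with", nMotifs(object), "motifs\n")
    cnt <- perSourceCounts(object)
    if (length(cnt))
        cat("  sources:",
            paste(sprintf("%s (%d)", names(cnt), cnt), collapse = ", "), "\n")
})

setMethod("show", "CandidateSet", function(object) {
    cat("CandidateSet:", length(object@genes), "candidate TF genes",
        sprintf("[%s]\n", object@species))
    cat("  expression rule:", object@expressionRule, "\n")
    if (length(object@unmatchedMotifs))
        cat("  unmatched consensus motifs:",
            length(object@unmatchedMotifs), "\n")
})

setMethod("show", "PPIGraph", function(object) {
    g <- object@graph
    cat("PPIGraph:", igraph::vcount(g), "proteins,",
        igraph::ecount(g), "interactions\n")
    nl <- sum(igraph::which_loop(g))
    if (nl) cat("  self-loops (flagged, not traversed):", nl, "\n")
})

setMethod("show", "TRModule", function(object) {
    if (object@isEmpty) {
        cat("TRModule: empty (no admissible target-query path)\n")
    } else {
        tab <- table(factor(object@roles,
                            levels = c("target", "enriched", "bridge")))
        cat("TRModule:", igraph::vcount(object@graph), "nodes,",
            igraph::ecount(object@graph), "edges\n")
        cat(sprintf("  roles: %d target, %d enriched, %d bridge\n",
                    tab["target"], tab["enriched"], tab["bridge"]))
    }
})

setMethod("show", "CombinedTRM", function(object) {
    cat("CombinedTRM over", object@nModules, "modules:",
        igraph::vcount(object@graph), "nodes,",
        igraph::ecount(object@graph), "edges\n")
})

setMethod("show", "AnnotationTable", function(object) {
    cat("AnnotationTable:", length(object@termGenes), "terms,",
        length(unique(unlist(object@termGenes))), "distinct genes\n")
})
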