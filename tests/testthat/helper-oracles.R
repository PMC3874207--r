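# independent oracles, deliberately built without the package's own
# search code or igraph path routines

# adjacency list from a PPIGraph's edge table (self-loops excluded)
.oracleAdj <- function(graph) {
    et <- edgeTable(graph)
    et <- et[et$gene_a != et$gene_b, , drop = FALSE]
    nodes <- nodeNames(graph)
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (i in seq_len(nrow(et))) {
        a <- et$gene_a[i]; b <- et$gene_b[i]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    adj
}

# all simple paths from u to v with at most maxEdges edges (DFS)
.simplePaths <- function(adj, u, v, maxEdges) {
    out <- list()
    walk <- function(path) {
        last <- path[length(path)]
        if (last == v && length(path) > 1) {
            out[[length(out) + 1L]] <<- path
            return()
        }
        if (length(path) - 1L >= maxEdges) return()
        for (nb in adj[[last]])
            if (!(nb %in% path)) walk(c(path, nb))
    }
    if (u %in% names(adj) && v %in% names(adj) && u != v) walk(u)
    out
}

# brute-force module oracle: per target-query pair enumerate simple paths
# of <= maxBridge+1 edges, keep only minimal-length ones, union nodes,
# induce the subgraph
bruteTRM <- function(graph, targets, queries, maxBridge,
                     targetPairs = TRUE) {
    adj <- .oracleAdj(graph)
    vn <- names(adj)
    targets <- unique(targets); queries <- setdiff(unique(queries), targets)
    pT <- intersect(targets, vn); pQ <- intersect(queries, vn)
    nodes <- character()
    pairs <- list()
    for (t in pT) {
        others <- pQ
        if (targetPairs) others <- union(others, setdiff(pT, t))
        for (q in others) pairs[[length(pairs) + 1L]] <- c(t, q)
    }
    for (p in pairs) {
        paths <- .simplePaths(adj, p[1], p[2], maxBridge + 1)
        if (!length(paths)) next
        lens <- lengths(paths)
        nodes <- union(nodes,
                       unlist(paths[lens == min(lens)], use.names = FALSE))
    }
    et <- edgeTable(graph)
    keep <- et$gene_a %in% nodes & et$gene_b %in% nodes &
        et$gene_a != et$gene_b
    list(nodes = sort(nodes),
         edges = sort(unique(paste(pmin(et$gene_a[keep], et$gene_b[keep]),
                                   pmax(et$gene_a[keep], et$gene_b[keep]),
                                   sep = "|"))))
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# counts size-n subsets of a universe of N (K annotated) with overlap >= k
enumHyperUpper <- function(k, K, n, N) {
    if (n == 0) return(as.numeric(k == 0))
    annotated <- seq_len(N) <= K
    combos <- utils::combn(N, n)
    hits <- colSums(matrix(annotated[combos], nrow = n)) >= k
    sum(hits) / ncol(combos)
}

# naive complete-linkage agglomerator returning the cophenetic matrix
naiveCompleteLinkage <- function(D) {
    labs <- rownames(D)
    clusters <- as.list(labs)
    coph <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
    while (length(clusters) > 1) {
        best <- c(Inf, NA, NA)
        for (i in seq_along(clusters)) {
            for (j in seq_along(clusters)) {
                if (j <= i) next
                d <- max(D[clusters[[i]], clusters[[j]]])
                if (d < best[1]) best <- c(d, i, j)
            }
        }
        i <- best[2]; j <- best[3]
        coph[clusters[[i]], clusters[[j]]] <- best[1]
        coph[clusters[[j]], clusters[[i]]] <- best[1]
        clusters[[i]] <- c(clusters[[i]], clusters[[j]])
        clusters[[j]] <- NULL
    }
    coph
}
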