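#' Unordered edge key set of a module
#'
#' Canonical unordered keys ("a|b", a <= b) for a module's edges;
#' self-loops are excluded. Comparing modules by shared edges rather than
#' shared nodes distinguishes modules that contain the same proteins wired
#' differently.
#'
#' @param x a [TRModule-class], [CombinedTRM-class], [PPIGraph-class], or
#'   an edge data.frame with gene_a/gene_b columns.
#' @return character vector of unique edge keys.
#' @export
edgeKeySet <- function(x) {
    et <- if (is.data.frame(x)) x else edgeTable(x)
    if (!nrow(et)) return(character())
    keys <- .edgeKey(et$gene_a, et$gene_b)
    keep <- et$gene_a != et$gene_b
    unique(keys[keep])
}

#' Jaccard index of two edge sets
#'
#' \code{|a intersect b| / |a union b|}. When both sets are empty the
#' index is defined as 0 with a warning, so empty modules cannot poison a
#' similarity matrix with NaN.
#'
#' @param a,b character vectors of edge keys (from [edgeKeySet()]).
#' @return numeric in [0, 1].
#' @export
jaccardEdges <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0) {
        warning("both edge sets empty; Jaccard defined as 0",
                call. = FALSE)
        return(0)
    }
    length(intersect(a, b)) / u
}

#' Partition two edge sets into exclusive and shared counts
#'
#' @param a,b character vectors of edge keys.
#' @return named integer vector: only_a, shared, only_b.
#' @export
commonEdgeCounts <- function(a, b) {
    a <- unique(a); b <- unique(b)
    shared <- length(intersect(a, b))
    c(only_a = length(a) - shared, shared = shared,
      only_b = length(b) - shared)
}

#' Pairwise edge-Jaccard similarity matrix over modules
#'
#' All-against-all comparison of shared edges among modules. Symmetric
#' with unit diagonal (also for empty modules, by convention).
#'
#' @param modules named list of [TRModule-class]/[CombinedTRM-class]
#'   objects (or precomputed edge key sets); >= 2 entries.
#' @return symmetric numeric matrix with module names as dimnames.
#' @export
similarityMatrix <- function(modules) {
    if (length(modules) < 2)
        stop("need at least 2 modules", call. = FALSE)
    labs <- names(modules)
    if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs))
        stop("modules must be uniquely named", call. = FALSE)
    keys <- lapply(modules, function(m)
        if (is.character(m)) unique(m) else edgeKeySet(m))
    n <- length(keys)
    J <- diag(1, n)
    dimnames(J) <- list(labs, labs)
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            J[i, j] <- J[j, i] <-
                suppressWarnings(jaccardEdges(keys[[i]], keys[[j]]))
        }
    }
    J
}

#' Hierarchically cluster modules by their similarity profiles
#'
#' Rows of the Jaccard matrix are the modules' similarity profiles;
#' pairwise row distances are Pearson distances (d = 1 - r, where r is
#' the Pearson correlation coefficient), agglomerated with complete
#' linkage. Labels are sorted before clustering so ties resolve
#' deterministically by label order.
#'
#' @param J similarity matrix from [similarityMatrix()].
#' @param excludeDiagonal drop each row's self-similarity entry before
#'   computing correlations (default FALSE: the matrix is clustered as
#'   is, diagonal included).
#' @return list: \code{hclust} (the stats::hclust tree),
#'   \code{leafOrder}, \code{distanceDef}, \code{linkage}.
#' @export
clusterModules <- function(J, excludeDiagonal = FALSE) {
    if (nrow(J) < 2) stop("need at least 2 modules", call. = FALSE)
    labs <- sort(rownames(J))
    J <- J[labs, labs, drop = FALSE]
    sds <- apply(J, 1, stats::sd)
    if (any(sds == 0))
        stop("constant similarity profile (correlation undefined) for: ",
             paste(labs[sds == 0], collapse = ", "), call. = FALSE)
    Jc <- J
    if (excludeDiagonal) diag(Jc) <- NA
    r <- suppressWarnings(
        cor(t(Jc), use = if (excludeDiagonal) "pairwise.complete.obs"
                         else "everything"))
    d <- as.dist(1 - r)
    hc <- hclust(d, method = "complete")
    list(hclust = hc, leafOrder = hc$labels[hc$order],
         distanceDef = "pearson (d = 1 - r)", linkage = "complete")
}

#' Write a similarity matrix as TSV with header row and column
#'
#' @param J similarity matrix.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeSimilarityMatrix <- function(J, path) {
    df <- data.frame(module = rownames(J), J, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
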