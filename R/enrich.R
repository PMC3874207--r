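#' Upper-tail hypergeometric probability
#'
#' \code{P(X >= k)} for X ~ Hypergeometric drawing \code{n} genes from a
#' universe of \code{N} genes of which \code{K} carry the annotation.
#' Computed as \code{phyper(k - 1, K, N - K, n, lower.tail = FALSE)}; the
#' off-by-one is handled here so callers always get the inclusive
#' upper tail, and \code{k = 0} is exactly 1.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K annotated genes in the universe.
#' @param n query genes in the universe.
#' @param N universe size.
#' @return probability in (0, 1].
#' @examples
#' hypergeomUpper(4, K = 5, n = 4, N = 10)  # 5/210
#' @export
hypergeomUpper <- function(k, K, n, N) {
    for (v in list(k = k, K = K, n = n, N = N))
        if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
            stop("k, K, n, N must be single nonnegative integers",
                 call. = FALSE)
    if (K > N || n > N)
        stop("K and n cannot exceed N", call. = FALSE)
    if (k > min(K, n))
        stop("k cannot exceed min(K, n)", call. = FALSE)
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a term-to-gene annotation table
#'
#' Two-column TSV (term, gene) with header, plus an optional term-name
#' TSV (term, name).
#'
#' @param path annotation TSV.
#' @param namesPath optional term-name TSV.
#' @return an [AnnotationTable-class].
#' @export
readAnnotationTable <- function(path, namesPath = NULL) {
    tab <- .readTsv(path)
    if (!all(c("term", "gene") %in% names(tab)))
        stop(path, ": annotation table needs term and gene columns",
             call. = FALSE)
    tg <- split(as.character(tab$gene), as.character(tab$term))
    tg <- lapply(tg, unique)
    nm <- setNames(character(), character())
    if (!is.null(namesPath)) {
        nt <- .readTsv(namesPath)
        nm <- setNames(as.character(nt$name), as.character(nt$term))
    }
    new("AnnotationTable", termGenes = tg, termNames = nm)
}

#' Hypergeometric term enrichment in a gene set
#'
#' Tests every annotation term with at least one gene in the query for
#' over-representation, using the inclusive upper-tail hypergeometric
#' test. Raw p-values are reported and flagged significant at
#' \code{p < alpha} (strict); no multiple-testing correction is applied
#' unless \code{adjust = "BH"} is requested.
#'
#' The universe defaults to all genes in the annotation table; supply the
#' appropriate background (e.g. expressed genes or PPI nodes) explicitly
#' when one is available. Query genes outside the universe are dropped
#' with a warning.
#'
#' @param query character vector of genes.
#' @param annotations an [AnnotationTable-class].
#' @param universe background gene set; default: all annotated genes.
#' @param alpha significance level on the raw p-value.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame sorted by p-value: term, name, k, K, n, N, p_value,
#'   (p_adjusted,) significant.
#' @export
enrichTerms <- function(query, annotations, universe = NULL, alpha = 0.05,
                        adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    stopifnot(is(annotations, "AnnotationTable"))
    tg <- termGenes(annotations)
    if (is.null(universe))
        universe <- unique(unlist(tg, use.names = FALSE))
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe", call. = FALSE)
    query <- unique(as.character(query))
    outside <- setdiff(query, universe)
    if (length(outside)) {
        warning(length(outside),
                " query gene(s) outside the universe dropped",
                call. = FALSE)
        query <- intersect(query, universe)
    }
    n <- length(query)
    N <- length(universe)
    rows <- list()
    for (term in names(tg)) {
        tgenes <- intersect(tg[[term]], universe)
        K <- length(tgenes)
        k <- length(intersect(tgenes, query))
        if (k < 1) next
        rows[[term]] <- data.frame(
            term = term,
            name = unname(termNames(annotations)[term] %|na|% term),
            k = k, K = K, n = n, N = N,
            p_value = hypergeomUpper(k, K, n, N),
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(term = character(), name = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p_value = numeric(),
                          significant = logical()))
    out <- do.call(rbind, rows)
    out <- out[order(out$p_value, out$term), , drop = FALSE]
    if (adjust == "BH") {
        out$p_adjusted <- p.adjust(out$p_value, method = "BH")
        out$significant <- out$p_adjusted < alpha
    } else {
        out$significant <- out$p_value < alpha
    }
    rownames(out) <- NULL
    out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Count query genes annotated to any of a set of terms
#'
#' E.g. how many proteins of a combined module are annotated with an
#' embryonic-lethality phenotype.
#'
#' @param query nonempty character vector of genes.
#' @param annotations an [AnnotationTable-class].
#' @param terms term ids to pool.
#' @return list with \code{count}, \code{fraction}, \code{genes}.
#' @export
countAnnotated <- function(query, annotations, terms) {
    stopifnot(is(annotations, "AnnotationTable"))
    query <- unique(as.character(query))
    if (!length(query)) stop("query must be nonempty", call. = FALSE)
    pool <- unique(unlist(termGenes(annotations)[
        intersect(terms, names(termGenes(annotations)))],
        use.names = FALSE))
    hit <- intersect(query, pool)
    list(count = length(hit), fraction = length(hit) / length(query),
         genes = sort(hit))
}
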