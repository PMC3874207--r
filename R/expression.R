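#' Read an expression matrix from TSV
#'
#' Gene rows, sample columns, header row; first column holds gene ids.
#'
#' @param path TSV file path.
#' @param scale one of \code{"log2_intensity"}, \code{"raw_counts"},
#'   \code{"cpm"}; recorded in the \code{"scale"} attribute.
#' @return numeric matrix with gene rownames and a \code{scale} attribute.
#' @export
readExpressionMatrix <- function(path, scale = c("log2_intensity",
                                 "raw_counts", "cpm")) {
    scale <- match.arg(scale)
    tab <- .readTsv(path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- as.character(tab[[1]])
    if (scale == "raw_counts" && any(m < 0, na.rm = TRUE))
        stop(path, ": raw counts must be nonnegative", call. = FALSE)
    attr(m, "scale") <- scale
    m
}

#' Convert raw counts to counts per million
#'
#' \code{cpm[g, s] = raw[g, s] * 1e6 / libsize[s]}, so every sample column
#' sums to one million. Rank order of genes within a sample is preserved.
#'
#' @param counts nonnegative count matrix (genes x samples).
#' @return CPM matrix with \code{scale} attribute \code{"cpm"}.
#' @export
computeCPM <- function(counts) {
    m <- as.matrix(counts)
    if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
    lib <- colSums(m)
    if (any(lib == 0)) {
        bad <- colnames(m)[lib == 0] %||% which(lib == 0)
        stop("zero library size in sample(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    out <- sweep(m, 2, lib, "/") * 1e6
    attr(out, "scale") <- "cpm"
    out
}

#' Call expressed genes by a hard cutoff
#'
#' A gene is expressed when its value strictly exceeds the cutoff in every
#' sample (\code{mode = "all"}, the default used for multi-sample RNA-seq
#' filtering) or in at least one sample (\code{mode = "any"}). Values
#' exactly at the cutoff never pass.
#'
#' Typical cutoffs: CPM > 1 for RNA-seq; a dataset-specific log2 intensity
#' (chosen by inspecting the bimodal value distribution and marker genes)
#' for microarray data. The cutoff is always user-supplied;
#' [expressionHistogram()] helps choose one but never picks it.
#'
#' @param expr expression matrix (genes x samples).
#' @param cutoff finite numeric cutoff on the matrix scale.
#' @param mode \code{"all"} or \code{"any"}.
#' @return character vector of expressed gene ids.
#' @export
expressedGenes <- function(expr, cutoff, mode = c("all", "any")) {
    mode <- match.arg(mode)
    .assertScalarNumber(cutoff, "cutoff")
    m <- as.matrix(expr)
    pass <- m > cutoff
    keep <- if (mode == "all") rowSums(!pass) == 0 else rowSums(pass) > 0
    rownames(m)[keep]
}

#' Histogram of expression values (cutoff-selection aid)
#'
#' Returns bin midpoints and counts over all matrix entries so the bimodal
#' background/expressed structure can be inspected. Deliberately does not
#' propose a cutoff.
#'
#' @param expr expression matrix.
#' @param breaks number of bins.
#' @return data.frame with \code{mid} and \code{count}.
#' @export
expressionHistogram <- function(expr, breaks = 50) {
    h <- graphics::hist(as.numeric(as.matrix(expr)), breaks = breaks,
                        plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
}
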