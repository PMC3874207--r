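#' Read position weight matrices into a PWMCollection
#'
#' Parses one or more PWM files and tags every motif with its source
#' database and species. Two plain-text layouts are understood and
#' auto-detected per file: JASPAR PFM (a \code{>} header line followed by
#' four nucleotide rows, optionally prefixed with the base letter and
#' bracketed) and a generic long-format TSV with columns
#' \code{motif_id}, \code{base}, \code{p1..pL}.
#'
#' Matrices are stored as given (counts or frequencies); no pseudocount is
#' added because no sequence scanning is performed downstream.
#'
#' @param files character vector of file paths.
#' @param source source tag, one of \code{"jaspar"}, \code{"uniprobe"},
#'   \code{"htselex"}, \code{"custom"}.
#' @param species taxon label recorded per motif (e.g. \code{"Mus musculus"}).
#' @return a [PWMCollection-class] object.
#' @examples
#' pfm <- system.file("extdata", "example_jaspar.pfm", package = "trmnet")
#' readPWMCollection(pfm, source = "jaspar", species = "Homo sapiens")
#' @export
readPWMCollection <- function(files, source = c("custom", "jaspar",
                              "uniprobe", "htselex"), species = "unknown") {
    source <- match.arg(source)
    mats <- list()
    for (f in files) {
        parsed <- .parsePWMFile(f)
        dup <- intersect(names(parsed), names(mats))
        if (length(dup))
            stop("duplicated motif id(s) within one load: ",
                 paste(dup, collapse = ", "), call. = FALSE)
        mats <- c(mats, parsed)
    }
    .newPWMCollection(mats, source, species)
}

.newPWMCollection <- function(mats, source, species) {
    info <- data.frame(
        motif_id = names(mats) %||% character(),
        source = rep(source, length.out = length(mats)),
        species = rep(species, length.out = length(mats)),
        width = vapply(mats, ncol, integer(1), USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    rownames(info) <- NULL
    new("PWMCollection", matrices = mats, info = info)
}

.parsePWMFile <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(list())
    if (startsWith(trimws(lines[[1]]), ">"))
        .parseJasparPfm(lines, path)
    else
        .parsePWMTsv(path)
}

## ">MA0004.1 Arnt" header, then rows like "A [ 4 19 0 ]" or "4 19 0"
.parseJasparPfm <- function(lines, path) {
    hdr <- grep("^>", trimws(lines))
    out <- list()
    for (i in seq_along(hdr)) {
        from <- hdr[i] + 1L
        to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
        id <- strsplit(sub("^>\\s*", "", trimws(lines[hdr[i]])), "\\s+")[[1]][1]
        body <- lines[seq(from, length.out = max(0L, to - from + 1L))]
        if (length(body) != 4L)
            stop(sprintf("%s: motif '%s' has %d rows, expected 4",
                         path, id, length(body)), call. = FALSE)
        rows <- lapply(body, function(x) {
            x <- gsub("^[ACGTacgt]\\s*", "", trimws(x))
            x <- gsub("\\[|\\]", " ", x)
            vals <- suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1]]))
            if (anyNA(vals))
                stop(sprintf("%s: motif '%s' has a non-numeric cell",
                             path, id), call. = FALSE)
            vals
        })
        if (length(unique(lengths(rows))) != 1L)
            stop(sprintf("%s: motif '%s' has ragged columns", path, id),
                 call. = FALSE)
        m <- do.call(rbind, rows)
        rownames(m) <- c("A", "C", "G", "T")
        if (ncol(m) < 1L)
            stop(sprintf("%s: motif '%s' has no positions", path, id),
                 call. = FALSE)
        if (any(m < 0))
            stop(sprintf("%s: motif '%s' has negative entries", path, id),
                 call. = FALSE)
        if (id %in% names(out))
            stop(sprintf("%s: duplicated motif id '%s'", path, id),
                 call. = FALSE)
        out[[id]] <- m
    }
    out
}

.parsePWMTsv <- function(path) {
    tab <- .readTsv(path)
    need <- c("motif_id", "base")
    if (!all(need %in% names(tab)))
        stop(path, ": generic PWM TSV needs motif_id and base columns",
             call. = FALSE)
    poscols <- setdiff(names(tab), need)
    out <- list()
    for (id in unique(tab$motif_id)) {
        sub <- tab[tab$motif_id == id, , drop = FALSE]
        if (nrow(sub) != 4L || !setequal(sub$base, c("A", "C", "G", "T")))
            stop(sprintf("%s: motif '%s' must have exactly rows A,C,G,T",
                         path, id), call. = FALSE)
        sub <- sub[match(c("A", "C", "G", "T"), sub$base), , drop = FALSE]
        m <- as.matrix(sub[, poscols, drop = FALSE])
        mode(m) <- "numeric"
        keep <- colSums(is.na(m)) < 4L  # fully-NA trailing columns allowed
        m <- m[, keep, drop = FALSE]
        if (anyNA(m))
            stop(sprintf("%s: motif '%s' has ragged columns", path, id),
                 call. = FALSE)
        if (ncol(m) < 1L)
            stop(sprintf("%s: motif '%s' has no positions", path, id),
                 call. = FALSE)
        if (any(m < 0))
            stop(sprintf("%s: motif '%s' has negative entries", path, id),
                 call. = FALSE)
        rownames(m) <- c("A", "C", "G", "T")
        colnames(m) <- NULL
        out[[id]] <- m
    }
    out
}

#' Merge PWM collections from several source databases
#'
#' Takes the union of motif libraries. When the same motif id occurs in
#' more than one source, both matrices are kept and the colliding ids are
#' suffixed \code{"<id>@<source>"}: sources are independent catalogues and
#' a silent overwrite would lose provenance.
#'
#' @param collections list of [PWMCollection-class] objects.
#' @return a single merged [PWMCollection-class].
#' @export
mergePWMCollections <- function(collections) {
    if (!length(collections)) stop("no collections", call. = FALSE)
    stopifnot(all(vapply(collections, is, logical(1), "PWMCollection")))
    allIds <- unlist(lapply(collections, function(x) names(x@matrices)))
    dup <- unique(allIds[duplicated(allIds)])
    mats <- list()
    info <- list()
    for (col in collections) {
        ids <- names(col@matrices)
        ci <- col@info
        newIds <- ifelse(ids %in% dup, paste0(ids, "@", ci$source), ids)
        m <- col@matrices
        names(m) <- newIds
        ci$motif_id <- newIds
        mats <- c(mats, m)
        info[[length(info) + 1L]] <- ci
    }
    info <- do.call(rbind, info)
    rownames(info) <- NULL
    new("PWMCollection", matrices = mats, info = info)
}

#' Summarise a PWM collection and its gene coverage
#'
#' Reports the number of motifs per source database, the total motif
#' count, and the number of distinct genes the library maps to through a
#' motif-to-gene table.
#'
#' @param collection a [PWMCollection-class].
#' @param geneMap a motif-to-gene map as returned by [readMotifGeneMap()],
#'   or NULL to skip gene coverage.
#' @return list with \code{per_source}, \code{total_motifs},
#'   \code{distinct_genes}.
#' @export
pwmSummary <- function(collection, geneMap = NULL) {
    stopifnot(is(collection, "PWMCollection"))
    genes <- character()
    if (!is.null(geneMap)) {
        hit <- geneMap$motif_id %in% names(collection@matrices)
        genes <- unique(geneMap$gene[hit])
    }
    list(per_source = as.list(perSourceCounts(collection)),
         total_motifs = nMotifs(collection),
         distinct_genes = length(genes))
}
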