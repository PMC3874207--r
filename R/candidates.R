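#' Extend ChIP-seq peak summits into fixed-width regions
#'
#' Each summit (a single genomic position, 0-based) is extended by
#' \code{flank} bp on either side, giving half-open regions
#' \code{[pos - flank, pos + flank)} of width \code{2 * flank} (400 bp at
#' the default flank of 200), clipped at the chromosome origin. No
#' chromosome-length clipping is applied (a sizes file is not required).
#'
#' @param summits data.frame with columns \code{chrom} and \code{position}
#'   (0-based summit coordinate), optionally \code{name}.
#' @param flank bp added on each side; must be > 0.
#' @return a [GenomicRanges::GRanges] of the extended regions.
#' @examples
#' extendSummits(data.frame(chrom = "chr1", position = 1000))
#' @export
extendSummits <- function(summits, flank = 200) {
    if (!is.numeric(flank) || length(flank) != 1L || flank <= 0)
        stop("flank must be a positive number", call. = FALSE)
    if (!all(c("chrom", "position") %in% names(summits)))
        stop("summits needs chrom and position columns", call. = FALSE)
    pos <- summits$position
    if (any(pos < 0)) stop("negative summit position", call. = FALSE)
    start0 <- pmax(0, pos - flank)   # 0-based half-open
    end0 <- pos + flank
    gr <- GenomicRanges::GRanges(
        seqnames = summits$chrom,
        ranges = IRanges::IRanges(start = start0 + 1L, end = end0))
    if (!is.null(summits$name)) names(gr) <- summits$name
    gr
}

#' Write genomic regions as 4-column BED
#'
#' @param gr a GRanges.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBed <- function(gr, path) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
        rtracklayer::export(gr, path, format = "BED")
    } else {
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr),
                         name = names(gr) %||% ".")
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Parse replicate motif-enrichment result tables
#'
#' Reads one results table per de novo enrichment run (HOMER-style TSV
#' with configurable column names) and pools them with a \code{run_id}
#' assigned by file order, starting at 1. Rows whose q-value does not
#' parse as a number are dropped with a warning.
#'
#' @param files character vector of TSV paths, one per replicate run.
#' @param motifCol,qCol column names holding the motif id and q-value.
#' @return data.frame with run_id, motif_id, q_value.
#' @export
parseEnrichmentRuns <- function(files, motifCol = "motif_id",
                                qCol = "q_value") {
    recs <- list()
    for (i in seq_along(files)) {
        tab <- .readTsv(files[i])
        if (!all(c(motifCol, qCol) %in% names(tab)))
            stop(files[i], ": missing required column(s) ",
                 paste(setdiff(c(motifCol, qCol), names(tab)),
                       collapse = ", "), call. = FALSE)
        q <- suppressWarnings(as.numeric(tab[[qCol]]))
        bad <- is.na(q)
        if (any(bad))
            warning(files[i], ": dropped ", sum(bad),
                    " row(s) with unparsable q-value", call. = FALSE)
        recs[[i]] <- data.frame(run_id = rep(i, sum(!bad)),
                                motif_id = as.character(tab[[motifCol]])[!bad],
                                q_value = q[!bad],
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs) %||%
        data.frame(run_id = integer(), motif_id = character(),
                   q_value = numeric())
    rownames(out) <- NULL
    out
}

#' Consensus motifs across replicate enrichment runs
#'
#' De novo enrichment against randomly sampled background sequences varies
#' run to run; a motif is only trusted when it is enriched
#' (\code{q < qThresh}, strictly) in at least \code{minFrac} of the
#' replicate runs (ceiling rule: 80\% of 10 runs means 8 runs exactly).
#' Duplicated records for the same (run, motif) count once.
#'
#' @param records data.frame from [parseEnrichmentRuns()].
#' @param nRuns total number of replicate runs performed.
#' @param qThresh enrichment q-value threshold (strict \code{<}).
#' @param minFrac minimum fraction of runs, in (0, 1].
#' @return character vector of consensus motif ids.
#' @export
consensusMotifs <- function(records, nRuns, qThresh = 0.05, minFrac = 0.8) {
    if (nRuns < 1) stop("nRuns must be >= 1", call. = FALSE)
    if (minFrac <= 0 || minFrac > 1)
        stop("minFrac must be in (0, 1]", call. = FALSE)
    if (nrow(records) && any(records$run_id > nRuns | records$run_id < 1))
        stop("records reference run_id outside 1..nRuns", call. = FALSE)
    need <- ceiling(round(minFrac * nRuns, 9))
    hits <- unique(records[records$q_value < qThresh,
                           c("run_id", "motif_id")])
    if (!nrow(hits)) return(character())
    tab <- table(hits$motif_id)
    sort(names(tab)[tab >= need])
}

#' Filter de novo-to-library motif matches by q-value
#'
#' Keeps matches with \code{q < qThresh} (strict). De novo motifs whose
#' matches were all filtered out get an empty entry and a warning.
#'
#' @param matches data.frame with denovo_id, library_motif_id, q_value.
#' @param qThresh match q-value threshold.
#' @return named list: denovo_id -> character vector of library motif ids.
#' @export
filterMotifMatches <- function(matches, qThresh = 0.05) {
    out <- list()
    lost <- character()
    for (d in unique(matches$denovo_id)) {
        sub <- matches[matches$denovo_id == d & matches$q_value < qThresh, ]
        out[[d]] <- unique(as.character(sub$library_motif_id))
        if (!length(out[[d]])) lost <- c(lost, d)
    }
    if (length(lost))
        warning("de novo motif(s) with no surviving library match: ",
                paste(lost, collapse = ", "), call. = FALSE)
    out
}

#' Read a de novo-to-library match table (Tomtom-style TSV)
#'
#' @param path TSV path.
#' @param denovoCol,libraryCol,qCol column names.
#' @return data.frame with denovo_id, library_motif_id, q_value.
#' @export
readMotifMatches <- function(path, denovoCol = "denovo_id",
                             libraryCol = "library_motif_id",
                             qCol = "q_value") {
    tab <- .readTsv(path)
    need <- c(denovoCol, libraryCol, qCol)
    if (!all(need %in% names(tab)))
        stop(path, ": missing required column(s) ",
             paste(setdiff(need, names(tab)), collapse = ", "),
             call. = FALSE)
    data.frame(denovo_id = as.character(tab[[denovoCol]]),
               library_motif_id = as.character(tab[[libraryCol]]),
               q_value = as.numeric(tab[[qCol]]),
               stringsAsFactors = FALSE)
}

#' Select expression-filtered candidate TFs for one ChIP-seq library
#'
#' Maps the consensus-enriched de novo motifs through their library
#' matches to genes of the target species, then removes genes not
#' expressed in the cell type under study. Provenance records which
#' library motifs supported each candidate. Consensus motifs without a
#' library match are excluded and listed in a warning.
#'
#' @param consensus character vector of consensus de novo motif ids.
#' @param matchMap named list from [filterMotifMatches()].
#' @param geneMap motif-to-gene table from [readMotifGeneMap()].
#' @param expressed character vector of expressed gene ids.
#' @param ortho ortholog table, or NULL.
#' @param targetSpecies species of the analysis.
#' @param expressionRule free-text label recording the cutoff used.
#' @return a [CandidateSet-class].
#' @export
selectCandidates <- function(consensus, matchMap, geneMap, expressed,
                             ortho = NULL, targetSpecies = "unknown",
                             expressionRule = "user-supplied") {
    unmatched <- consensus[vapply(consensus, function(d)
        length(matchMap[[d]]) == 0, logical(1))]
    libMotifs <- unique(unlist(matchMap[setdiff(consensus, unmatched)],
                               use.names = FALSE))
    if (length(unmatched))
        warning("consensus motif(s) with no library match: ",
                paste(unmatched, collapse = ", "), call. = FALSE)
    prov <- list()
    if (length(libMotifs)) {
        for (m in libMotifs) {
            g <- suppressWarnings(
                mapMotifsToGenes(m, geneMap, ortho, targetSpecies))
            for (gene in intersect(g, expressed))
                prov[[gene]] <- unique(c(prov[[gene]], m))
        }
    }
    new("CandidateSet", genes = names(prov) %||% character(),
        provenance = prov,
        expressionRule = expressionRule,
        unmatchedMotifs = unmatched, species = targetSpecies)
}

#' Export a candidate set as TSV (gene, motifs, species)
#'
#' @param cs a [CandidateSet-class].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeCandidateSet <- function(cs, path) {
    stopifnot(is(cs, "CandidateSet"))
    df <- data.frame(
        gene = candidateGenes(cs),
        motifs = vapply(provenance(cs)[candidateGenes(cs)],
                        paste, character(1), collapse = ","),
        species = cs@species, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
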