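#' Read a motif-to-gene mapping table
#'
#' Two-plus-column TSV with a header; required columns \code{motif_id} and
#' \code{gene}, optional \code{species} (species of the gene; defaults to
#' the collection species when absent). Gene identifiers are opaque
#' strings (typically Entrez ids) and are never validated against a live
#' service.
#'
#' @param path TSV file path.
#' @param defaultSpecies species assumed when the table has no species
#'   column.
#' @return data.frame with columns motif_id, gene, species.
#' @export
readMotifGeneMap <- function(path, defaultSpecies = "unknown") {
    tab <- .readTsv(path)
    if (!all(c("motif_id", "gene") %in% names(tab)))
        stop(path, ": motif-gene map needs motif_id and gene columns",
             call. = FALSE)
    if (is.null(tab$species)) tab$species <- defaultSpecies
    tab$gene <- as.character(tab$gene)
    tab <- tab[nzchar(tab$gene), c("motif_id", "gene", "species")]
    unique(tab)
}

#' Read an ortholog mapping table
#'
#' TSV with header columns \code{gene}, \code{species},
#' \code{ortholog_gene}, \code{ortholog_species}. One-to-many mappings are
#' kept in full: every ortholog is a candidate and over-inclusion is
#' corrected downstream by the expression filter.
#'
#' @param path TSV file path.
#' @return data.frame of ortholog pairs.
#' @export
readOrthologMap <- function(path) {
    tab <- .readTsv(path)
    need <- c("gene", "species", "ortholog_gene", "ortholog_species")
    if (!all(need %in% names(tab)))
        stop(path, ": ortholog map needs columns ",
             paste(need, collapse = ", "), call. = FALSE)
    tab$gene <- as.character(tab$gene)
    tab$ortholog_gene <- as.character(tab$ortholog_gene)
    unique(tab[, need])
}

#' Look up orthologs of a gene in a target species
#'
#' Unmapped genes yield an empty set, never an error.
#'
#' @param ortho ortholog table from [readOrthologMap()] (or NULL).
#' @param gene gene id.
#' @param fromSpecies species of \code{gene}.
#' @param toSpecies species to translate into.
#' @return character vector of ortholog gene ids (possibly empty).
#' @export
orthologLookup <- function(ortho, gene, fromSpecies, toSpecies) {
    if (is.null(ortho) || !nrow(ortho)) return(character())
    hit <- ortho$gene == gene & ortho$species == fromSpecies &
        ortho$ortholog_species == toSpecies
    unique(ortho$ortholog_gene[hit])
}

#' Map enriched motifs to genes of the target species
#'
#' Resolves motif ids through the motif-to-gene table; genes annotated to
#' a foreign species are translated through the ortholog table into the
#' target species (all orthologs kept, no best-hit choice). Motifs with no
#' gene mapping are reported in a warning and returned in the
#' \code{"unmapped"} attribute.
#'
#' @param motifs character vector of motif ids (nonempty).
#' @param geneMap data.frame from [readMotifGeneMap()].
#' @param ortho ortholog table from [readOrthologMap()], or NULL.
#' @param targetSpecies species of the returned genes.
#' @return character vector of gene ids in the target species, with
#'   attribute \code{unmapped} listing motifs that resolved to nothing.
#' @export
mapMotifsToGenes <- function(motifs, geneMap, ortho = NULL,
                             targetSpecies = "unknown") {
    if (!length(motifs)) stop("motifs must be nonempty", call. = FALSE)
    genes <- character()
    unmapped <- character()
    for (m in unique(motifs)) {
        rows <- geneMap[geneMap$motif_id == m, , drop = FALSE]
        hit <- character()
        for (i in seq_len(nrow(rows))) {
            if (rows$species[i] == targetSpecies) {
                hit <- c(hit, rows$gene[i])
            } else {
                hit <- c(hit, orthologLookup(ortho, rows$gene[i],
                                             rows$species[i], targetSpecies))
            }
        }
        if (!length(hit)) unmapped <- c(unmapped, m)
        genes <- c(genes, hit)
    }
    if (length(unmapped))
        warning("motifs with no gene mapping in ", targetSpecies, ": ",
                paste(unmapped, collapse = ", "), call. = FALSE)
    structure(unique(genes), unmapped = unmapped)
}

#' Annotate genes with their TF structural class lineage
#'
#' Assigns each gene its (superclass, class, family, subclass) lineage
#' from a structural classification, either by direct lookup or through an
#' ortholog in the annotated species (e.g. mouse TFs classified through
#' their human orthologs). Genes with neither route are flagged
#' \code{"unclassified"}.
#'
#' @param genes character vector of gene ids.
#' @param ann annotation data.frame from [readTFClassObo()].
#' @param ortho ortholog table, or NULL for direct lookup only.
#' @param species species of \code{genes}.
#' @param annSpecies species the annotation is keyed in.
#' @return data.frame: gene, superclass, class, family, subclass, status.
#' @export
annotateTFClass <- function(genes, ann, ortho = NULL,
                            species = "unknown", annSpecies = species) {
    cols <- c("superclass", "class", "family", "subclass")
    ng <- length(genes)
    out <- data.frame(gene = as.character(genes),
                      superclass = rep(NA_character_, ng),
                      class = rep(NA_character_, ng),
                      family = rep(NA_character_, ng),
                      subclass = rep(NA_character_, ng),
                      status = rep("unclassified", ng),
                      stringsAsFactors = FALSE)
    if (!length(genes)) return(out)
    for (i in seq_along(genes)) {
        hit <- ann[ann$gene == genes[i], , drop = FALSE]
        via <- "direct"
        if (!nrow(hit) && !is.null(ortho)) {
            orths <- orthologLookup(ortho, genes[i], species, annSpecies)
            hit <- ann[ann$gene %in% orths, , drop = FALSE]
            via <- "ortholog"
        }
        if (nrow(hit)) {
            out[i, cols] <- hit[1L, cols]
            out$status[i] <- via
        }
    }
    out
}
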