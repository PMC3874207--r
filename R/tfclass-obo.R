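#' Parse a TF structural-classification OBO file
#'
#' Reads an OBO 1.2 ontology describing the structural classification of
#' transcription factors (superclass -> class -> family -> optional
#' subclass -> gene -> factor species). Each \code{[Term]} stanza carries
#' its level in the standard \code{subset:} tag and gene-level terms carry
#' an \code{xref: EntrezGene:<id>} cross-reference (the term name is used
#' when no xref is present).
#'
#' Factor-species entries (protein isoforms below the gene level) are
#' dropped before gene resolution: the gene is the basic unit of the
#' analysis pipeline. Orphan terms (a parent id that does not exist) are
#' skipped with a warning; a cyclic \code{is_a} chain is an error.
#'
#' @param path OBO file path.
#' @return data.frame with one row per gene-level term: \code{gene},
#'   \code{gene_name}, \code{superclass}, \code{class}, \code{family},
#'   \code{subclass} (NA when the optional level is absent).
#' @examples
#' obo <- system.file("extdata", "tfclass_synthetic.obo", package = "trmnet")
#' readTFClassObo(obo)
#' @export
readTFClassObo <- function(path) {
    terms <- .parseOboTerms(path)
    empty <- data.frame(gene = character(), gene_name = character(),
                        superclass = character(), class = character(),
                        family = character(), subclass = character(),
                        stringsAsFactors = FALSE)
    if (!length(terms)) return(empty)

    level <- vapply(terms, function(t) t$level, character(1))
    keep <- level != "factor_species"
    terms <- terms[keep]
    level <- level[keep]
    ids <- names(terms)

    ## orphan check (after factor-species removal the survivors must still
    ## resolve; a gene whose parent was factor-species would be malformed)
    parent <- vapply(terms, function(t) t$is_a %||% NA_character_,
                     character(1))
    orphan <- !is.na(parent) & !(parent %in% ids)
    if (any(orphan)) {
        warning("skipping orphan term(s): ",
                paste(ids[orphan], collapse = ", "), call. = FALSE)
        terms <- terms[!orphan]
        level <- level[!orphan]
        ids <- names(terms)
        parent <- parent[!orphan]
    }

    lineageOf <- function(id) {
        lin <- c(superclass = NA_character_, class = NA_character_,
                 family = NA_character_, subclass = NA_character_)
        seen <- character()
        cur <- terms[[id]]$is_a
        while (!is.null(cur) && !is.na(cur)) {
            if (cur %in% seen)
                stop("cyclic is_a chain at term ", cur, call. = FALSE)
            seen <- c(seen, cur)
            t <- terms[[cur]]
            if (is.null(t)) break
            if (t$level %in% names(lin)) lin[t$level] <- t$name
            cur <- t$is_a
        }
        lin
    }

    rows <- list()
    for (id in ids[level == "gene"]) {
        t <- terms[[id]]
        lin <- lineageOf(id)
        if (is.na(lin["superclass"]) || is.na(lin["class"])) {
            warning("gene term ", id,
                    " lacks a resolvable superclass/class; skipped",
                    call. = FALSE)
            next
        }
        rows[[length(rows) + 1L]] <- data.frame(
            gene = t$gene %||% t$name, gene_name = t$name,
            superclass = lin[["superclass"]], class = lin[["class"]],
            family = lin[["family"]], subclass = lin[["subclass"]],
            stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.parseOboTerms <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^\\[Term\\]\\s*$", lines)
    terms <- list()
    bounds <- c(starts, length(lines) + 1L)
    for (i in seq_along(starts)) {
        chunk <- lines[seq(starts[i] + 1L,
                           length.out = bounds[i + 1L] - starts[i] - 1L)]
        chunk <- chunk[!grepl("^\\[", chunk)]
        tag <- sub(":.*$", "", chunk)
        val <- trimws(sub("^[^:]*:", "", chunk))
        getAll <- function(t) val[tag == t]
        get1 <- function(t) {
            v <- getAll(t)
            if (length(v)) v[[1]] else NULL
        }
        id <- get1("id")
        if (is.null(id)) next
        isa <- get1("is_a")
        if (!is.null(isa)) isa <- sub("\\s*!.*$", "", isa)  # strip comment
        lev <- get1("subset") %||% "unknown"
        lev <- gsub("[ -]", "_", tolower(lev))
        gene <- NULL
        for (x in getAll("xref")) {
            if (grepl("^EntrezGene:", x)) gene <- sub("^EntrezGene:", "", x)
        }
        terms[[id]] <- list(id = id, name = get1("name") %||% id,
                            is_a = isa, level = lev, gene = gene)
    }
    terms
}
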