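## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.readTsv <- function(path, ...) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
               comment.char = "#", ...)
}

## canonical unordered edge key "a|b" with a <= b
.edgeKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}

.assertScalarNumber <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(what, " must be a single finite number", call. = FALSE)
    invisible(x)
}

## named-list -> JSON file, unboxed scalars
.writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
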