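#' @import methods
#' @importFrom stats phyper cor hclust as.dist setNames p.adjust rnorm runif rbinom
#' @importFrom utils read.delim write.table head
#' @importFrom graphics hist
NULL

#' @export
setGeneric("nMotifs", function(x) standardGeneric("nMotifs"))

#' @export
setGeneric("pwmMatrices", function(x) standardGeneric("pwmMatrices"))

#' @export
setGeneric("pwmInfo", function(x) standardGeneric("pwmInfo"))

#' @export
setGeneric("perSourceCounts", function(x) standardGeneric("perSourceCounts"))

#' @export
setGeneric("candidateGenes", function(x) standardGeneric("candidateGenes"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))

#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("edgeMultiplicity", function(x) standardGeneric("edgeMultiplicity"))

#' @export
setGeneric("moduleRoles", function(x) standardGeneric("moduleRoles"))

#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @export
setGeneric("queryGenes", function(x) standardGeneric("queryGenes"))

#' @export
setGeneric("isEmptyModule", function(x) standardGeneric("isEmptyModule"))

#' @export
setGeneric("nodeFreq", function(x) standardGeneric("nodeFreq"))

#' @export
setGeneric("edgeFreq", function(x) standardGeneric("edgeFreq"))

#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))

#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
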