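NULL

#' @export
setGeneric("specimen", function(x) standardGeneric("specimen"))

#' @export
setGeneric("readCount", function(x) standardGeneric("readCount"))

#' @export
setGeneric("insertionPos", function(x) standardGeneric("insertionPos"))

#' @export
setGeneric("taSites", function(x, chrom) standardGeneric("taSites"))

#' @export
setGeneric("totalTA", function(x) standardGeneric("totalTA"))

#' @export
setGeneric("geneFootprints", function(x) standardGeneric("geneFootprints"))

#' @export
setGeneric("cutoffReads", function(x) standardGeneric("cutoffReads"))

#' @export
setGeneric("driverTable", function(x) standardGeneric("driverTable"))

#' @export
setGeneric("significantDrivers", function(x, ...) standardGeneric("significantDrivers"))

#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @export
setGeneric("cellDepths", function(x) standardGeneric("cellDepths"))

#' @export
setGeneric("trunkGenes", function(x) standardGeneric("trunkGenes"))

#' @export
setGeneric("privateGenes", function(x) standardGeneric("privateGenes"))

#' @export
setGeneric("donorWindowRange", function(x) standardGeneric("donorWindowRange"))

#' @export
setGeneric("excludedGenes", function(x) standardGeneric("excludedGenes"))
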