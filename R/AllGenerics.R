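#' @rdname GenomeDataset-accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname GenomeDataset-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname GenomeDataset-accessors
#' @export
setGeneric("geneRecords", function(x) standardGeneric("geneRecords"))

#' @rdname GenomeDataset-accessors
#' @export
setGeneric("geneticCodeId", function(x) standardGeneric("geneticCodeId"))

#' @rdname GenomeDataset-accessors
#' @export
setGeneric("geneTable", function(x, ...) standardGeneric("geneTable"))

#' @rdname GenomeDataset-accessors
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))

#' @rdname StopUsageTable-accessors
#' @export
setGeneric("stopCounts", function(x) standardGeneric("stopCounts"))

#' @rdname StopUsageTable-accessors
#' @export
setGeneric("stopFreqs", function(x) standardGeneric("stopFreqs"))

#' @rdname stopPercentages
#' @export
setGeneric("stopPercentages",
           function(x, decimals = 1) standardGeneric("stopPercentages"))
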