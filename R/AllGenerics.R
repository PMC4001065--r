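#' @import methods
NULL

#' @export
setGeneric("variantData", function(x, ...) standardGeneric("variantData"))

#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))

#' @export
setGeneric("atomRecords", function(x, ...) standardGeneric("atomRecords"))

#' @export
setGeneric("sdsTable", function(x, ...) standardGeneric("sdsTable"))

#' @export
setGeneric("sds", function(x, ...) standardGeneric("sds"))

#' @export
setGeneric("finalPriority", function(x, ...) standardGeneric("finalPriority"))

#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))
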