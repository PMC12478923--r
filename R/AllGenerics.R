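#' @include AllClasses.R
NULL

#' @rdname ContactMap-accessors
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))

#' @rdname ContactMap-accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname ContactMap-accessors
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @rdname ContactMap-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname ContactMap-accessors
#' @export
setGeneric("retainedBins", function(x) standardGeneric("retainedBins"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("biosamples", function(x) standardGeneric("biosamples"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("assays", function(x) standardGeneric("assays"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("observedKeys", function(x) standardGeneric("observedKeys"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("nObserved", function(x) standardGeneric("nObserved"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("mapAt", function(x, biosample, assay) standardGeneric("mapAt"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("isObserved",
    function(x, biosample, assay) standardGeneric("isObserved"))

#' @rdname ContactGrid-accessors
#' @export
setGeneric("setMapAt",
    function(x, biosample, assay, value) standardGeneric("setMapAt"))

#' @rdname BinMask-accessors
#' @export
setGeneric("keptBins", function(x) standardGeneric("keptBins"))

#' @rdname trainingHistory
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname trainingHistory
#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))

#' @rdname FeatureProfile-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname FeatureProfile-accessors
#' @export
setGeneric("profileKind", function(x) standardGeneric("profileKind"))
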