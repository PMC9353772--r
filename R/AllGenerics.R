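#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("neutralMass", function(x) standardGeneric("neutralMass"))

#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("classLabels<-", function(x, value) standardGeneric("classLabels<-"))

#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MassFeatureSet-accessors
#' @export
setGeneric("occurrenceMatrix", function(x) standardGeneric("occurrenceMatrix"))

#' @rdname MDBTable-accessors
#' @export
setGeneric("mdbLabels", function(x) standardGeneric("mdbLabels"))

#' @rdname MDBTable-accessors
#' @export
setGeneric("mdbMasses", function(x) standardGeneric("mdbMasses"))

#' @rdname MDBTable-accessors
#' @export
setGeneric("mdbCounts", function(x) standardGeneric("mdbCounts"))

#' @rdname MassDiffNet-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname MassDiffNet-accessors
#' @export
setGeneric("nodeMasses", function(x) standardGeneric("nodeMasses"))

#' @rdname MassDiffNet-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
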