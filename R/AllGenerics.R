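#' @include AllClasses.R
NULL

#' @rdname ProteinRecord
#' @param x a `ProteinRecord` or `TrackDataset`.
#' @export
setGeneric("seqString", function(x) standardGeneric("seqString"))

#' @rdname ProteinRecord
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname ProteinRecord
#' @export
setGeneric("trackLabels", function(x) standardGeneric("trackLabels"))

#' @rdname ProteinRecord
#' @export
setGeneric("trackPredictions", function(x) standardGeneric("trackPredictions"))

#' @rdname ProteinRecord
#' @param value replacement value.
#' @export
setGeneric("trackPredictions<-",
           function(x, value) standardGeneric("trackPredictions<-"))

#' @rdname ProteinRecord
#' @export
setGeneric("bindingClass", function(x) standardGeneric("bindingClass"))

#' @rdname ProteinRecord
#' @export
setGeneric("recordSource", function(x) standardGeneric("recordSource"))

#' @rdname ProteinRecord
#' @export
setGeneric("recordSplit", function(x) standardGeneric("recordSplit"))

#' @rdname ProteinRecord
#' @export
setGeneric("recordSplit<-", function(x, value) standardGeneric("recordSplit<-"))

#' @rdname TrackDataset
#' @param x a `TrackDataset`.
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname TrackDataset
#' @export
setGeneric("records", function(x) standardGeneric("records"))
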