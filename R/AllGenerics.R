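#' @rdname SequenceDataset-class
#' @param x,object An object.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname SequenceDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SequenceDataset-class
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))

#' @rdname SequenceDataset-class
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname KmerEmbedding-class
#' @param x An object.
#' @export
setGeneric("wordVectors", function(x) standardGeneric("wordVectors"))

#' @rdname KmerEmbedding-class
#' @export
setGeneric("contextVectors", function(x) standardGeneric("contextVectors"))

#' @rdname KmerEmbedding-class
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname KmerEmbedding-class
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname EvalReport-class
#' @param x An object.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname CVReport-class
#' @param x An object.
#' @export
setGeneric("foldReports", function(x) standardGeneric("foldReports"))
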