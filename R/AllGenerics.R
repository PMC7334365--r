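#' Accessors for package classes
#'
#' @param object an object of the documented class.
#' @return The slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("connWeights", function(object) standardGeneric("connWeights"))

#' @rdname accessors
#' @export
setMethod("connWeights", "Connectome", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("nodeVolumes", function(object) standardGeneric("nodeVolumes"))

#' @rdname accessors
#' @export
setMethod("nodeVolumes", "Connectome", function(object) object@nodeVolumes)

#' @rdname accessors
#' @export
setGeneric("streamlineCounts",
           function(object) standardGeneric("streamlineCounts"))

#' @rdname accessors
#' @export
setMethod("streamlineCounts", "Connectome",
          function(object) object@streamlineCounts)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setMethod("adjacency", "BinaryConnectome", function(object) object@adjacency)

#' @rdname accessors
#' @export
setGeneric("streamlines", function(object) standardGeneric("streamlines"))

#' @rdname accessors
#' @export
setMethod("streamlines", "StreamlineSet", function(object) object@streamlines)

#' @rdname accessors
#' @export
setGeneric("faVolume", function(object) standardGeneric("faVolume"))

#' @rdname accessors
#' @export
setMethod("faVolume", "TensorFieldPhantom", function(object) object@fa)

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setMethod("parcelLabels", "TensorFieldPhantom", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("parcelLabels", "Parcellation", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("regionVolumes", function(object) standardGeneric("regionVolumes"))

#' @rdname accessors
#' @export
setMethod("regionVolumes", "Parcellation",
          function(object) object@regionVolumes)
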