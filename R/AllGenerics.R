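#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("presentMask", function(x) standardGeneric("presentMask"))

#' @rdname signature-accessors
#' @export
setGeneric("sigWeights", function(x) standardGeneric("sigWeights"))

#' @rdname signature-accessors
#' @export
setGeneric("positiveSet", function(x) standardGeneric("positiveSet"))

#' @rdname signature-accessors
#' @export
setGeneric("negativeSet", function(x) standardGeneric("negativeSet"))

#' @rdname sam-accessors
#' @export
setGeneric("samStatistics", function(x) standardGeneric("samStatistics"))

#' @rdname sam-accessors
#' @export
setGeneric("expectedOrderStats", function(x) standardGeneric("expectedOrderStats"))

#' @rdname sam-accessors
#' @export
setGeneric("fudgeFactor", function(x) standardGeneric("fudgeFactor"))

#' @rdname sam-accessors
#' @export
setGeneric("deltaTable", function(x) standardGeneric("deltaTable"))

#' @rdname activity-accessors
#' @export
setGeneric("activityScores", function(x) standardGeneric("activityScores"))

#' @rdname dendrogram-accessors
#' @export
setGeneric("nodeCorrelations", function(x) standardGeneric("nodeCorrelations"))
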