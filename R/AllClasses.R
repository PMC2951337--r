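#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ExpressionMatrix: genes-by-samples log2 expression container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"exprs"} assay of log2-scale expression values. Missing observations
#' are encoded as \code{NA}; the presence mask is derived, not stored.
#' Gene identifiers are the rownames, sample identifiers the colnames.
#'
#' @slot ... inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- NULL
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v))
      msg <- c(msg, "'exprs' must be numeric")
    if (any(is.infinite(v)))
      msg <- c(msg, "present values must be finite (use NA for missing)")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must exist and be unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must exist and be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (log2 scale), \code{NA} for
#'   missing observations.
#' @param geneIds,sampleIds optional identifier vectors; default taken from
#'   \code{dimnames(values)}.
#' @param colData optional per-sample annotation (\code{DataFrame} or
#'   data.frame).
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             sampleIds = colnames(values), colData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(geneIds))
    stop("gene identifiers are required")
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = colData)
  new("ExpressionMatrix", se)
}

#' SamResult: output of a two-class unpaired SAM analysis
#'
#' Holds the per-gene observed relative-difference statistic d (original gene
#' order), the gene-specific scatter s, the fudge factor s0, the expected order
#' statistics dbar (aligned with d sorted ascending), the per-permutation
#' sorted-d matrix, and the delta calibration table.
#'
#' @slot d named numeric, observed statistic per gene.
#' @slot s named numeric, gene-specific scatter per gene.
#' @slot s0 numeric(1), fudge factor.
#' @slot dbar numeric, expected order statistics (ascending).
#' @slot dperm numeric matrix, permutations in columns, sorted d in rows.
#' @slot deltaTable data.frame with columns delta, nCalled,
#'   medianFalsePositives, fdr.
#' @slot nPerm integer(1), number of permutations used.
#' @slot enumerated logical(1), TRUE if all distinct labelings were enumerated.
#' @slot seed integer(1), seed used for sampled permutations (NA if enumerated).
#' @slot excluded character, genes dropped for insufficient per-class presence.
#' @export
setClass("SamResult",
  representation(d = "numeric", s = "numeric", s0 = "numeric",
                 dbar = "numeric", dperm = "matrix",
                 deltaTable = "data.frame", nPerm = "integer",
                 enumerated = "logical", seed = "integer",
                 excluded = "character"))

setValidity("SamResult", function(object) {
  msg <- NULL
  if (length(object@d) != length(object@dbar))
    msg <- c(msg, "d and dbar must have equal length")
  if (length(object@d) != length(object@s))
    msg <- c(msg, "d and s must have equal length")
  if (length(object@s0) != 1L || object@s0 < 0)
    msg <- c(msg, "s0 must be a single nonnegative value")
  if (nrow(object@dperm) > 0 && nrow(object@dperm) != length(object@d))
    msg <- c(msg, "dperm rows must match gene count")
  if (nrow(object@deltaTable) > 0) {
    if (!all(c("delta", "nCalled", "medianFalsePositives", "fdr") %in%
               names(object@deltaTable)))
      msg <- c(msg, "deltaTable must have delta/nCalled/medianFalsePositives/fdr")
    else {
      tab <- object@deltaTable[order(object@deltaTable$delta), ]
      if (is.unsorted(-tab$nCalled))
        msg <- c(msg, "nCalled must be non-increasing in delta")
      if (any(tab$fdr < 0 | tab$fdr > 1))
        msg <- c(msg, "reported FDR must lie in [0, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' GeneSignature: SAM-weighted gene signature
#'
#' Differentially expressed genes with their SAM statistics as weights,
#' partitioned by sign into a positive and a negative set.
#'
#' @slot geneIds character, signature gene identifiers.
#' @slot weights named numeric, SAM statistic per gene (no zeros).
#' @slot fdrThreshold numeric(1), the FDR cutoff used to derive the signature.
#' @slot name character(1), label for reports.
#' @export
setClass("GeneSignature",
  representation(geneIds = "character", weights = "numeric",
                 fdrThreshold = "numeric", name = "character"))

setValidity("GeneSignature", function(object) {
  msg <- NULL
  if (length(object@geneIds) != length(object@weights))
    msg <- c(msg, "geneIds and weights must have equal length")
  if (length(object@weights) && any(object@weights == 0))
    msg <- c(msg, "zero weights are not allowed in a signature")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "signature gene identifiers must be unique")
  if (is.null(msg)) TRUE else msg
})

#' GeneSignature constructor
#'
#' @param geneIds character vector of gene identifiers.
#' @param weights numeric vector of nonzero weights (SAM statistics).
#' @param fdrThreshold FDR cutoff the signature was derived at (NA if external).
#' @param name signature label.
#' @return A \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(geneIds, weights, fdrThreshold = NA_real_,
                          name = "signature") {
  geneIds <- as.character(geneIds)
  weights <- as.numeric(weights)
  names(weights) <- geneIds
  new("GeneSignature", geneIds = geneIds, weights = weights,
      fdrThreshold = as.numeric(fdrThreshold), name = as.character(name))
}

#' ActivityScores: per-sample signature activity
#'
#' @slot scores named numeric, inner-product activity per sample.
#' @slot nGenesMatched integer(1), signature genes found in the matrix.
#' @slot nGenesSignature integer(1), total signature size.
#' @slot signatureName character(1).
#' @slot centered logical(1), whether genes were median-centered first.
#' @export
setClass("ActivityScores",
  representation(scores = "numeric", nGenesMatched = "integer",
                 nGenesSignature = "integer", signatureName = "character",
                 centered = "logical"))

setValidity("ActivityScores", function(object) {
  msg <- NULL
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "activity scores must be finite")
  if (object@nGenesMatched > object@nGenesSignature)
    msg <- c(msg, "matched genes cannot exceed signature size")
  if (is.null(msg)) TRUE else msg
})

#' GeneDendrogram: correlation-based gene merge tree
#'
#' Agglomerative (average-linkage) tree over genes under centered Pearson
#' similarity. Each internal node carries a node correlation: the similarity
#' (1 - merge height) at which its two branches join. With average linkage the
#' node correlation is non-increasing from leaves toward the root.
#'
#' @slot merge integer matrix as in \code{\link[stats]{hclust}}: negative
#'   entries are leaves, positive entries earlier merges.
#' @slot nodeCorrelation numeric, similarity at each merge.
#' @slot labels character, leaf gene identifiers.
#' @slot order integer, leaf display order.
#' @export
setClass("GeneDendrogram",
  representation(merge = "matrix", nodeCorrelation = "numeric",
                 labels = "character", order = "integer"))

setValidity("GeneDendrogram", function(object) {
  msg <- NULL
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "merge must have (n leaves - 1) rows")
  if (length(object@nodeCorrelation) != nrow(object@merge))
    msg <- c(msg, "one node correlation per merge is required")
  if (length(object@nodeCorrelation) &&
      any(object@nodeCorrelation < -1 - 1e-8 | object@nodeCorrelation > 1 + 1e-8))
    msg <- c(msg, "node correlations must lie in [-1, 1]")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "leaf labels must be unique")
  if (is.null(msg)) TRUE else msg
})
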