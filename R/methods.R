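#' Accessors for ExpressionMatrix
#'
#' \code{geneIds} and \code{sampleIds} return the identifiers,
#' \code{exprValues} the numeric log2 matrix (NA = missing), and
#' \code{presentMask} the logical presence matrix.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return Identifier vectors, a numeric matrix, or a logical matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("presentMask", "ExpressionMatrix",
          function(x) !is.na(SummarizedExperiment::assay(x, "exprs")))

#' Accessors for GeneSignature
#'
#' @param x a \linkS4class{GeneSignature}.
#' @return \code{geneIds}: all signature genes; \code{sigWeights}: named
#'   weight vector; \code{positiveSet}/\code{negativeSet}: genes with
#'   positive/negative weight.
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
setMethod("geneIds", "GeneSignature", function(x) x@geneIds)

#' @rdname signature-accessors
#' @export
setMethod("sigWeights", "GeneSignature", function(x) x@weights)

#' @rdname signature-accessors
#' @export
setMethod("positiveSet", "GeneSignature",
          function(x) x@geneIds[x@weights > 0])

#' @rdname signature-accessors
#' @export
setMethod("negativeSet", "GeneSignature",
          function(x) x@geneIds[x@weights < 0])

#' Accessors for SamResult
#'
#' @param x a \linkS4class{SamResult}.
#' @return \code{samStatistics}: named observed d per gene;
#'   \code{expectedOrderStats}: dbar aligned with sorted d;
#'   \code{fudgeFactor}: s0; \code{deltaTable}: the delta calibration table.
#' @name sam-accessors
NULL

#' @rdname sam-accessors
#' @export
setMethod("samStatistics", "SamResult", function(x) x@d)

#' @rdname sam-accessors
#' @export
setMethod("expectedOrderStats", "SamResult", function(x) x@dbar)

#' @rdname sam-accessors
#' @export
setMethod("fudgeFactor", "SamResult", function(x) x@s0)

#' @rdname sam-accessors
#' @export
setMethod("deltaTable", "SamResult", function(x) x@deltaTable)

#' Accessors for ActivityScores and GeneDendrogram
#'
#' @param x an \linkS4class{ActivityScores} or \linkS4class{GeneDendrogram}.
#' @return \code{activityScores}: named per-sample score vector;
#'   \code{nodeCorrelations}: similarity at each merge;
#'   \code{geneIds}: dendrogram leaf labels.
#' @name activity-accessors
NULL

#' @rdname activity-accessors
#' @export
setMethod("activityScores", "ActivityScores", function(x) x@scores)

#' @rdname activity-accessors
#' @name dendrogram-accessors
#' @export
setMethod("nodeCorrelations", "GeneDendrogram", function(x) x@nodeCorrelation)

#' @rdname activity-accessors
#' @export
setMethod("geneIds", "GeneDendrogram", function(x) x@labels)

setMethod("show", "ExpressionMatrix", function(object) {
  v <- exprValues(object)
  cat("ExpressionMatrix:", nrow(v), "genes x", ncol(v), "samples\n")
  miss <- sum(is.na(v))
  cat(sprintf("  missing: %d values (%.2f%%)\n", miss,
              100 * miss / max(length(v), 1L)))
  callNextMethod()
})

setMethod("show", "SamResult", function(object) {
  cat("SamResult:", length(object@d), "genes\n")
  cat(sprintf("  s0 = %.4g; %d %s permutations\n", object@s0, object@nPerm,
              if (object@enumerated) "enumerated" else "sampled"))
  if (length(object@excluded))
    cat("  excluded (insufficient per-class presence):",
        length(object@excluded), "genes\n")
  if (nrow(object@deltaTable)) {
    cat("  delta table (first rows):\n")
    print(utils::head(object@deltaTable, 4L))
  }
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s': %d genes (%d positive, %d negative)",
              object@name, length(object@geneIds),
              sum(object@weights > 0), sum(object@weights < 0)))
  if (!is.na(object@fdrThreshold))
    cat(sprintf("; FDR < %g", object@fdrThreshold))
  cat("\n")
})

setMethod("show", "ActivityScores", function(object) {
  cat(sprintf("ActivityScores '%s': %d samples; %d/%d signature genes matched%s\n",
              object@signatureName, length(object@scores),
              object@nGenesMatched, object@nGenesSignature,
              if (object@centered) "; gene-median-centered" else ""))
})

setMethod("show", "GeneDendrogram", function(object) {
  cat("GeneDendrogram:", length(object@labels), "genes;",
      nrow(object@merge), "merges\n")
  if (length(object@nodeCorrelation))
    cat(sprintf("  node correlation range: [%.3f, %.3f]\n",
                min(object@nodeCorrelation), max(object@nodeCorrelation)))
})

#' Coerce a GeneDendrogram to hclust
#'
#' @param x a \linkS4class{GeneDendrogram}.
#' @param ... unused.
#' @return An object of class \code{hclust} (heights are
#'   1 - node correlation).
#' @export
as.hclust.GeneDendrogram <- function(x, ...) {
  structure(list(merge = x@merge, height = 1 - x@nodeCorrelation,
                 order = x@order, labels = x@labels,
                 method = "average", dist.method = "1 - pearson"),
            class = "hclust")
}
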