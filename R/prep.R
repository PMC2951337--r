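## Input/output, two-channel normalization, and the gene filters applied
## before differential-expression analysis.

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers, and tab-separated log2 values; blank cells (or NA) are
#' treated as missing. Duplicate gene identifiers are collapsed by per-gene
#' median (see \code{\link{collapseGenes}}) unless \code{collapse = FALSE}.
#'
#' @param path file path.
#' @param collapse collapse duplicate gene ids by median?
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, collapse = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  if (ncol(tab) < 2)
    stop("expected a gene-id column plus at least one sample column")
  ids <- tab[[1L]]
  sampleIds <- colnames(tab)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifiers in header")
  values <- vapply(tab[-1L], function(col) as.numeric(col),
                   numeric(nrow(tab)))
  values <- matrix(values, nrow = nrow(tab),
                   dimnames = list(NULL, sampleIds))
  if (anyDuplicated(ids)) {
    if (!collapse)
      stop("duplicate gene identifiers present and collapse = FALSE")
    rownames(values) <- NULL
    return(collapseGenes(values, ids))
  }
  rownames(values) <- ids
  ExpressionMatrix(values)
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: gene ids in the first
#' column, missing values as blank cells. Values are written in full
#' precision so read/write round-trips are bit-exact.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  chr <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  chr[is.na(v)] <- ""
  out <- data.frame(geneId = rownames(v), chr, stringsAsFactors = FALSE)
  colnames(out) <- c("geneId", colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Collapse duplicate gene identifiers by per-gene median
#'
#' Multiple probes mapping to one gene are summarized by the median of their
#' present values, per sample. Row order follows the first occurrence of each
#' identifier.
#'
#' @param values numeric matrix (probes in rows) or
#'   \linkS4class{ExpressionMatrix}.
#' @param ids gene identifier per row (ignored for ExpressionMatrix input,
#'   whose rownames are already unique).
#' @return An \linkS4class{ExpressionMatrix} with unique gene ids.
#' @export
collapseGenes <- function(values, ids = rownames(values)) {
  if (is(values, "ExpressionMatrix")) return(values)
  stopifnot(length(ids) == nrow(values))
  uniq <- unique(ids)
  if (length(uniq) == length(ids)) {
    rownames(values) <- ids
    return(ExpressionMatrix(values))
  }
  out <- matrix(NA_real_, length(uniq), ncol(values),
                dimnames = list(uniq, colnames(values)))
  idx <- split(seq_along(ids), factor(ids, levels = uniq))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1L) values[rows, ]
    else apply(values[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  ExpressionMatrix(out)
}

#' Lowess-normalize a two-channel spot table
#'
#' Computes M = log2(Cy5/Cy3) and A = log2(sqrt(Cy5*Cy3)) per spot and
#' removes the intensity-dependent dye bias by subtracting a lowess fit of M
#' on A (locally weighted linear regression with tricube weights and
#' robustness iterations, via \code{\link[stats]{lowess}}).
#'
#' @param spots data.frame with columns \code{probeId}, \code{cy3},
#'   \code{cy5} (nonnegative intensities). Spots with a nonpositive intensity
#'   in either channel are dropped with a warning.
#' @param span lowess smoother span in (0, 1].
#' @param iter robustness iterations.
#' @return The spot table with columns \code{A}, \code{M} (raw log-ratio),
#'   \code{fit} (estimated bias) and \code{Mnorm} (normalized log-ratio).
#' @examples
#' spots <- simulateTwoChannel(500, biasFn = function(a) 0.4 * sin(a), seed = 3)
#' norm <- lowessNormalize(spots)
#' head(norm$Mnorm)
#' @export
lowessNormalize <- function(spots, span = 0.4, iter = 3L) {
  req <- c("probeId", "cy3", "cy5")
  if (!all(req %in% names(spots)))
    stop("spot table needs columns probeId, cy3, cy5")
  if (span <= 0 || span > 1)
    stop("span must lie in (0, 1]")
  ok <- spots$cy3 > 0 & spots$cy5 > 0 & is.finite(spots$cy3) &
    is.finite(spots$cy5)
  if (sum(ok) < 20)
    stop("need at least 20 spots with positive intensity in both channels")
  if (any(!ok))
    warning(sum(!ok), " spots with nonpositive intensity dropped")
  sp <- spots[ok, , drop = FALSE]
  M <- log2(sp$cy5 / sp$cy3)
  A <- 0.5 * log2(sp$cy5 * sp$cy3)
  if (max(3, ceiling(span * length(A))) < 4)
    stop("span too small for the number of spots")
  fit <- stats::lowess(A, M, f = span, iter = iter)
  bias <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  sp$A <- A
  sp$M <- M
  sp$fit <- bias
  sp$Mnorm <- M - bias
  sp
}

#' Filter genes by channel intensity and presence
#'
#' Retains genes with usable data in at least \code{minPresent} of samples.
#' A sample counts as usable for a gene when its value is present
#' (non-missing) and, if raw channel intensities are supplied, both dye
#' channels are at least \code{minIntensity} units. With
#' \code{conjunctive = FALSE} the two clauses are evaluated independently:
#' the gene must pass the presence fraction and, separately, the
#' both-channels intensity fraction.
#'
#' The filter is idempotent and preserves row order.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param cy3,cy5 optional raw intensity matrices aligned with \code{x}
#'   (same dimnames); when omitted only the presence criterion applies.
#' @param minIntensity minimum absolute intensity in both channels.
#' @param minPresent minimum fraction of samples passing, in (0, 1].
#' @param conjunctive combine the intensity and presence clauses per sample
#'   (default) or as two independent fractions.
#' @return The filtered \linkS4class{ExpressionMatrix}.
#' @export
filterGenes <- function(x, cy3 = NULL, cy5 = NULL, minIntensity = 10,
                        minPresent = 0.70, conjunctive = TRUE) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (minPresent <= 0 || minPresent > 1)
    stop("minPresent must lie in (0, 1]")
  v <- exprValues(x)
  present <- !is.na(v)
  hasChannels <- !is.null(cy3) && !is.null(cy5)
  if (hasChannels) {
    cy3 <- as.matrix(cy3)[rownames(v), colnames(v), drop = FALSE]
    cy5 <- as.matrix(cy5)[rownames(v), colnames(v), drop = FALSE]
    bright <- !is.na(cy3) & !is.na(cy5) &
      cy3 >= minIntensity & cy5 >= minIntensity
  } else bright <- NULL
  n <- ncol(v)
  if (conjunctive || !hasChannels) {
    usable <- if (hasChannels) present & bright else present
    keep <- rowSums(usable) / n >= minPresent
  } else {
    keep <- rowSums(present) / n >= minPresent &
      rowSums(bright) / n >= minPresent
  }
  x[keep, ]
}

#' Median-center genes
#'
#' Subtracts each gene's median over its present values, so that per-gene
#' medians of the output are zero. Used before cross-dataset signature
#' projection and before correlation clustering.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return A centered \linkS4class{ExpressionMatrix}.
#' @export
medianCenter <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  med <- apply(v, 1L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  out <- v - med
  SummarizedExperiment::assay(x, "exprs") <- out
  x
}
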