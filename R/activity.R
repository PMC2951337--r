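## Signature-activity projection: inner product of SAM weights with sample
## expression profiles, and group comparison of the resulting scores.

#' Project a gene signature onto expression profiles
#'
#' Computes, per sample, the inner product of the signature gene weights with
#' the sample's expression values over the signature genes found in the
#' matrix: score_j = sum_i w_i x_ij. The result is a relative activity
#' measure of the signature, comparable only within the projected dataset.
#'
#' Genes are matched by exact identifier after upper-casing; unmatched
#' signature genes are dropped and counted. By default the matrix is
#' gene-median-centered first, making the score a contrast; missing values
#' contribute 0 after centering.
#'
#' @param signature a \linkS4class{GeneSignature}, or a named numeric weight
#'   vector (zero weights are then permitted and contribute nothing).
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param center gene-median-center the matrix before projecting?
#' @param normalize \code{"none"} (plain inner product, default) or
#'   \code{"mean"} (divide by the number of matched genes, for comparisons
#'   across signatures with unequal coverage).
#' @return An \linkS4class{ActivityScores}.
#' @examples
#' sig <- GeneSignature(c("A", "B", "C"), c(2, -1, 0.5))
#' m <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' activityScores(projectSignature(sig, ExpressionMatrix(m), center = FALSE))
#' @export
projectSignature <- function(signature, x, center = TRUE,
                             normalize = c("none", "mean")) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (is.numeric(signature)) {
    if (is.null(names(signature)))
      stop("a raw weight vector must be named by gene id")
    nTotal <- length(signature)
    w0 <- signature[signature != 0]  # zero weights are inert in an inner product
    if (!length(w0)) {
      scores <- stats::setNames(rep(0, ncol(x)), sampleIds(x))
      return(new("ActivityScores", scores = scores, nGenesMatched = 0L,
                 nGenesSignature = as.integer(nTotal),
                 signatureName = "weights", centered = isTRUE(center)))
    }
    signature <- GeneSignature(names(w0), w0, name = "weights")
  } else stopifnot(is(signature, "GeneSignature"))
  normalize <- match.arg(normalize)
  if (center) x <- medianCenter(x)
  v <- exprValues(x)
  rowKey <- toupper(rownames(v))
  sigKey <- toupper(geneIds(signature))
  hit <- match(sigKey, rowKey)
  matched <- which(!is.na(hit))
  if (!length(matched))
    stop("no signature genes found in the expression matrix")
  w <- sigWeights(signature)[matched]
  sub <- v[hit[matched], , drop = FALSE]
  sub[is.na(sub)] <- 0
  scores <- as.numeric(crossprod(sub, w))
  if (normalize == "mean") scores <- scores / length(matched)
  names(scores) <- colnames(v)
  new("ActivityScores", scores = scores,
      nGenesMatched = length(matched),
      nGenesSignature = length(geneIds(signature)),
      signatureName = signature@name, centered = isTRUE(center))
}

#' Compare signature activity across sample groups
#'
#' One-way ANOVA of the activity scores on a grouping factor, with
#' boxplot-ready per-group summaries (n, quartiles, mean).
#'
#' @param scores an \linkS4class{ActivityScores} or named numeric vector.
#' @param groups factor over the same samples; at least two groups with at
#'   least two samples each.
#' @return A list with \code{statistic} (the ANOVA F), \code{df} (numerator,
#'   denominator), \code{pValue}, and \code{summary} (per-group data.frame).
#' @export
compareActivity <- function(scores, groups) {
  s <- if (is(scores, "ActivityScores")) activityScores(scores) else scores
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(s) != length(groups))
    stop("one group label per score is required")
  sizes <- table(groups)
  if (length(sizes) < 2)
    stop("at least two groups are required")
  if (any(sizes < 2))
    stop("every group needs at least two samples")
  fit <- stats::aov(s ~ groups)
  an <- stats::anova(fit)
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    x <- s[groups == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(x), q1 = q[1], median = q[2],
               q3 = q[3], mean = mean(x), stringsAsFactors = FALSE)
  }))
  list(statistic = an[["F value"]][1L],
       df = c(an[["Df"]][1L], an[["Df"]][2L]),
       pValue = an[["Pr(>F)"]][1L],
       summary = summ)
}
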