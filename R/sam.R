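## Two-class unpaired Significance Analysis of Microarrays (SAM):
## relative-difference statistic d = (mean2 - mean1) / (s + s0), fudge-factor
## tuning, permutation null of expected order statistics, asymmetric delta
## cutpoints, and median-false-positive FDR estimation.

# Per-gene numerator and scatter for a two-class split.
# v: genes x samples (NA = missing); cls2: logical, TRUE = class 2.
# s is the pooled SD scaled by sqrt(1/n1 + 1/n2).
.samParts <- function(v, cls2) {
  present <- !is.na(v)
  v0 <- v
  v0[!present] <- 0
  p1 <- present[, !cls2, drop = FALSE]
  p2 <- present[, cls2, drop = FALSE]
  n1 <- rowSums(p1)
  n2 <- rowSums(p2)
  sum1 <- rowSums(v0[, !cls2, drop = FALSE])
  sum2 <- rowSums(v0[, cls2, drop = FALSE])
  m1 <- sum1 / n1
  m2 <- sum2 / n2
  ss1 <- rowSums(v0[, !cls2, drop = FALSE]^2) - n1 * m1^2
  ss2 <- rowSums(v0[, cls2, drop = FALSE]^2) - n2 * m2^2
  pooled <- (ss1 + ss2) / (n1 + n2 - 2)
  pooled[pooled < 0] <- 0  # guard against tiny negative rounding error
  list(r = m2 - m1,
       s = sqrt((1 / n1 + 1 / n2) * pooled),
       n1 = n1, n2 = n2)
}

.checkLabels <- function(v, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two class labels are required")
  if (length(labels) != ncol(v))
    stop("one label per sample is required")
  labels
}

#' SAM relative-difference statistic
#'
#' Computes the per-gene SAM statistic d = (mean2 - mean1) / (s + s0), where
#' s is the pooled standard deviation scaled by sqrt(1/n1 + 1/n2) and s0 is
#' the fudge factor. With s0 = 0 this is exactly the classical
#' pooled-variance two-sample t statistic. Genes with fewer than two present
#' values in either class are excluded with a warning.
#'
#' @param x an \linkS4class{ExpressionMatrix} or numeric matrix
#'   (genes x samples).
#' @param labels two-level factor over samples; d is oriented as the second
#'   level's mean minus the first level's mean, so swapping the levels
#'   negates every d.
#' @param s0 nonnegative fudge factor.
#' @return Named numeric vector of d, with the gene-specific scatter s as
#'   attribute \code{"s"} and excluded gene ids as attribute
#'   \code{"excluded"}.
#' @examples
#' sim <- simulateKnockdown(nGenes = 50, seed = 1)
#' d <- samStatistic(sim$expression, sim$labels, s0 = 0.1)
#' @export
samStatistic <- function(x, labels, s0 = 0) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  labels <- .checkLabels(v, labels)
  if (s0 < 0) stop("s0 must be nonnegative")
  cls2 <- labels == levels(labels)[2L]
  parts <- .samParts(v, cls2)
  bad <- parts$n1 < 2 | parts$n2 < 2
  if (any(bad)) {
    warning(sum(bad), " genes with < 2 present values in a class excluded")
  }
  d <- parts$r / (parts$s + s0)
  d[parts$s + s0 == 0] <- 0  # zero scatter and zero s0: define 0/0 as no change
  d <- d[!bad]
  s <- parts$s[!bad]
  names(d) <- rownames(v)[!bad]
  names(s) <- names(d)
  attr(d, "s") <- s
  attr(d, "excluded") <- rownames(v)[bad]
  d
}

#' Estimate the SAM fudge factor s0
#'
#' Searches the percentiles {0, 5, ..., 100} of the gene-specific scatter s
#' for the value that minimizes the coefficient of variation of the median
#' absolute deviation of d = r / (s + s0) computed within 100 s-quantile
#' windows. Ties are broken toward the lowest percentile.
#'
#' @param numer per-gene numerator (mean difference) r.
#' @param s per-gene scatter.
#' @return s0 (a single nonnegative number), with the chosen percentile as
#'   attribute \code{"percentile"}.
#' @export
estimateS0 <- function(numer, s) {
  stopifnot(length(numer) == length(s))
  if (length(s) < 2) return(structure(0, percentile = 0))
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE, type = 7)
  brk <- unique(stats::quantile(s, seq(0, 1, length.out = 101),
                                names = FALSE))
  grp <- if (length(brk) > 2)
    cut(s, breaks = brk, include.lowest = TRUE)
  else factor(rep(1L, length(s)))
  cvs <- vapply(cand, function(s0a) {
    d <- numer / (s + s0a)
    d[s + s0a == 0] <- 0
    mads <- tapply(d, grp, stats::mad)
    mads <- mads[!is.na(mads)]
    m <- mean(mads)
    if (m == 0) return(if (stats::sd(mads) == 0 || length(mads) < 2) 0 else Inf)
    stats::sd(mads) / m
  }, numeric(1))
  cvs[!is.finite(cvs)] <- Inf
  best <- which.min(cvs)  # which.min takes the first (lowest-percentile) tie
  structure(cand[best], percentile = 100 * alphas[best])
}

#' Permutation null for SAM
#'
#' Builds the permutation distribution of the SAM statistic by reassigning
#' class labels. When the number of distinct label assignments
#' choose(n, n1) is at most \code{enumerationLimit}, all assignments are
#' enumerated exactly once (the result is then seed-independent); otherwise
#' \code{nPerm} seeded random shuffles are drawn. The expected order
#' statistics dbar are the means of the sorted permuted d.
#'
#' @param x expression matrix (or \linkS4class{ExpressionMatrix}).
#' @param labels two-level factor over samples.
#' @param s0 fudge factor (held fixed across permutations).
#' @param nPerm permutations to sample when not enumerating.
#' @param seed integer seed for sampled permutations.
#' @param enumerationLimit enumerate exhaustively when the number of
#'   distinct assignments does not exceed this.
#' @return A list with \code{dbar} (ascending expected order statistics),
#'   \code{dperm} (genes x permutations matrix of sorted permuted d),
#'   \code{nPerm}, and \code{enumerated}.
#' @export
permutationNull <- function(x, labels, s0, nPerm = 1000L, seed = NULL,
                            enumerationLimit = 10000L) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  labels <- .checkLabels(v, labels)
  cls2obs <- labels == levels(labels)[2L]
  parts <- .samParts(v, cls2obs)
  keep <- !(parts$n1 < 2 | parts$n2 < 2)
  v <- v[keep, , drop = FALSE]
  n <- ncol(v)
  n2 <- sum(cls2obs)
  nAssign <- choose(n, n2)
  enumerated <- nAssign <= enumerationLimit
  if (!enumerated && nPerm < 1)
    stop("nPerm must be at least 1 when not enumerating")
  permStat <- function(cls2) {
    p <- .samParts(v, cls2)
    d <- p$r / (p$s + s0)
    d[p$s + s0 == 0] <- 0
    d[p$n1 < 2 | p$n2 < 2] <- NA_real_
    sort(d, na.last = TRUE)
  }
  if (enumerated) {
    sets <- utils::combn(n, n2)
    dperm <- apply(sets, 2L, function(idx) {
      cls2 <- rep(FALSE, n)
      cls2[idx] <- TRUE
      permStat(cls2)
    })
    nPermUsed <- ncol(sets)
  } else {
    dperm <- withSeed(seed, {
      vapply(seq_len(nPerm), function(b) {
        cls2 <- rep(FALSE, n)
        cls2[sample.int(n, n2)] <- TRUE
        permStat(cls2)
      }, numeric(nrow(v)))
    })
    nPermUsed <- nPerm
  }
  list(dbar = rowMeans(dperm, na.rm = TRUE), dperm = dperm,
       nPerm = as.integer(nPermUsed), enumerated = enumerated)
}

#' Call significant genes at a delta threshold
#'
#' Sorts d ascending against the expected order statistics dbar and places
#' asymmetric cutpoints: the up cutpoint is the smallest observed d whose
#' displacement d - dbar is at least delta (all genes with d at or above it
#' are called up-regulated); symmetrically, the low cutpoint is the largest
#' observed d displaced below the identity line by at least delta.
#'
#' @param d named observed statistics (original gene order).
#' @param dbar expected order statistics, ascending, same length.
#' @param delta nonnegative band half-width; \code{Inf} calls nothing.
#' @return A list with \code{up}, \code{down} (gene id vectors),
#'   \code{cutUp}, \code{cutLow}.
#' @export
callSignificant <- function(d, dbar, delta) {
  if (delta < 0) stop("delta must be nonnegative")
  stopifnot(length(d) == length(dbar))
  ord <- order(d)  # stable: ties keep gene-index order
  dsort <- d[ord]
  disp <- dsort - dbar
  upIdx <- which(disp >= delta)
  lowIdx <- which(disp <= -delta)
  cutUp <- if (length(upIdx)) dsort[min(upIdx)] else Inf
  cutLow <- if (length(lowIdx)) dsort[max(lowIdx)] else -Inf
  list(up = names(d)[d >= cutUp],
       down = names(d)[d <= cutLow],
       cutUp = unname(cutUp), cutLow = unname(cutLow))
}

#' Delta calibration table with permutation FDR
#'
#' For each delta on a grid, counts the genes called on the observed data and
#' the median, over permutations, of permuted statistics falling beyond the
#' same cutpoints. FDR = median false positives / max(called, 1), optionally
#' scaled by an estimate of the true-null proportion pi0, and reported
#' clipped to [0, 1].
#'
#' @param d named observed statistics.
#' @param dbar expected order statistics (ascending).
#' @param dperm sorted permuted statistics, permutations in columns.
#' @param deltaGrid increasing nonnegative deltas.
#' @param pi0Correct multiply the false-positive count by the estimated
#'   true-null proportion (default FALSE: the plain median-false-positive
#'   definition).
#' @return data.frame with columns delta, nCalled, medianFalsePositives, fdr.
#' @export
fdrTable <- function(d, dbar, dperm, deltaGrid, pi0Correct = FALSE) {
  if (!length(deltaGrid)) stop("empty delta grid")
  deltaGrid <- sort(deltaGrid)
  pi0 <- 1
  if (pi0Correct) {
    qq <- stats::quantile(dperm, c(0.25, 0.75), na.rm = TRUE)
    pi0 <- min(1, sum(d > qq[1] & d < qq[2]) / (0.5 * length(d)))
  }
  rows <- lapply(deltaGrid, function(delta) {
    cuts <- callSignificant(d, dbar, delta)
    nCalled <- length(unique(c(cuts$up, cuts$down)))
    falsePerPerm <- colSums(dperm >= cuts$cutUp | dperm <= cuts$cutLow,
                            na.rm = TRUE)
    medFalse <- stats::median(falsePerPerm) * pi0
    data.frame(delta = delta, nCalled = nCalled,
               medianFalsePositives = medFalse,
               fdr = min(1, medFalse / max(nCalled, 1)))
  })
  do.call(rbind, rows)
}

#' Run a full two-class unpaired SAM analysis
#'
#' Orchestrates the SAM engine: computes the gene-specific scatter, tunes the
#' fudge factor s0 (unless supplied), builds the permutation null
#' (enumerating all label assignments when feasible), and tabulates FDR over
#' a delta grid derived from the observed displacements.
#'
#' @param x an \linkS4class{ExpressionMatrix} or numeric matrix.
#' @param labels two-level factor over samples.
#' @param s0 fudge factor; \code{NULL} (default) tunes it from the data.
#' @param nPerm sampled permutations when enumeration is infeasible.
#' @param seed integer seed for sampled permutations.
#' @param enumerationLimit see \code{\link{permutationNull}}.
#' @param deltaGrid deltas for the calibration table; default: 101 quantiles
#'   of the absolute observed displacements (plus zero).
#' @param pi0Correct see \code{\link{fdrTable}}.
#' @return A \linkS4class{SamResult}.
#' @examples
#' sim <- simulateKnockdown(nGenes = 200, seed = 2)
#' res <- runSam(sim$expression, sim$labels, seed = 2)
#' res
#' @export
runSam <- function(x, labels, s0 = NULL, nPerm = 1000L, seed = NULL,
                   enumerationLimit = 10000L, deltaGrid = NULL,
                   pi0Correct = FALSE) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  labels <- .checkLabels(v, labels)
  cls2 <- labels == levels(labels)[2L]
  parts <- .samParts(v, cls2)
  bad <- parts$n1 < 2 | parts$n2 < 2
  excluded <- rownames(v)[bad]
  if (length(excluded))
    warning(length(excluded),
            " genes with < 2 present values in a class excluded")
  numer <- parts$r[!bad]
  s <- parts$s[!bad]
  if (is.null(s0)) s0 <- as.numeric(estimateS0(numer, s))
  d <- numer / (s + s0)
  d[s + s0 == 0] <- 0
  names(d) <- rownames(v)[!bad]
  names(s) <- names(d)
  null <- permutationNull(v, labels, s0 = s0, nPerm = nPerm, seed = seed,
                          enumerationLimit = enumerationLimit)
  if (is.null(deltaGrid)) {
    disp <- abs(sort(d) - null$dbar)
    deltaGrid <- sort(unique(c(0, stats::quantile(disp, seq(0, 1, 0.01),
                                                  names = FALSE))))
  }
  tab <- fdrTable(d, null$dbar, null$dperm, deltaGrid,
                  pi0Correct = pi0Correct)
  new("SamResult", d = d, s = s, s0 = as.numeric(s0), dbar = null$dbar,
      dperm = null$dperm, deltaTable = tab, nPerm = null$nPerm,
      enumerated = null$enumerated,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      excluded = as.character(excluded))
}

#' Derive a SAM-weighted gene signature at an FDR threshold
#'
#' Selects the smallest delta whose estimated FDR is below the threshold and
#' returns the genes called there, weighted by their observed SAM statistic
#' and partitioned by sign. If no delta achieves the threshold an empty
#' signature is returned with a message.
#'
#' @param samResult a \linkS4class{SamResult}.
#' @param fdrThreshold target FDR in (0, 1).
#' @param name signature label.
#' @return A \linkS4class{GeneSignature}.
#' @export
deriveSignature <- function(samResult, fdrThreshold = 0.01,
                            name = "signature") {
  stopifnot(is(samResult, "SamResult"))
  if (fdrThreshold <= 0 || fdrThreshold >= 1)
    stop("fdrThreshold must lie in (0, 1)")
  tab <- samResult@deltaTable
  ok <- tab$fdr < fdrThreshold
  if (!any(ok)) {
    message("no delta achieves FDR < ", fdrThreshold,
            "; returning an empty signature")
    return(GeneSignature(character(0), numeric(0), fdrThreshold, name))
  }
  delta <- min(tab$delta[ok])
  cuts <- callSignificant(samResult@d, samResult@dbar, delta)
  called <- c(cuts$up, cuts$down)
  w <- samResult@d[called]
  keep <- w != 0
  GeneSignature(called[keep], w[keep], fdrThreshold, name)
}
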