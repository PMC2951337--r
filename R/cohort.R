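## Expression-stratified survival association and the cohort-level group
## tests: median split, Kaplan-Meier curves, log-rank, ANOVA/t, chi-square
## for response, and growth-curve doubling time.

#' Split samples into high/low halves by ranked expression
#'
#' Ranks values high-to-low and labels the top ceiling(n/2) "high", the rest
#' "low". Ties are broken by stable input order, so the split is
#' deterministic; missing values always fall in the "low" half.
#'
#' @param values numeric vector (at least 2 non-missing).
#' @return Factor with levels \code{c("high", "low")}, aligned with the
#'   input.
#' @examples
#' rankSplit(c(4, 3, 2, 1))
#' @export
rankSplit <- function(values) {
  if (sum(!is.na(values)) < 2)
    stop("need at least 2 non-missing values")
  ord <- order(values, decreasing = TRUE, na.last = TRUE)
  nHigh <- ceiling(length(values) / 2)
  out <- rep("low", length(values))
  out[ord[seq_len(nHigh)]] <- "high"
  factor(out, levels = c("high", "low"))
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator via \code{\link[survival]{survfit}}; censored
#' subjects reduce the at-risk count without producing steps.
#'
#' @param times positive follow-up times.
#' @param events logical (or 0/1) event indicators.
#' @param groups optional grouping factor (single group when omitted).
#' @return data.frame with columns group, time, nRisk, nEvent, survival.
#' @export
kmEstimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("negative survival times")
  events <- as.integer(as.logical(events))
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(groups)[1L], length(sm$time))
  else sub("^groups=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, nRisk = sm$n.risk,
             nEvent = sm$n.event, survival = sm$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic (via
#' \code{\link[survival]{survdiff}}), asymptotically chi-square with
#' (groups - 1) degrees of freedom. A naive 2x2 chi-square on death counts
#' (ignoring follow-up time) is available for sensitivity checks.
#'
#' @param times positive follow-up times.
#' @param events logical event indicators.
#' @param groups factor with at least two levels present.
#' @param method \code{"logrank"} (default) or \code{"naive2x2"}.
#' @return list(statistic, df, pValue).
#' @export
logrankTest <- function(times, events, groups,
                        method = c("logrank", "naive2x2")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("at least two groups are required")
  events <- as.integer(as.logical(events))
  if (sum(events) < 1) stop("at least one event is required")
  if (method == "naive2x2") {
    tab <- table(groups, factor(events, levels = 0:1))
    return(pcrChisq(as.matrix(tab)))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       pValue = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Expression-versus-group association tests
#'
#' Two groups: two-sided two-sample t test (pooled by default, Welch
#' optionally). More than two groups: one-way ANOVA.
#'
#' @param expr numeric expression values.
#' @param labels grouping factor.
#' @param welch use Welch's unequal-variance t test for the 2-group case?
#' @return list(test, statistic, df, pValue).
#' @export
expressionGroupTests <- function(expr, labels, welch = FALSE) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("at least two groups are required")
  if (any(table(labels) < 2)) stop("every group needs at least two samples")
  if (nlevels(labels) == 2L) {
    tt <- stats::t.test(expr ~ labels, var.equal = !welch)
    list(test = if (welch) "welch-t" else "t",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         pValue = tt$p.value)
  } else {
    an <- stats::anova(stats::aov(expr ~ labels))
    list(test = "anova", statistic = an[["F value"]][1L],
         df = c(an[["Df"]][1L], an[["Df"]][2L]),
         pValue = an[["Pr(>F)"]][1L])
  }
}

#' Pearson chi-square on a 2x2 contingency table
#'
#' Used for response-by-expression-half association (e.g., pathological
#' complete response versus high/low marker expression). No continuity
#' correction by default.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correct apply the Yates continuity correction?
#' @return list(statistic, df, pValue).
#' @examples
#' pcrChisq(matrix(c(10, 20, 20, 10), 2))
#' @export
pcrChisq <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("a 2x2 table is required")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the table")
  ct <- stats::chisq.test(counts, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       pValue = ct$p.value)
}

#' Doubling time from a growth curve
#'
#' Ordinary least squares of log2(count) on time; the doubling time is the
#' reciprocal of the slope. Non-growing cultures (slope <= 0) are flagged
#' and return \code{NA} hours.
#'
#' @param counts positive cell counts (at least 3).
#' @param timesH observation times in hours.
#' @return list(doublingTime (hours), slope, r2, growing).
#' @examples
#' doublingTime(c(1e5, 2e5, 4e5, 8e5), c(0, 24, 48, 72))
#' @export
doublingTime <- function(counts, timesH) {
  if (length(counts) < 3) stop("need at least 3 counts")
  if (any(counts <= 0)) stop("counts must be positive")
  if (length(counts) != length(timesH)) stop("counts and times must align")
  fit <- stats::lm(log2(counts) ~ timesH)
  slope <- unname(stats::coef(fit)[2L])
  growing <- is.finite(slope) && slope > 0
  if (!growing) warning("non-positive growth slope; culture not growing")
  # summary.lm warns on an exactly exponential input; a perfect fit is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(doublingTime = if (growing) 1 / slope else NA_real_,
       slope = slope, r2 = r2, growing = growing)
}

#' Survival association of a gene's expression in a cohort
#'
#' Convenience wrapper reproducing the cohort workflow: rank-split the
#' gene's expression into halves, estimate Kaplan-Meier curves per half, and
#' test the difference by log-rank, optionally restricted to a subset of
#' subtypes.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param clinical data.frame with sampleId, osTime, osEvent (and subtype).
#' @param gene gene identifier to stratify on.
#' @param subtypes optional subtype labels to restrict to.
#' @return list(split, km, logrank, n).
#' @export
survivalByExpression <- function(x, clinical, gene, subtypes = NULL) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!gene %in% geneIds(x)) stop("gene '", gene, "' not in matrix")
  idx <- match(clinical$sampleId, sampleIds(x))
  if (any(is.na(idx))) stop("clinical samples missing from the matrix")
  keep <- if (is.null(subtypes)) rep(TRUE, nrow(clinical))
  else clinical$subtype %in% subtypes
  cl <- clinical[keep, , drop = FALSE]
  expr <- exprValues(x)[gene, idx[keep]]
  split <- rankSplit(expr)
  list(split = split,
       km = kmEstimate(cl$osTime, cl$osEvent, split),
       logrank = logrankTest(cl$osTime, cl$osEvent, split),
       n = nrow(cl))
}
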