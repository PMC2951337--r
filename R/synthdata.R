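## Seeded generators for every input shape the pipeline consumes.
## Each generator emits its ground truth (DE set, planted population,
## pre-bias log-ratios) so downstream recovery can be tested.

# Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Simulate a two-class knockdown experiment
#'
#' Generates a genes-by-samples log2 expression matrix emulating a small
#' two-channel knockdown study (defaults: 5 knockdown vs 6 control arrays)
#' with a planted fraction of differentially expressed genes. The planted DE
#' gene set is returned alongside the matrix for recovery testing.
#'
#' Gene-level noise is heteroscedastic by default: per-gene variance is drawn
#' from a scaled inverse-chi-square (an inverse-gamma) with \code{varDf}
#' degrees of freedom and scale \code{sigma^2}, so that low-variance genes
#' exist and the SAM fudge factor has something to regularize. Set
#' \code{heteroscedastic = FALSE} for equal-variance draws (useful when
#' checking the t-statistic limit).
#'
#' @param nGenes number of genes.
#' @param nClass1,nClass2 samples per class (class 1 = control, class 2 =
#'   knockdown); both must be >= 2.
#' @param deFraction proportion of genes with a planted shift, in [0, 1];
#'   exactly \code{round(deFraction * nGenes)} genes are shifted.
#' @param effectSize log2 mean shift of planted genes in class 2 relative to
#'   class 1 (magnitude; see \code{deSign}).
#' @param sigma noise scale (per-gene SD when homoscedastic; the
#'   inverse-chi-square scale otherwise).
#' @param heteroscedastic draw per-gene SDs from the inverse-gamma-like prior?
#' @param varDf degrees of freedom of the variance prior.
#' @param deSign \code{"both"} alternates the sign of the planted shift across
#'   DE genes (so both up- and down-regulated genes exist); \code{"up"} or
#'   \code{"down"} forces one direction.
#' @param missingRate proportion of entries set missing completely at random.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list with \code{expression} (\linkS4class{ExpressionMatrix} with
#'   a \code{class} column in \code{colData}), \code{labels} (factor), and
#'   \code{trueDe} (character vector of planted gene ids, with the signed
#'   shift as a named attribute \code{"shift"}).
#' @examples
#' sim <- simulateKnockdown(nGenes = 100, seed = 1)
#' length(sim$trueDe)
#' @export
simulateKnockdown <- function(nGenes = 1000L, nClass1 = 6L, nClass2 = 5L,
                              deFraction = 0.1, effectSize = 2, sigma = 0.5,
                              heteroscedastic = TRUE, varDf = 6,
                              deSign = c("both", "up", "down"),
                              missingRate = 0, seed = NULL) {
  deSign <- match.arg(deSign)
  if (nGenes < 1 || nClass1 < 2 || nClass2 < 2)
    stop("nGenes must be positive and both classes need >= 2 samples")
  if (deFraction < 0 || deFraction > 1)
    stop("deFraction must lie in [0, 1]")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  withSeed(seed, {
    n <- nClass1 + nClass2
    genes <- sprintf("G%04d", seq_len(nGenes))
    labels <- factor(rep(c("class1", "class2"), c(nClass1, nClass2)),
                     levels = c("class1", "class2"))
    samples <- paste0(ifelse(labels == "class1", "ctrl", "kd"),
                      c(seq_len(nClass1), seq_len(nClass2)))
    nDe <- round(deFraction * nGenes)
    deIdx <- if (nDe > 0) sort(sample.int(nGenes, nDe)) else integer(0)
    shiftSign <- switch(deSign,
      both = rep_len(c(1, -1), nDe),
      up = rep(1, nDe),
      down = rep(-1, nDe))
    baseline <- stats::rnorm(nGenes, 0, 1)
    sdGene <- if (heteroscedastic)
      sigma * sqrt(varDf / stats::rchisq(nGenes, df = varDf))
    else rep(sigma, nGenes)
    mu <- matrix(baseline, nGenes, n)
    if (nDe > 0)
      mu[deIdx, labels == "class2"] <-
        mu[deIdx, labels == "class2"] + shiftSign * effectSize
    noise <- matrix(stats::rnorm(nGenes * n), nGenes, n) * sdGene
    values <- mu + noise
    if (missingRate > 0)
      values[stats::runif(length(values)) < missingRate] <- NA_real_
    dimnames(values) <- list(genes, samples)
    trueDe <- genes[deIdx]
    attr(trueDe, "shift") <- shiftSign * effectSize
    em <- ExpressionMatrix(values,
                           colData = S4Vectors::DataFrame(class = labels,
                                                          row.names = samples))
    list(expression = em, labels = labels, trueDe = trueDe)
  })
}

#' Simulate a tumor cohort with subtype structure and survival
#'
#' Emulates a breast-tumor cohort: five molecular subtypes, a marker gene and
#' a block of signature genes shifted per subtype, and exponential overall
#' survival whose per-sample hazard depends on the marker gene's expression:
#' hazard_i = baselineHazard * exp(logHazardRatio * x_marker,i). Censoring is
#' independent exponential, calibrated so roughly \code{censorRate} of
#' subjects are censored (none when \code{censorRate = 0}).
#'
#' Default group sizes mirror a 147-tumor cohort without adjuvant
#' chemotherapy (LumA 50, LumB 34, HER2 29, Basal 24, Claudin-low 10).
#'
#' @param nPerSubtype named integer vector of samples per subtype; all > 0.
#' @param nGenes total genes in the matrix (>= signatureGenes + 1).
#' @param signatureGenes number of subtype-shifted genes (besides the marker).
#' @param subtypeShift named numeric, mean log2 shift of marker and signature
#'   genes per subtype.
#' @param noiseSd residual SD of expression values.
#' @param baselineHazard events per time unit for a sample with marker
#'   expression 0; must be > 0.
#' @param logHazardRatio change in log hazard per unit marker expression
#'   (0 = survival unrelated to expression).
#' @param censorRate target proportion censored, in [0, 1).
#' @param pcrLogOdds change in log-odds of pathological complete response per
#'   unit marker expression.
#' @param markerGene identifier given to the marker gene.
#' @param seed integer seed.
#' @return A list with \code{expression} (\linkS4class{ExpressionMatrix}),
#'   \code{clinical} (data.frame: sampleId, subtype, osTime, osEvent, size,
#'   grade, pcr), \code{markerGene}, and \code{signatureGenes}.
#' @examples
#' cohort <- simulateCohort(seed = 1)
#' table(cohort$clinical$subtype)
#' @export
simulateCohort <- function(nPerSubtype = c(LumA = 50L, LumB = 34L, HER2 = 29L,
                                           Basal = 24L, `Claudin-low` = 10L),
                           nGenes = 200L, signatureGenes = 50L,
                           subtypeShift = c(LumA = 1, LumB = 0.7, HER2 = -0.3,
                                            Basal = -1, `Claudin-low` = -0.7),
                           noiseSd = 1, baselineHazard = 0.05,
                           logHazardRatio = -0.5, censorRate = 0.3,
                           pcrLogOdds = -0.7, markerGene = "MYB",
                           seed = NULL) {
  if (is.null(names(nPerSubtype)) || any(nPerSubtype < 1))
    stop("nPerSubtype must be a named vector of positive counts")
  if (!all(names(nPerSubtype) %in% names(subtypeShift)))
    stop("subtypeShift must cover every subtype")
  if (baselineHazard <= 0)
    stop("baselineHazard must be positive")
  if (censorRate < 0 || censorRate >= 1)
    stop("censorRate must lie in [0, 1)")
  if (nGenes < signatureGenes + 1)
    stop("nGenes must accommodate the marker and signature genes")
  withSeed(seed, {
    subtype <- factor(rep(names(nPerSubtype), nPerSubtype),
                      levels = names(nPerSubtype))
    n <- length(subtype)
    samples <- sprintf("T%03d", seq_len(n))
    shift <- subtypeShift[as.character(subtype)]
    sigIds <- sprintf("SIG%03d", seq_len(signatureGenes))
    bgIds <- sprintf("BG%03d", seq_len(nGenes - signatureGenes - 1L))
    genes <- c(markerGene, sigIds, bgIds)
    nShifted <- 1L + signatureGenes
    mu <- rbind(matrix(rep(shift, each = nShifted), nShifted, n),
                matrix(0, nGenes - nShifted, n))
    values <- mu + matrix(stats::rnorm(nGenes * n, 0, noiseSd), nGenes, n)
    dimnames(values) <- list(genes, samples)
    marker <- values[markerGene, ]
    hazard <- baselineHazard * exp(logHazardRatio * marker)
    eventTime <- stats::rexp(n, rate = hazard)
    if (censorRate > 0) {
      censRate <- mean(hazard) * censorRate / (1 - censorRate)
      censTime <- stats::rexp(n, rate = censRate)
    } else censTime <- rep(Inf, n)
    osTime <- pmin(eventTime, censTime)
    osEvent <- eventTime <= censTime
    clinical <- data.frame(
      sampleId = samples,
      subtype = subtype,
      osTime = osTime,
      osEvent = osEvent,
      size = factor(sample(c("T1", "T2", "T3"), n, replace = TRUE,
                           prob = c(0.45, 0.4, 0.15))),
      grade = factor(sample(1:3, n, replace = TRUE), levels = 1:3),
      pcr = stats::runif(n) < stats::plogis(pcrLogOdds * marker),
      stringsAsFactors = FALSE)
    em <- ExpressionMatrix(values,
      colData = S4Vectors::DataFrame(subtype = subtype, row.names = samples))
    list(expression = em, clinical = clinical, markerGene = markerGene,
         signatureGenes = sigIds)
  })
}

#' Simulate a sorted mammary-lineage expression panel
#'
#' Generates expression profiles for four sorted mammary cell populations
#' (mammary stem cell-enriched, luminal progenitor, mature luminal, stromal)
#' in which one planted population over-expresses the positive-weight genes
#' of a signature and under-expresses its negative-weight genes, so that the
#' signature's projected activity should peak there.
#'
#' @param signature a \linkS4class{GeneSignature} whose genes are planted.
#' @param populations population labels (default MaSC, LP, ML, St).
#' @param nPerPopulation samples per population (>= 2 for group tests).
#' @param plantedPopulation the label that carries the activity shift.
#' @param shift log2 magnitude of the planted shift.
#' @param noiseSd residual SD.
#' @param nNoiseGenes unrelated genes added to the matrix.
#' @param seed integer seed.
#' @return A list with \code{expression}, \code{populations} (factor), and
#'   \code{plantedPopulation}.
#' @examples
#' sig <- GeneSignature(c("A", "B"), c(2, -1))
#' simulateLineages(sig, nPerPopulation = 3, seed = 1)$plantedPopulation
#' @export
simulateLineages <- function(signature,
                             populations = c("MaSC", "LP", "ML", "St"),
                             nPerPopulation = 5L, plantedPopulation = "ML",
                             shift = 1, noiseSd = 0.5, nNoiseGenes = 100L,
                             seed = NULL) {
  stopifnot(is(signature, "GeneSignature"))
  if (!plantedPopulation %in% populations)
    stop("plantedPopulation must be one of the population labels")
  if (nPerPopulation < 1)
    stop("nPerPopulation must be positive")
  withSeed(seed, {
    pop <- factor(rep(populations, each = nPerPopulation),
                  levels = populations)
    n <- length(pop)
    samples <- paste0(rep(populations, each = nPerPopulation), "_",
                      seq_len(nPerPopulation))
    sigGenes <- geneIds(signature)
    w <- sigWeights(signature)
    genes <- c(sigGenes, if (nNoiseGenes > 0)
      sprintf("NOISE%03d", seq_len(nNoiseGenes)))
    mu <- matrix(0, length(genes), n, dimnames = list(genes, samples))
    planted <- pop == plantedPopulation
    mu[sigGenes, planted] <- sign(w) * shift
    values <- mu + matrix(stats::rnorm(length(genes) * n, 0, noiseSd),
                          length(genes), n)
    dimnames(values) <- list(genes, samples)
    em <- ExpressionMatrix(values,
      colData = S4Vectors::DataFrame(population = pop, row.names = samples))
    list(expression = em, populations = pop,
         plantedPopulation = plantedPopulation)
  })
}

#' Simulate a two-channel spot table with intensity-dependent dye bias
#'
#' Draws spot mean log-intensities A and true log-ratios M, applies a
#' user-supplied bias function mapping A to a log-ratio offset (the classic
#' banana-shaped dye bias when nonlinear), adds noise, and converts back to
#' Cy3/Cy5 intensities. The pre-bias true M is retained so normalization can
#' be checked against it.
#'
#' @param nSpots number of spots.
#' @param biasFn function of A returning the log2-ratio offset; default 0.
#' @param noiseSd SD of additive log-ratio noise.
#' @param mSd SD of the true log-ratios.
#' @param aRange range of mean log2 intensities (uniform draw).
#' @param seed integer seed.
#' @return A data.frame with probeId, cy3, cy5, A, trueM, observedM.
#' @examples
#' spots <- simulateTwoChannel(200, biasFn = function(a) 0.5 * sin(a), seed = 1)
#' head(spots)
#' @export
simulateTwoChannel <- function(nSpots = 2000L, biasFn = function(a) 0,
                               noiseSd = 0.1, mSd = 0.3, aRange = c(6, 14),
                               seed = NULL) {
  if (nSpots < 1) stop("nSpots must be positive")
  stopifnot(is.function(biasFn))
  withSeed(seed, {
    A <- stats::runif(nSpots, aRange[1], aRange[2])
    trueM <- stats::rnorm(nSpots, 0, mSd)
    observedM <- trueM + biasFn(A) + stats::rnorm(nSpots, 0, noiseSd)
    data.frame(probeId = sprintf("P%05d", seq_len(nSpots)),
               cy3 = 2^(A - observedM / 2),
               cy5 = 2^(A + observedM / 2),
               A = A, trueM = trueM, observedM = observedM,
               stringsAsFactors = FALSE)
  })
}
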