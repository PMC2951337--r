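test_that("d is zero for equal class means and invariant to location shifts", {
  v <- rbind(g1 = c(1, 2, 3, 1, 2, 3), g2 = c(1, 1, 2, 5, 6, 7))
  colnames(v) <- paste0("s", 1:6)
  labels <- factor(rep(c("a", "b"), each = 3))
  d <- samStatistic(v, labels, s0 = 0.1)
  expect_equal(unname(d["g1"]), 0)
  vShift <- v
  vShift["g2", ] <- v["g2", ] + 100
  d2 <- samStatistic(vShift, labels, s0 = 0.1)
  expect_equal(d2["g2"], d["g2"])
})

test_that("swapping class labels negates every d", {
  sim <- simulateKnockdown(nGenes = 100, seed = 4)
  d <- samStatistic(sim$expression, sim$labels, s0 = 0.2)
  swapped <- factor(sim$labels, levels = rev(levels(sim$labels)))
  dSwap <- samStatistic(sim$expression, sim$labels, s0 = 0.2)
  dNeg <- samStatistic(sim$expression, swapped, s0 = 0.2)
  expect_equal(as.numeric(dNeg), -as.numeric(dSwap))
})

test_that("with s0 = 0 the SAM statistic is the pooled two-sample t", {
  sim <- simulateKnockdown(nGenes = 300, missingRate = 0.05, seed = 10)
  v <- exprValues(sim$expression)
  d <- suppressWarnings(samStatistic(v, sim$labels, s0 = 0))
  tRef <- pooledT(v, sim$labels == "class2")
  expect_lt(max(abs(d - tRef[names(d)]) / pmax(abs(tRef[names(d)]), 1)), 1e-10)
})

test_that("genes without two present values per class are excluded", {
  v <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  v[2, 1:2] <- NA  # class a retains a single value
  labels <- factor(rep(c("a", "b"), each = 3))
  expect_warning(d <- samStatistic(v, labels, s0 = 0.1), "excluded")
  expect_false("g2" %in% names(d))
  expect_identical(attr(d, "excluded"), "g2")
})

test_that("s0 search ties resolve to the lowest percentile on constant scatter", {
  s <- rep(0.5, 200)
  set.seed(1)
  numer <- rnorm(200)
  s0 <- estimateS0(numer, s)
  expect_equal(as.numeric(s0), 0.5)
  expect_equal(attr(s0, "percentile"), 0)
})

test_that("a planted mean-variance trend drives s0 above zero", {
  set.seed(2)
  n <- 1000
  s <- sqrt(rchisq(n, 5) / 5) * seq(0.05, 2, length.out = n)
  numer <- rnorm(n, 0, s)  # scatter-proportional noise, no real effects
  s0 <- as.numeric(estimateS0(numer, s))
  expect_gt(s0, 0)
  d <- numer / (s + s0)
  tRaw <- numer / s
  topD <- order(-abs(d))[1:50]
  topT <- order(-abs(tRaw))[1:50]
  # the fudge factor stops low-scatter genes from dominating the top list
  expect_gt(mean(s[topD]), mean(s[topT]))
})

test_that("homoscedastic data keep the d ranking close to the t ranking", {
  # with near-constant scatter the CV criterion is nearly flat in s0, so the
  # chosen percentile is immaterial: any s0 leaves the ranking t-like
  sim <- simulateKnockdown(nGenes = 500, heteroscedastic = FALSE,
                           sigma = 0.5, seed = 12)
  v <- exprValues(sim$expression)
  cls2 <- sim$labels == "class2"
  parts <- lumisig:::.samParts(v, cls2)
  s0 <- as.numeric(estimateS0(parts$r, parts$s))
  expect_gte(s0, min(parts$s))  # s0 is always a percentile of s
  expect_lte(s0, max(parts$s))
  d <- parts$r / (parts$s + s0)
  expect_gt(cor(rank(d), rank(pooledT(v, cls2))), 0.99)
})

test_that("feasible designs are enumerated exactly and seed-independently", {
  toy <- makeFourVsFour(nGenes = 50)
  n1 <- permutationNull(toy$values, toy$labels, s0 = 0.1, seed = 1)
  n2 <- permutationNull(toy$values, toy$labels, s0 = 0.1, seed = 999)
  expect_true(n1$enumerated)
  expect_equal(n1$nPerm, choose(8, 4))
  expect_identical(n1$dperm, n2$dperm)
  expect_identical(n1$dbar, n2$dbar)
})

test_that("sampled permutations converge to the enumerated expected order stats", {
  toy <- makeFourVsFour(nGenes = 100)
  enum <- permutationNull(toy$values, toy$labels, s0 = 0.1)
  err <- vapply(c(100L, 2000L), function(np) {
    samp <- permutationNull(toy$values, toy$labels, s0 = 0.1, nPerm = np,
                            seed = 5, enumerationLimit = 1L)
    max(abs(samp$dbar - enum$dbar))
  }, numeric(1))
  expect_lt(err[2], err[1])   # error shrinks with more draws
  expect_lt(err[2], 0.05)
})

test_that("on pure noise the observed order statistics track the null line", {
  toy <- makeFourVsFour(nGenes = 500, seed = 13)
  d <- samStatistic(toy$values, toy$labels, s0 = 0.1)
  null <- permutationNull(toy$values, toy$labels, s0 = 0.1)
  slope <- coef(lm(sort(d) ~ null$dbar))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("delta cutpoints match a brute-force evaluation on a worked example", {
  # hand-placed displacements around the identity line
  d <- c(a = -3, b = -1.2, c = -0.4, d = -0.1, e = 0.05,
         f = 0.3, g = 0.8, h = 1.5, i = 2.4, j = 4)
  dbar <- c(-2.2, -1.4, -0.6, -0.2, 0, 0.2, 0.6, 1.2, 1.9, 2.8)
  delta <- 0.5
  res <- callSignificant(d, dbar, delta)
  # brute force: smallest sorted d displaced upward by >= delta, then all above
  dsort <- sort(d)
  upCut <- suppressWarnings(min(dsort[dsort - dbar >= delta]))
  lowCut <- suppressWarnings(max(dsort[dsort - dbar <= -delta]))
  expect_equal(res$cutUp, upCut)
  expect_equal(res$cutLow, lowCut)
  expect_setequal(res$up, names(d)[d >= upCut])
  expect_setequal(res$down, names(d)[d <= lowCut])
  expect_identical(sort(c(res$up, res$down)), sort(names(d)[c(1, 9, 10)]))
  # degenerate deltas
  all0 <- callSignificant(d, dbar, 0)
  expect_setequal(union(all0$up, all0$down), names(d))
  none <- callSignificant(d, dbar, 100)
  expect_length(c(none$up, none$down), 0)
  expect_error(callSignificant(d, dbar, -1), "nonnegative")
})

test_that("FDR is ~1 on pure null data and called counts are monotone", {
  toy <- makeFourVsFour(nGenes = 300, seed = 17)
  res <- runSam(toy$values, toy$labels)
  tab <- deltaTable(res)
  expect_gt(tab$fdr[tab$delta == 0], 0.9)
  expect_true(all(diff(tab$nCalled[order(tab$delta)]) <= 0))
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  expect_error(fdrTable(res@d, res@dbar, res@dperm, numeric(0)), "empty")
})

test_that("a null-only experiment yields an empty or near-empty signature", {
  toy <- makeFourVsFour(nGenes = 400, seed = 19)
  res <- runSam(toy$values, toy$labels)
  sig <- suppressMessages(deriveSignature(res, fdrThreshold = 0.01))
  expect_lt(length(geneIds(sig)), 10)
})

test_that("a planted strong signal is recovered by the derived signature", {
  sim <- simulateKnockdown(nGenes = 1000, deFraction = 0.1, effectSize = 2,
                           sigma = 0.5, seed = 23)
  res <- runSam(sim$expression, sim$labels, seed = 23)
  sig <- deriveSignature(res, fdrThreshold = 0.05)
  expect_gte(mean(sim$trueDe %in% geneIds(sig)), 0.9)
  expect_true(all(sign(sigWeights(sig)[positiveSet(sig)]) == 1))
  expect_true(all(sign(sigWeights(sig)[negativeSet(sig)]) == -1))
  expect_setequal(c(positiveSet(sig), negativeSet(sig)), geneIds(sig))
  expect_error(deriveSignature(res, fdrThreshold = 0), "fdrThreshold")
})

test_that("sampled-permutation SAM is deterministic for a fixed seed", {
  sim <- simulateKnockdown(nGenes = 80, nClass1 = 8, nClass2 = 8, seed = 31)
  r1 <- runSam(sim$expression, sim$labels, nPerm = 50, seed = 5,
               enumerationLimit = 1L)
  r2 <- runSam(sim$expression, sim$labels, nPerm = 50, seed = 5,
               enumerationLimit = 1L)
  expect_false(r1@enumerated)
  expect_identical(r1@dperm, r2@dperm)
  expect_identical(deltaTable(r1), deltaTable(r2))
})
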