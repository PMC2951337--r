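test_that("knockdown generator is seed-deterministic and plants the stated DE set", {
  a <- simulateKnockdown(nGenes = 300, deFraction = 0.1, seed = 7)
  b <- simulateKnockdown(nGenes = 300, deFraction = 0.1, seed = 7)
  expect_identical(exprValues(a$expression), exprValues(b$expression))
  expect_identical(a$trueDe, b$trueDe)
  expect_length(a$trueDe, round(0.1 * 300))
  expect_equal(dim(a$expression), c(300L, 11L))
  c2 <- simulateKnockdown(nGenes = 300, deFraction = 0.1, seed = 8)
  expect_false(identical(exprValues(a$expression), exprValues(c2$expression)))
})

test_that("knockdown noise-free limit reproduces planted shifts exactly", {
  sim <- simulateKnockdown(nGenes = 100, deFraction = 0.2, effectSize = 2,
                           sigma = 0, heteroscedastic = FALSE, seed = 3)
  v <- exprValues(sim$expression)
  diff <- rowMeans(v[, sim$labels == "class2"]) -
    rowMeans(v[, sim$labels == "class1"])
  expect_equal(unname(abs(diff[sim$trueDe])), rep(2, length(sim$trueDe)))
  nullGenes <- setdiff(rownames(v), sim$trueDe)
  expect_equal(unname(diff[nullGenes]), rep(0, length(nullGenes)))
  # signed shifts are recorded alongside the planted set
  expect_equal(unname(diff[sim$trueDe]), unname(attr(sim$trueDe, "shift")))
})

test_that("zero effect size behaves as a pure null", {
  sim <- simulateKnockdown(nGenes = 500, deFraction = 0.1, effectSize = 0,
                           sigma = 0.5, seed = 5)
  v <- exprValues(sim$expression)
  d <- pooledT(v, sim$labels == "class2")
  # every gene, planted or not, is null: t p-values are uniform
  expect_gt(ks.test(pt(d, df = 9), "punif")$p.value, 0.01)
  # planted group-mean differences are pure noise, centered at zero
  diff <- rowMeans(v[sim$trueDe, sim$labels == "class2"]) -
    rowMeans(v[sim$trueDe, sim$labels == "class1"])
  expect_lt(abs(mean(diff)), 4 * sd(diff) / sqrt(length(diff)))
})

test_that("knockdown generator validates its inputs", {
  expect_error(simulateKnockdown(nClass1 = 1), "classes")
  expect_error(simulateKnockdown(deFraction = 1.2), "deFraction")
  expect_error(simulateKnockdown(missingRate = 1), "missingRate")
})

test_that("missing values are injected at the requested rate", {
  sim <- simulateKnockdown(nGenes = 2000, missingRate = 0.2, seed = 2)
  expect_equal(mean(is.na(exprValues(sim$expression))), 0.2, tolerance = 0.05)
})

test_that("null cohort survival matches the exponential closed form", {
  co <- simulateCohort(nPerSubtype = c(LumA = 10000L), nGenes = 2,
                       signatureGenes = 1, subtypeShift = c(LumA = 0),
                       logHazardRatio = 0, censorRate = 0,
                       baselineHazard = 0.1, seed = 9)
  expect_true(all(co$clinical$osEvent))
  expect_true(all(co$clinical$osTime > 0))
  # median of Exp(lambda) is ln(2)/lambda
  expect_equal(median(co$clinical$osTime), log(2) / 0.1, tolerance = 0.02)
})

test_that("cohort generator censors at roughly the requested rate", {
  co <- simulateCohort(nPerSubtype = c(LumA = 4000L), nGenes = 2,
                       signatureGenes = 1, subtypeShift = c(LumA = 0),
                       logHazardRatio = 0, censorRate = 0.3, seed = 4)
  expect_equal(mean(!co$clinical$osEvent), 0.3, tolerance = 0.05)
})

test_that("cohort generator validates subtype structure and rates", {
  expect_error(simulateCohort(nPerSubtype = c(LumA = 0L)), "positive")
  expect_error(simulateCohort(censorRate = 1), "censorRate")
  expect_error(simulateCohort(baselineHazard = 0), "baselineHazard")
  co <- simulateCohort(seed = 1)
  expect_setequal(levels(co$clinical$subtype),
                  c("LumA", "LumB", "HER2", "Basal", "Claudin-low"))
})

test_that("lineage panel plants a recoverable activity ordering", {
  sig <- GeneSignature(sprintf("SG%02d", 1:10), c(rep(2, 5), rep(-2, 5)))
  # noise-free limit: activity strictly maximal in the planted population
  lin0 <- simulateLineages(sig, nPerPopulation = 3, noiseSd = 0,
                           plantedPopulation = "ML", seed = 1)
  act0 <- activityScores(projectSignature(sig, lin0$expression, center = FALSE))
  planted <- lin0$populations == "ML"
  expect_true(min(act0[planted]) > max(act0[!planted]))
  # different seeds: different matrices, same recovered ordering
  lin1 <- simulateLineages(sig, seed = 21)
  lin2 <- simulateLineages(sig, seed = 22)
  expect_false(identical(exprValues(lin1$expression),
                         exprValues(lin2$expression)))
  for (lin in list(lin1, lin2)) {
    act <- activityScores(projectSignature(sig, lin$expression))
    byPop <- tapply(act, lin$populations, median)
    expect_equal(names(which.max(byPop)), "ML")
  }
})

test_that("zero lineage shift gives indistinguishable activity", {
  sig <- GeneSignature(sprintf("SG%02d", 1:10), c(rep(2, 5), rep(-2, 5)))
  pvals <- vapply(1:200, function(s) {
    lin <- simulateLineages(sig, shift = 0, seed = s)
    act <- projectSignature(sig, lin$expression)
    compareActivity(act, lin$populations)$pValue
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("two-channel generator exposes its ground truth", {
  # no bias, no noise: observed M equals true M and intensities invert exactly
  sp0 <- simulateTwoChannel(100, noiseSd = 0, seed = 1)
  expect_equal(sp0$observedM, sp0$trueM)
  expect_equal(log2(sp0$cy5 / sp0$cy3), sp0$observedM)
  expect_equal(0.5 * log2(sp0$cy5 * sp0$cy3), sp0$A)
  # constant bias c shifts observed M by exactly c
  spc <- simulateTwoChannel(100, biasFn = function(a) 0.3, noiseSd = 0,
                            seed = 1)
  expect_equal(spc$observedM - spc$trueM, rep(0.3, 100))
  # binned mean of (observed - true) reproduces a sinusoidal bias curve
  sps <- simulateTwoChannel(5000, biasFn = function(a) 0.5 * sin(a),
                            noiseSd = 0.05, seed = 2)
  bins <- cut(sps$A, 20)
  obs <- tapply(sps$observedM - sps$trueM, bins, mean)
  expected <- tapply(0.5 * sin(sps$A), bins, mean)
  expect_lt(max(abs(obs - expected)), 0.02)
})
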