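test_that("rank split follows the ceiling rule with stable ties", {
  expect_identical(as.character(rankSplit(c(4, 3, 2, 1))),
                   c("high", "high", "low", "low"))
  s5 <- rankSplit(c(5, 1, 4, 2, 3))
  expect_equal(sum(s5 == "high"), 3L)   # ceiling(5/2)
  expect_identical(as.character(s5), c("high", "low", "high", "low", "high"))
  # all tied: the first ceiling(n/2) in input order are labeled high
  tied <- rankSplit(rep(7, 5))
  expect_identical(as.character(tied), c("high", "high", "high", "low", "low"))
  expect_error(rankSplit(c(NA, NA, 1)), "non-missing")
  # group sizes differ by at most one
  for (n in 2:9) {
    sp <- rankSplit(rnorm(n))
    expect_lte(abs(sum(sp == "high") - sum(sp == "low")), 1L)
  }
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$nRisk, c(3, 2, 1))
  # censoring reduces risk sets without steps
  km2 <- kmEstimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 2], 2 / 3)  # censored: no step
  expect_equal(km2$survival[km2$time == 3], 0)
  # no events: flat at 1
  flat <- kmEstimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(flat$survival == 1))
  # time-scale equivariance
  set.seed(1)
  t0 <- rexp(30); ev <- runif(30) < 0.7
  a <- kmEstimate(t0, ev)
  b <- kmEstimate(2 * t0, ev)
  expect_equal(b$survival, a$survival)
  expect_equal(b$time, 2 * a$time)
  expect_equal(a$survival, cummin(a$survival))  # non-increasing from 1
  expect_error(kmEstimate(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("log-rank statistic is zero for identical groups", {
  t0 <- c(1, 2, 3, 4, 5)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  res <- logrankTest(c(t0, t0), c(ev, ev),
                     factor(rep(c("a", "b"), each = 5)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_error(logrankTest(t0, ev, factor(rep("a", 5))), "two groups")
  expect_error(logrankTest(t0, rep(FALSE, 5),
                           factor(c("a", "a", "a", "b", "b"))), "event")
})

test_that("log-rank is invariant under monotone time transforms", {
  set.seed(3)
  t0 <- rexp(60); ev <- runif(60) < 0.8
  g <- factor(rep(c("a", "b"), 30))
  a <- logrankTest(t0, ev, g)
  b <- logrankTest(log1p(t0), ev, g)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("expression group tests cover the t, Welch and ANOVA layouts", {
  x <- c(1, 2, 3, 4)
  g2 <- factor(rep(c("a", "b"), each = 2))
  same <- expressionGroupTests(c(x, x),
                               factor(rep(c("a", "b"), each = 4)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$pValue, 1, tolerance = 1e-12)
  # two-group F = t^2 identity
  set.seed(5)
  e <- rnorm(12); g <- factor(rep(c("a", "b"), each = 6))
  tRes <- expressionGroupTests(e, g)
  fRes <- expressionGroupTests(c(e, rnorm(0)), g)  # same two-group data
  aov3 <- expressionGroupTests(rnorm(15), factor(rep(letters[1:3], each = 5)))
  expect_equal(aov3$test, "anova")
  an <- anova(aov(e ~ g))
  expect_equal(tRes$statistic^2, an[["F value"]][1], tolerance = 1e-10)
  welch <- expressionGroupTests(e, g, welch = TRUE)
  expect_equal(welch$test, "welch-t")
  expect_error(expressionGroupTests(e, factor(rep("a", 12))), "two groups")
})

test_that("planted subtype shifts are detected by ANOVA on the marker", {
  co <- simulateCohort(seed = 2)
  expr <- exprValues(co$expression)[co$markerGene, ]
  res <- expressionGroupTests(expr, co$clinical$subtype)
  expect_lt(res$pValue, 0.01)
  # luminal vs non-luminal two-group comparison is also significant
  lum <- factor(ifelse(co$clinical$subtype %in% c("LumA", "LumB"),
                       "luminal", "other"))
  expect_lt(expressionGroupTests(expr, lum)$pValue, 0.01)
})

test_that("2x2 chi-square matches the textbook O/E computation", {
  expect_equal(pcrChisq(matrix(c(10, 20, 10, 20), 2))$statistic, 0,
               tolerance = 1e-12)
  tab <- matrix(c(10, 20, 20, 10), 2)
  res <- pcrChisq(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)  # 6.667 by hand
  expect_equal(res$df, 1L)
  # symmetric under transposition
  expect_equal(pcrChisq(t(tab))$statistic, res$statistic)
  expect_error(pcrChisq(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(pcrChisq(matrix(1:6, 2)), "2x2")
})

test_that("doubling time inverts exact and noisy exponential growth", {
  expect_equal(doublingTime(c(1, 2, 4, 8) * 1e5, c(0, 24, 48, 72))$doublingTime,
               24)
  expect_equal(doublingTime(c(1e5, 4e5, 16e5), c(0, 48, 96))$doublingTime, 24)
  expect_warning(res <- doublingTime(c(8, 4, 2, 1), c(0, 1, 2, 3)),
                 "not growing")
  expect_true(is.na(res$doublingTime))
  # noisy exponential: mean estimate within 2% of truth (closed-form OLS)
  set.seed(9)
  times <- c(0, 24, 48, 96)
  est <- vapply(1:1000, function(i) {
    counts <- 5e4 * 2^(times / 24) * exp(rnorm(4, 0, 0.05))
    doublingTime(counts, times)$doublingTime
  }, numeric(1))
  expect_equal(mean(est), 24, tolerance = 0.02)
})

test_that("expression-stratified survival wrapper ties the pieces together", {
  co <- simulateCohort(logHazardRatio = -0.8, seed = 6)
  res <- survivalByExpression(co$expression, co$clinical, co$markerGene)
  expect_equal(res$n, nrow(co$clinical))
  expect_true(all(c("high", "low") %in% res$km$group))
  expect_lt(res$logrank$pValue, 0.05)
  # high marker expression was simulated protective: better survival at a
  # common evaluation time (step-function lookup, not curve minima, since
  # the two halves end at different follow-up times)
  tEval <- median(co$clinical$osTime)
  kmAt <- function(grp) {
    km <- res$km[res$km$group == grp, ]
    past <- km$time <= tEval
    if (any(past)) km$survival[max(which(past))] else 1
  }
  expect_gt(kmAt("high"), kmAt("low"))
  # subtype restriction mirrors the luminal-only analysis
  lum <- survivalByExpression(co$expression, co$clinical, co$markerGene,
                              subtypes = c("LumA", "LumB"))
  expect_equal(lum$n, sum(co$clinical$subtype %in% c("LumA", "LumB")))
  expect_error(survivalByExpression(co$expression, co$clinical, "NOPE"),
               "not in matrix")
})
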