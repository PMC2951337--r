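# Shared fixture builders. Everything is generated in code at test time.

# Small genes x samples ExpressionMatrix with optional NA entries.
makeMatrix <- function(nGenes = 10, nSamples = 6, seed = 1, naIdx = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  if (!is.null(naIdx)) v[naIdx] <- NA_real_
  ExpressionMatrix(v)
}

# Correlated 5-gene block (pairwise r ~ 0.9) among independent noise genes.
makeBlockMatrix <- function(nNoise = 20, nSamples = 30, seed = 1) {
  set.seed(seed)
  f <- rnorm(nSamples)
  block <- matrix(rep(f, each = 5), 5, nSamples) +
    matrix(rnorm(5 * nSamples, 0, 1 / 3), 5, nSamples)
  noise <- matrix(rnorm(nNoise * nSamples), nNoise, nSamples)
  m <- rbind(block, noise)
  dimnames(m) <- list(c(paste0("BLK", 1:5), sprintf("NSE%02d", seq_len(nNoise))),
                      sprintf("s%02d", seq_len(nSamples)))
  ExpressionMatrix(m)
}

# Independent textbook pooled-variance two-sample t statistic, per gene.
pooledT <- function(v, cls2) {
  apply(v, 1L, function(r) {
    x1 <- r[!cls2][!is.na(r[!cls2])]
    x2 <- r[cls2][!is.na(r[cls2])]
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
    (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  })
}

# A fixed 4 vs 4 toy experiment (70 distinct label assignments).
makeFourVsFour <- function(nGenes = 200, seed = 11) {
  set.seed(seed)
  v <- matrix(rnorm(nGenes * 8), nGenes, 8,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%d", 1:8)))
  labels <- factor(rep(c("a", "b"), each = 4))
  list(values = v, labels = labels)
}
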