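## Gene-dimension hierarchical clustering under centered Pearson similarity,
## node-correlation module extraction around a seed gene, and overlap
## decomposition of a module against named gene signatures.

#' Correlation dendrogram over genes
#'
#' Median-centers gene rows, computes pairwise Pearson correlations across
#' samples (pairwise-complete over present values), and clusters genes
#' agglomeratively with average linkage on the distance 1 - r. Each merge
#' node carries a node correlation (1 - merge height); with average linkage
#' these are non-increasing toward the root, so threshold-based module
#' extraction is well defined. Constant genes (undefined correlation) are
#' excluded with a warning.
#'
#' @param x an \linkS4class{ExpressionMatrix} (at least 2 genes, 3 samples).
#' @param center median-center gene rows first (default TRUE).
#' @return A \linkS4class{GeneDendrogram}.
#' @examples
#' sim <- simulateKnockdown(nGenes = 30, seed = 5)
#' correlationDendrogram(sim$expression)
#' @export
correlationDendrogram <- function(x, center = TRUE) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (nrow(x) < 2 || ncol(x) < 3)
    stop("need at least 2 genes and 3 samples")
  if (center) x <- medianCenter(x)
  v <- exprValues(x)
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant genes excluded from clustering")
    v <- v[!constant, , drop = FALSE]
  }
  if (nrow(v) < 2) stop("fewer than 2 variable genes remain")
  r <- stats::cor(t(v), use = "pairwise.complete.obs")
  if (any(!is.finite(r)))
    stop("undefined pairwise correlations (too few overlapping samples)")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  new("GeneDendrogram", merge = hc$merge,
      nodeCorrelation = 1 - hc$height,
      labels = rownames(v), order = as.integer(hc$order))
}

# Leaf labels under merge-tree node k (positive = merge row, negative = leaf).
.nodeLeaves <- function(merge, labels, k) {
  stack <- k
  leaves <- integer(0)
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    if (node < 0) leaves <- c(leaves, -node)
    else stack <- c(merge[node, 1L], merge[node, 2L], stack)
  }
  labels[leaves]
}

#' Extract the gene module around a seed gene by node correlation
#'
#' Ascends the dendrogram from the seed leaf toward the root, accepting
#' ancestor nodes while their node correlation stays at or above
#' \code{minCorr}, and returns the leaves of the highest accepted ancestor
#' (the seed alone if its first merge already falls below the threshold).
#' Raising \code{minCorr} never enlarges the module.
#'
#' @param tree a \linkS4class{GeneDendrogram}.
#' @param seedGene leaf gene identifier to grow the module around.
#' @param minCorr node-correlation threshold in [-1, 1] (default 0.65).
#' @return Character vector of module gene ids (always includes the seed).
#' @examples
#' sim <- simulateKnockdown(nGenes = 30, seed = 5)
#' tree <- correlationDendrogram(sim$expression)
#' extractNodeModule(tree, geneIds(tree)[1], minCorr = 0.65)
#' @export
extractNodeModule <- function(tree, seedGene, minCorr = 0.65) {
  stopifnot(is(tree, "GeneDendrogram"))
  leaf <- match(seedGene, tree@labels)
  if (is.na(leaf))
    stop("seed gene '", seedGene, "' is not a leaf of the tree")
  merge <- tree@merge
  # parent of each node: leaves are -i, merges are +k
  child <- -leaf
  accepted <- 0L
  repeat {
    parent <- which(merge[, 1L] == child | merge[, 2L] == child)
    if (!length(parent)) break
    if (tree@nodeCorrelation[parent] >= minCorr) {
      accepted <- parent
      child <- parent
    } else break
  }
  if (accepted == 0L) return(seedGene)
  .nodeLeaves(merge, tree@labels, accepted)
}

#' Serialize a gene dendrogram to Newick
#'
#' Internal nodes are labeled with their node correlation; branch lengths
#' are omitted.
#'
#' @param tree a \linkS4class{GeneDendrogram}.
#' @param digits digits for node-correlation labels.
#' @return A single Newick string (terminated by ";").
#' @export
dendrogramToNewick <- function(tree, digits = 4L) {
  stopifnot(is(tree, "GeneDendrogram"))
  merge <- tree@merge
  fmt <- function(node) {
    if (node < 0) return(tree@labels[-node])
    sprintf("(%s,%s)%s", fmt(merge[node, 1L]), fmt(merge[node, 2L]),
            format(round(tree@nodeCorrelation[node], digits)))
  }
  paste0(fmt(nrow(merge)), ";")
}

#' Decompose a gene module by signature overlap
#'
#' Assigns each module gene to exactly one exclusive category: the single
#' signature containing it, \code{"multiple"} when two or more signatures
#' contain it, or \code{"none"}. Counts therefore partition the module, and
#' percentages are counts over the module size.
#'
#' @param moduleGenes character vector of module gene ids (non-empty).
#' @param signatures named list of gene-id vectors (or
#'   \linkS4class{GeneSignature} objects).
#' @return A list with \code{moduleSize}, \code{table} (data.frame: category,
#'   count, percent), and \code{assignment} (named category per gene).
#' @examples
#' overlapAnalysis(letters[1:10],
#'   list(sigA = letters[1:4], sigB = c("e", "f"), sigC = "f"))
#' @export
overlapAnalysis <- function(moduleGenes, signatures) {
  if (!length(moduleGenes)) stop("module is empty")
  if (is.null(names(signatures)) || any(names(signatures) == ""))
    stop("signatures must be a named list")
  sets <- lapply(signatures, function(s)
    if (is(s, "GeneSignature")) geneIds(s) else as.character(s))
  hits <- vapply(sets, function(s) moduleGenes %in% s,
                 logical(length(moduleGenes)))
  hits <- matrix(hits, nrow = length(moduleGenes),
                 dimnames = list(moduleGenes, names(sets)))
  nHit <- rowSums(hits)
  assignment <- rep("none", length(moduleGenes))
  single <- nHit == 1
  assignment[single] <- colnames(hits)[apply(hits[single, , drop = FALSE],
                                             1L, which)]
  assignment[nHit > 1] <- "multiple"
  names(assignment) <- moduleGenes
  cats <- c(names(sets), "multiple", "none")
  counts <- vapply(cats, function(cc) sum(assignment == cc), integer(1))
  list(moduleSize = length(moduleGenes),
       table = data.frame(category = cats, count = as.integer(counts),
                          percent = 100 * counts / length(moduleGenes),
                          row.names = NULL, stringsAsFactors = FALSE),
       assignment = assignment)
}
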