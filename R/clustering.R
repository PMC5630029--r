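## Response archetypes: joint feature matrices, agglomerative clustering with
## small-cluster removal, PCA summaries, and cluster-mean profiles that feed
## the RNAPII compartment model.

#' Build a joint feature matrix from response matrices
#'
#' Concatenates log2-response blocks (e.g. RNAPII promoter / gene-body / TES
#' and synthesis responses) over a shared gene universe, standardizing each
#' block to unit pooled variance so every data type contributes comparably
#' to distances. Baseline (untreated intensity) columns can be appended for
#' display but are excluded from distance computation by default.
#'
#' @param responses Named list of `genes x features` response matrices (see
#'   [responseMatrix()]).
#' @param baseline Optional `genes x b` matrix of untreated intensities,
#'   standardized separately and appended with attribute
#'   `baselineCols` marking them.
#' @return `genes x features` numeric matrix.
#' @export
buildFeatureMatrix <- function(responses, baseline = NULL) {
  if (is.matrix(responses)) responses <- list(responses)
  g0 <- rownames(responses[[1L]])
  blocks <- lapply(seq_along(responses), function(i) {
    m <- responses[[i]]
    if (!identical(rownames(m), g0)) stop("mismatched gene universes")
    s <- sd(as.numeric(m))
    if (is.finite(s) && s > 0) m <- m / s
    if (!is.null(names(responses)[i]) && nzchar(names(responses)[i]))
      colnames(m) <- paste(names(responses)[i], colnames(m), sep = ".")
    m
  })
  out <- do.call(cbind, blocks)
  if (!is.null(baseline)) {
    if (!identical(rownames(baseline), g0)) stop("mismatched gene universes")
    b <- scale(baseline)
    colnames(b) <- paste0("baseline.", colnames(baseline))
    attr(out, "baselineCols") <- ncol(out) + seq_len(ncol(b))
    out <- cbind(out, b)
  }
  out
}

#' Hierarchical clustering with small-cluster removal
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances by
#' default), cut at `k` clusters; clusters are relabeled in decreasing size
#' order and clusters below `minClusterSize` are marked `"removed"` rather
#' than silently dropped. Fully deterministic for fixed inputs.
#'
#' @param x `genes x features` matrix (see [buildFeatureMatrix()]; baseline
#'   columns, if marked, are excluded from distances).
#' @param k Number of clusters (default 14).
#' @param minClusterSize Minimum surviving cluster size (default 30).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Linkage method for [stats::hclust()] (default `"ward.D2"`).
#' @return Factor of cluster labels (`"1"`, `"2"`, ... in decreasing size
#'   order, plus `"removed"`), named by gene, with attributes `k`,
#'   `minClusterSize`, `metric`, `linkage`.
#' @export
hierarchicalClusters <- function(x, k = 14L, minClusterSize = 30L,
                                 metric = "euclidean",
                                 linkage = "ward.D2") {
  stopifnot(k >= 2L)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  bc <- attr(x, "baselineCols")
  if (!is.null(bc)) x <- x[, -bc, drop = FALSE]
  hc <- hclust(dist(x, method = metric), method = linkage)
  raw <- cutree(hc, k = k)
  sizes <- table(raw)
  ord <- order(-sizes, as.integer(names(sizes)))   # ties: smaller index
  relabel <- setNames(seq_len(k), names(sizes)[ord])
  lab <- as.character(relabel[as.character(raw)])
  lab[sizes[as.character(raw)] < minClusterSize] <- "removed"
  out <- factor(lab, levels = c(as.character(seq_len(k)), "removed"))
  names(out) <- rownames(x)
  attr(out, "k") <- k
  attr(out, "minClusterSize") <- minClusterSize
  attr(out, "metric") <- metric
  attr(out, "linkage") <- linkage
  out
}

#' PCA explained-variance fractions and scores
#'
#' Centered (not rescaled) principal component analysis of a feature
#' matrix.
#'
#' @param x `genes x features` numeric matrix.
#' @return List with `fractions` (per-component explained-variance
#'   fractions, summing to 1 over all components), `scores` and `rotation`.
#' @export
pcaExplainedVariance <- function(x) {
  stopifnot(nrow(x) >= 2L)
  if (all(apply(x, 2L, sd) == 0)) stop("zero-variance matrix")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  list(fractions = pc$sdev^2 / sum(pc$sdev^2), scores = pc$x,
       rotation = pc$rotation)
}

#' Cluster-mean trajectories for RNAPII modeling
#'
#' Replicate-averaged, cluster-averaged trajectories of the promoter /
#' gene-body / TES RNAPII densities and synthesis rates — the profiles on
#' which [inferRates()] operates. Genes labeled `"removed"` are excluded;
#' clusters emptied by the exclusion are dropped with a warning.
#'
#' @param assignment Factor from [hierarchicalClusters()] (or any per-gene
#'   labeling), named by gene.
#' @param tables Named list with [SignalTable-class] objects `Pr`, `Gb`,
#'   `Te` and/or a precomputed `k1` matrix; every element must cover the
#'   assigned genes.
#' @return List of per-cluster profiles, each a list with `cluster`, `n`,
#'   and mean trajectories for each supplied stream.
#' @export
clusterProfiles <- function(assignment, tables) {
  genes <- names(assignment)
  if (is.null(genes)) stop("assignment must be named by gene")
  mats <- lapply(tables, function(tb) {
    m <- if (is(tb, "SignalTable")) {
      if (!tb@normalized) tb <- normalizeSignal(tb)
      averageReplicates(tb)
    } else as.matrix(tb)
    if (!all(genes %in% rownames(m))) stop("assignment covers genes absent ",
                                           "from a table")
    m[genes, , drop = FALSE]
  })
  keepLv <- setdiff(levels(assignment), "removed")
  out <- lapply(keepLv, function(lv) {
    sel <- assignment == lv
    if (!any(sel)) return(NULL)
    c(list(cluster = lv, n = sum(sel)),
      lapply(mats, function(m) colMeans(m[sel, , drop = FALSE])))
  })
  empty <- vapply(out, is.null, logical(1L))
  if (any(empty)) warning(sum(empty), " cluster(s) empty after removal")
  setNames(out[!empty], keepLv[!empty])
}
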