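## The MYC promoter "share": each promoter's fraction of the total genomic
## MYC signal, its change upon activation, the share-neutral threshold, ROC
## discrimination of induced vs repressed genes, and trend summaries.

#' Promoter share of total MYC binding
#'
#' `share_i = (b_i + pc) / sum_j (b_j + pc)`. The pseudocount is applied to
#' every promoter so that shares at different timepoints remain exactly
#' comparable (see [shareNeutralThreshold()]).
#'
#' @param binding Non-negative per-gene binding values.
#' @param pseudocount Pseudocount `pc` (default 0).
#' @param total Optional background total to use as denominator instead of
#'   `sum(binding + pc)` (e.g. total MYC over all genomic peaks when
#'   `binding` covers promoters only).
#' @return Numeric vector of shares; sums to 1 when `total` is not supplied.
#' @examples
#' computeShare(c(2, 3, 5))    # 0.2 0.3 0.5
#' @export
computeShare <- function(binding, pseudocount = 0, total = NULL) {
  stopifnot(all(binding >= 0), pseudocount >= 0)
  b <- binding + pseudocount
  denom <- if (is.null(total)) sum(b) else total
  if (denom <= 0) stop("total binding must be positive (all-zero input?)")
  b / denom
}

#' Share-neutral threshold of MYC binding change
#'
#' The per-gene log2 binding change at which a promoter's share of total MYC
#' is unchanged equals the global log2 change of total binding:
#' `delta* = log2( sum(b_after + pc) / sum(b_before + pc) )`. A gene's share
#' increases if and only if its own `delta = log2(b_after + pc) -
#' log2(b_before + pc)` exceeds `delta*`.
#'
#' @param before,after Non-negative per-gene binding at the untreated and
#'   activated conditions.
#' @param pseudocount Pseudocount applied symmetrically at both conditions.
#' @return The threshold `delta*` (log2).
#' @examples
#' shareNeutralThreshold(c(600, 400), c(2400, 1600))   # totals x4 -> 2
#' @export
shareNeutralThreshold <- function(before, after, pseudocount = 0) {
  stopifnot(length(before) == length(after))
  log2(sum(after + pseudocount) / sum(before + pseudocount))
}

#' Per-gene share bookkeeping between two conditions
#'
#' @inheritParams shareNeutralThreshold
#' @return A data.frame with per-gene `b_before`, `b_after`, `delta`
#'   (log2 binding change), `share_before`, `share_after` and `share_change`
#'   (log2 share ratio, which equals `delta - delta*` exactly); `delta*` is
#'   attached as `attr(, "neutral_threshold")`.
#' @export
shareTable <- function(before, after, pseudocount = 0) {
  sb <- computeShare(before, pseudocount)
  sa <- computeShare(after, pseudocount)
  delta <- log2(after + pseudocount) - log2(before + pseudocount)
  dstar <- shareNeutralThreshold(before, after, pseudocount)
  out <- data.frame(b_before = before, b_after = after, delta = delta,
                    share_before = sb, share_after = sa,
                    share_change = delta - dstar)
  if (!is.null(names(before))) rownames(out) <- names(before)
  attr(out, "neutral_threshold") <- dstar
  out
}

#' Classify genes as induced / repressed / unresponsive
#'
#' A gene is induced if its maximal response reaches `upThresh`, repressed if
#' its minimal response reaches `downThresh`; a gene meeting both is labeled
#' by the larger absolute excursion, with exact ties unresponsive.
#'
#' @param response `genes x features` matrix of log2 responses (e.g. from
#'   [responseMatrix()]) or a per-gene vector (e.g. a synthesis-rate change).
#' @param upThresh,downThresh Log2 thresholds (defaults +1 / -1).
#' @return Factor with levels `induced`, `repressed`, `unresponsive`.
#' @export
classifyRegulation <- function(response, upThresh = 1, downThresh = -1) {
  if (is.null(dim(response))) response <- cbind(response)
  stopifnot(all(is.finite(response)), upThresh > 0, downThresh < 0)
  hi <- apply(response, 1L, max)
  lo <- apply(response, 1L, min)
  up <- hi >= upThresh; down <- lo <= downThresh
  lab <- rep("unresponsive", nrow(response))
  lab[up & !down] <- "induced"
  lab[down & !up] <- "repressed"
  both <- up & down
  lab[both & hi > -lo] <- "induced"
  lab[both & -lo > hi] <- "repressed"
  out <- factor(lab, levels = c("induced", "repressed", "unresponsive"))
  names(out) <- rownames(response)
  out
}

#' ROC curve for discriminating induced from repressed genes
#'
#' Positives are induced genes, negatives repressed; unresponsive genes are
#' excluded. Every distinct score is swept as a threshold (predict induced
#' when score >= threshold), the AUC is the trapezoidal area, and tied scores
#' contribute diagonal segments — so the AUC equals the Mann-Whitney pair
#' statistic with half-credit for ties.
#'
#' @param score Per-gene predictor (e.g. `delta` from [shareTable()]).
#' @param labels Factor/character parallel to `score` with values among
#'   `induced`, `repressed`, `unresponsive`.
#' @param neutralThreshold Optional threshold at which to report the
#'   operating point (e.g. [shareNeutralThreshold()]).
#' @return List with `thresholds` (decreasing), `fpr`, `tpr`, `youden`,
#'   `auc`, and (when requested) `neutral_point = c(fpr, tpr)` plus
#'   `neutral_youden`.
#' @export
rocInducedVsRepressed <- function(score, labels, neutralThreshold = NULL) {
  keep <- labels %in% c("induced", "repressed")
  score <- score[keep]; labels <- as.character(labels[keep])
  stopifnot(all(is.finite(score)))
  npos <- sum(labels == "induced"); nneg <- sum(labels == "repressed")
  if (npos == 0L || nneg == 0L)
    stop("need at least one induced and one repressed gene")
  pos <- labels == "induced"
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  ends <- cumsum(rle(s)$lengths)       # last index of each distinct value
  cp <- cumsum(p); cn <- cumsum(!p)
  ## point i is the rule "predict induced when score >= thresholds[i]";
  ## tied scores enter together, giving diagonal ROC segments
  tpr <- c(0, cp[ends] / npos)
  fpr <- c(0, cn[ends] / nneg)
  thr <- c(Inf, s[ends])
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  out <- list(thresholds = thr, fpr = fpr, tpr = tpr, youden = tpr - fpr,
              auc = auc)
  if (!is.null(neutralThreshold)) {
    ntpr <- sum(score[pos] > neutralThreshold) / npos
    nfpr <- sum(score[!pos] > neutralThreshold) / nneg
    out$neutral_point <- c(fpr = nfpr, tpr = ntpr)
    out$neutral_youden <- ntpr - nfpr
  }
  out
}

#' Trend and rank correlation between binding change and response
#'
#' Points outside the stated percentile band of `x` are excluded, a
#' tricube-weighted quadratic local regression (loess) is fitted per label
#' group and on all trimmed points combined, and Spearman's rank correlation
#' is computed on the trimmed set.
#'
#' @param x Per-gene predictor (e.g. log2 MYC binding change).
#' @param y Per-gene response (e.g. log2 expression or synthesis change).
#' @param labels Optional gene classes; groups `induced` and `repressed` get
#'   their own trend in addition to `combined`.
#' @param trim Percentile band of `x` retained (default `c(2, 98)`).
#' @param span Loess span (default 0.5).
#' @param gridN Number of evaluation points of the trend.
#' @return List of per-group results, each with `rho`, `p`, `n` and a
#'   `trend` data.frame (`x`, `fit`).
#' @export
trendCorrelation <- function(x, y, labels = NULL, trim = c(2, 98),
                             span = 0.5, gridN = 50L) {
  stopifnot(length(x) == length(y))
  qs <- quantile(x, trim / 100, na.rm = TRUE)
  keep <- is.finite(x) & is.finite(y) & x >= qs[1L] & x <= qs[2L]
  if (sum(keep) < 10L) stop("fewer than 10 points after trimming")
  groups <- list(combined = keep)
  if (!is.null(labels)) {
    groups$induced <- keep & labels == "induced"
    groups$repressed <- keep & labels == "repressed"
  }
  lapply(groups, function(g) {
    if (sum(g) < 10L) return(NULL)
    xs <- x[g]; ys <- y[g]
    ct <- suppressWarnings(cor.test(xs, ys, method = "spearman",
                                    exact = sum(g) < 12L))
    fit <- loess(ys ~ xs, span = span, degree = 2,
                 family = "gaussian")
    gx <- seq(min(xs), max(xs), length.out = gridN)
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(g),
         trend = data.frame(x = gx, fit = predict(fit, newdata =
                                                    data.frame(xs = gx))))
  })
}

#' Youden-optimal threshold within cofactor strata
#'
#' Genes are binned by quantiles of a cofactor (e.g. ZBTB17 promoter
#' binding); within each sufficiently populated bin the binding-change
#' threshold maximizing Youden's J for induced-vs-repressed discrimination
#' is reported. Underpopulated bins are flagged, not dropped silently.
#'
#' @param delta Per-gene log2 binding change.
#' @param labels Gene classes (see [rocInducedVsRepressed()]).
#' @param cofactor Per-gene cofactor level.
#' @param nBins Number of quantile bins (default 4).
#' @param minPerClass Minimum induced and repressed genes a bin needs
#'   (default 20).
#' @return data.frame with one row per bin: `bin`, `cofactor_lo`,
#'   `cofactor_hi`, `n_induced`, `n_repressed`, `threshold`, `youden`, `ok`.
#' @export
stratifiedNeutralThreshold <- function(delta, labels, cofactor, nBins = 4L,
                                       minPerClass = 20L) {
  stopifnot(length(delta) == length(labels),
            length(cofactor) == length(delta))
  keep <- labels %in% c("induced", "repressed")
  delta <- delta[keep]; labels <- as.character(labels[keep])
  cofactor <- cofactor[keep]
  br <- quantile(cofactor, seq(0, 1, length.out = nBins + 1L))
  br[1L] <- -Inf; br[length(br)] <- Inf
  bin <- cut(cofactor, br, labels = FALSE, include.lowest = TRUE)
  res <- lapply(seq_len(nBins), function(b) {
    sel <- bin == b
    ni <- sum(labels[sel] == "induced"); nr <- sum(labels[sel] == "repressed")
    ok <- ni >= minPerClass && nr >= minPerClass
    thrOpt <- you <- NA_real_
    if (ok) {
      roc <- rocInducedVsRepressed(delta[sel], labels[sel])
      i <- which.max(roc$youden)
      thrOpt <- roc$thresholds[i]; you <- roc$youden[i]
    }
    data.frame(bin = b,
               cofactor_lo = if (b == 1L) min(cofactor) else br[b],
               cofactor_hi = if (b == nBins) max(cofactor) else br[b + 1L],
               n_induced = ni, n_repressed = nr, threshold = thrOpt,
               youden = you, ok = ok)
  })
  do.call(rbind, res)
}
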