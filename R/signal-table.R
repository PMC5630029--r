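## SignalTable operations: normalization, replicate averaging, response
## matrices, and the TSV + YAML-sidecar on-disk dialect.

#' Library-size normalize a SignalTable
#'
#' Scales each (timepoint, replicate) library to counts per million.
#' Normalizing an already-normalized table is an error.
#'
#' @param x A [SignalTable-class].
#' @return A [SignalTable-class] with `normalized = TRUE` and unit library
#'   sizes of 1e6 (so repeated CPM computation is idempotent in value).
#' @examples
#' st <- SignalTable("MYC", matrix(10, 1, 2, dimnames = list("g1", NULL)),
#'                   librarySizes = 1e6, timeGrid = TimeGrid(c(0, 1)))
#' signalValues(normalizeSignal(st))   # 10 CPM
#' @export
normalizeSignal <- function(x) {
  stopifnot(is(x, "SignalTable"))
  if (x@normalized) stop("SignalTable is already normalized")
  if (any(x@librarySizes <= 0)) stop("zero or negative library size")
  v <- x@values
  for (j in seq_len(dim(v)[2L]))
    for (r in seq_len(dim(v)[3L]))
      v[, j, r] <- v[, j, r] / x@librarySizes[j, r] * 1e6
  SignalTable(x@assay, v, librarySizes = 1e6, timeGrid = x@timeGrid,
              normalized = TRUE)
}

#' Average replicates of a SignalTable
#'
#' @param x A [SignalTable-class] (normalize first; averaging raw counts
#'   across libraries of different size is rarely meaningful and triggers a
#'   warning).
#' @return `genes x timepoints` matrix of replicate means.
#' @export
averageReplicates <- function(x) {
  stopifnot(is(x, "SignalTable"))
  if (!x@normalized && dim(x@values)[3L] > 1L &&
      stats::sd(x@librarySizes) > 0)
    warning("averaging raw counts across unequal libraries; normalize first")
  out <- apply(x@values, c(1L, 2L), mean)
  colnames(out) <- paste0("t", signif(x@timeGrid@times, 6))
  out
}

#' Per-gene noise level from replicates
#'
#' Median (across timepoints) coefficient of variation of the replicate
#' values, shrunk halfway toward the cohort median — a stabilized per-gene
#' relative noise estimate used to weight model fits.
#'
#' @param x A normalized [SignalTable-class] with >= 2 replicates.
#' @param floor Lower bound on the returned CV (guards noiseless data).
#' @return Named numeric vector, one CV per gene.
#' @export
replicateCV <- function(x, floor = 1e-3) {
  v <- x@values
  if (dim(v)[3L] < 2L) return(setNames(rep(floor, nrow(v)), rownames(v)))
  m <- apply(v, c(1L, 2L), mean)
  s <- apply(v, c(1L, 2L), sd)
  nr <- dim(v)[3L]
  c4 <- sqrt(2 / (nr - 1)) * gamma(nr / 2) / gamma((nr - 1) / 2)
  rel <- (s / c4) / pmax(m, .Machine$double.eps)
  cvg <- apply(rel, 1L, function(z) {
    z <- z[is.finite(z)]
    if (!length(z)) return(NA_real_)
    sqrt(mean(z^2))
  })
  cvg[!is.finite(cvg)] <- 0
  pooled <- median(cvg, na.rm = TRUE)
  pmax(sqrt(0.5 * cvg^2 + 0.5 * pooled^2), floor)
}

#' Log2 response matrix relative to the untreated condition
#'
#' For each table and post-activation timepoint, computes
#' `log2((x_t + pc) / (x_0 + pc))` on replicate-averaged normalized values.
#'
#' @param tables A [SignalTable-class] or list thereof (shared gene list and
#'   time grid required).
#' @param pseudocount Pseudocount `pc` in CPM units (default 1).
#' @param dropBaseline Drop the identically-zero time-0 column (default
#'   `FALSE`).
#' @return `genes x (assay.time)` numeric matrix; the pseudocount is recorded
#'   in `attr(, "pseudocount")`.
#' @export
responseMatrix <- function(tables, pseudocount = 1, dropBaseline = FALSE) {
  if (is(tables, "SignalTable")) tables <- list(tables)
  g0 <- geneIds(tables[[1L]]); t0 <- gridTimes(timeGrid(tables[[1L]]))
  blocks <- lapply(tables, function(st) {
    if (!identical(geneIds(st), g0)) stop("mismatched gene lists")
    if (!isTRUE(all.equal(gridTimes(timeGrid(st)), t0)))
      stop("mismatched time grids")
    if (!st@normalized) st <- normalizeSignal(st)
    m <- averageReplicates(st)
    lr <- log2(m + pseudocount) - log2(m[, 1L] + pseudocount)
    colnames(lr) <- paste(assayName(st), colnames(m), sep = ".")
    if (dropBaseline) lr[, -1L, drop = FALSE] else lr
  })
  out <- do.call(cbind, blocks)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "times") <- t0
  out
}

#' Write / read a SignalTable in the TSV dialect
#'
#' The table is written as `gene_id` plus `t<time>_r<rep>` columns; assay,
#' time grid, labeling duration, library sizes and normalization state go to
#' a YAML sidecar `<stem>.meta.yaml`. Round-tripping preserves values to at
#' least 12 significant digits.
#'
#' @param x A [SignalTable-class].
#' @param path Output TSV path.
#' @return `writeSignalTable` returns `path` invisibly; `readSignalTable`
#'   returns a [SignalTable-class].
#' @export
writeSignalTable <- function(x, path) {
  stopifnot(is(x, "SignalTable"))
  v <- x@values
  nt <- dim(v)[2L]; nr <- dim(v)[3L]
  ## column-major flattening: column index = (rep - 1) * ntimes + time
  flat <- matrix(v, nrow = dim(v)[1L])
  cn <- as.vector(outer(seq_len(nt), seq_len(nr), function(j, r)
    paste0("t", signif(x@timeGrid@times[j], 10), "_r", r)))
  ## array flattening is time-fastest within replicate: col = (r-1)*nt + j
  df <- data.frame(gene_id = rownames(v),
                   format(flat, digits = 15, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  num <- function(z) sprintf("%.17g", z)   # yaml truncates doubles otherwise
  meta <- list(assay = x@assay, times = num(x@timeGrid@times),
               labeling_duration = num(x@timeGrid@labelingDuration),
               library_sizes = lapply(seq_len(nr), function(r)
                 num(x@librarySizes[, r])),
               normalized = x@normalized)
  yaml::write_yaml(meta, paste0(sub("\\.tsv$", "", path), ".meta.yaml"))
  invisible(path)
}

#' @rdname writeSignalTable
#' @export
readSignalTable <- function(path) {
  meta <- yaml::read_yaml(paste0(sub("\\.tsv$", "", path), ".meta.yaml"))
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  genes <- df$gene_id
  num <- vapply(df[-1L], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L,
                                    dimnames = list(NULL, colnames(df)[-1L]))
  nt <- length(meta$times); nr <- length(meta$library_sizes)
  v <- array(num, dim = c(length(genes), nt, nr),
             dimnames = list(genes, NULL, NULL))
  ls <- do.call(cbind, lapply(meta$library_sizes, as.numeric))
  SignalTable(meta$assay, v, ls,
              TimeGrid(as.numeric(meta$times),
                       as.numeric(meta$labeling_duration)),
              normalized = isTRUE(meta$normalized))
}
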