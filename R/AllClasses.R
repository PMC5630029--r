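## Central S4 containers shared by all stages.

#' Sampling grid of a MYC activation time course
#'
#' Holds the ordered sampling times (hours after activation; the first time is
#' always 0, the untreated condition) together with the duration of the 4sU
#' metabolic-labeling window that precedes each collection.
#'
#' @slot times Numeric vector of sampling times in hours, strictly increasing,
#'   starting at 0.
#' @slot labelingDuration Length of the 4sU labeling window in hours
#'   (default 1/6 h = 10 min). Must not exceed the smallest gap between
#'   consecutive sampling times.
#' @export
setClass("TimeGrid", representation(times = "numeric",
                                    labelingDuration = "numeric"))

setValidity("TimeGrid", function(object) {
  t <- object@times
  if (length(t) < 2L) return("need at least two sampling times")
  if (t[1L] != 0) return("first sampling time must be 0 (untreated)")
  if (any(diff(t) <= 0)) return("sampling times must be strictly increasing")
  L <- object@labelingDuration
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    return("labelingDuration must be a single positive number")
  if (L > min(diff(t)) + 1e-12)
    return("labelingDuration exceeds the smallest inter-timepoint gap")
  TRUE
})

#' Construct a TimeGrid
#'
#' @param times Sampling times in hours; defaults to the untreated condition
#'   followed by 10 min, 30 min, 1 h, 2 h and 4 h of activation.
#' @param labelingDuration 4sU labeling window in hours (default 10 min).
#' @return A [TimeGrid-class] object.
#' @examples
#' TimeGrid()
#' TimeGrid(times = c(0, 0.5, 1, 2), labelingDuration = 0.25)
#' @export
TimeGrid <- function(times = c(0, 1/6, 1/2, 1, 2, 4), labelingDuration = 1/6) {
  new("TimeGrid", times = as.numeric(times),
      labelingDuration = as.numeric(labelingDuration))
}

#' @describeIn TimeGrid-class sampling times in hours
#' @param x,object A `TimeGrid`.
#' @export
setMethod("length", "TimeGrid", function(x) length(x@times))

#' Sampling times of a TimeGrid
#' @param x A [TimeGrid-class].
#' @return Numeric vector of times in hours.
#' @export
gridTimes <- function(x) x@times

#' Labeling-window duration of a TimeGrid
#' @param x A [TimeGrid-class].
#' @return Labeling duration in hours.
#' @export
labelingDuration <- function(x) x@labelingDuration

setMethod("show", "TimeGrid", function(object) {
  cat("TimeGrid:", paste(signif(object@times, 4), collapse = ", "),
      "h; labeling", signif(object@labelingDuration * 60, 3), "min\n")
})

#' Multiplicative noise model for synthetic signal tables
#'
#' @slot scheme Either `"lognormal"` (multiplicative log-normal noise with the
#'   stated coefficient of variation) or `"poisson_lognormal"` (the log-normal
#'   expectation is additionally resampled as Poisson counts at the stated
#'   sequencing depth).
#' @slot cv Coefficient of variation of the multiplicative noise (>= 0).
#' @slot depth Expected library size in reads (> 0).
#' @export
setClass("NoiseModel", representation(scheme = "character", cv = "numeric",
                                      depth = "numeric"))

setValidity("NoiseModel", function(object) {
  if (!object@scheme %in% c("lognormal", "poisson_lognormal"))
    return("scheme must be 'lognormal' or 'poisson_lognormal'")
  if (object@cv < 0) return("cv must be >= 0")
  if (object@depth <= 0) return("depth must be > 0")
  TRUE
})

#' Construct a NoiseModel
#'
#' @param cv Coefficient of variation of multiplicative noise (default 0.2).
#' @param scheme `"lognormal"` or `"poisson_lognormal"`.
#' @param depth Expected library size (reads); used for library-size metadata
#'   and for Poisson resampling.
#' @return A [NoiseModel-class] object.
#' @examples
#' NoiseModel(cv = 0)        # noiseless
#' NoiseModel(cv = 0.2)      # default study conditions
#' @export
NoiseModel <- function(cv = 0.2, scheme = c("lognormal", "poisson_lognormal"),
                       depth = 2e7) {
  scheme <- match.arg(scheme)
  new("NoiseModel", scheme = scheme, cv = as.numeric(cv),
      depth = as.numeric(depth))
}

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel:", object@scheme, "cv =", object@cv,
      "depth =", format(object@depth, big.mark = ","), "\n")
})

#' Genes x timepoints x replicates signal container
#'
#' One assay/region quantification (ChIP-seq counts in a window, or exonic /
#' intronic RNA-seq quantification) for a gene cohort over a [TimeGrid-class],
#' with per-(timepoint, replicate) library sizes.
#'
#' @slot assay Assay label, one of `"MYC"`, `"ZBTB17"`, `"RNAPII_promoter"`,
#'   `"RNAPII_genebody"`, `"RNAPII_tes"`, `"total_exon"`, `"total_intron"`,
#'   `"nascent_exon"`, `"nascent_intron"`.
#' @slot values 3-dimensional array `genes x timepoints x replicates` of
#'   non-negative values, with gene identifiers as rownames.
#' @slot librarySizes `timepoints x replicates` matrix of positive library
#'   sizes.
#' @slot timeGrid The [TimeGrid-class] of the experiment.
#' @slot normalized Logical; `TRUE` once values are on the counts-per-million
#'   scale.
#' @export
setClass("SignalTable", representation(assay = "character", values = "array",
                                       librarySizes = "matrix",
                                       timeGrid = "TimeGrid",
                                       normalized = "logical"))

.signalAssays <- c("MYC", "ZBTB17", "RNAPII_promoter", "RNAPII_genebody",
                   "RNAPII_tes", "total_exon", "total_intron", "nascent_exon",
                   "nascent_intron")

setValidity("SignalTable", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-d array")
  if (!object@assay %in% .signalAssays)
    return(paste("unknown assay; must be one of:",
                 paste(.signalAssays, collapse = ", ")))
  if (any(!is.finite(v)) || any(v < 0))
    return("values must be finite and non-negative")
  nt <- length(object@timeGrid@times)
  if (dim(v)[2L] != nt) return("values/timeGrid timepoint mismatch")
  if (nrow(object@librarySizes) != nt ||
      ncol(object@librarySizes) != dim(v)[3L])
    return("librarySizes must be timepoints x replicates")
  if (any(object@librarySizes <= 0)) return("library sizes must be > 0")
  if (is.null(rownames(v))) return("values must carry gene ids as rownames")
  TRUE
})

#' Construct a SignalTable
#'
#' @param assay Assay label (see [SignalTable-class]).
#' @param values `genes x timepoints x replicates` array (a matrix is treated
#'   as a single replicate); rownames are gene identifiers.
#' @param librarySizes `timepoints x replicates` matrix, or a single number
#'   recycled to all libraries.
#' @param timeGrid A [TimeGrid-class].
#' @param normalized Whether `values` are already counts-per-million.
#' @return A [SignalTable-class].
#' @export
SignalTable <- function(assay, values, librarySizes, timeGrid,
                        normalized = FALSE) {
  if (length(dim(values)) == 2L)
    values <- array(values, dim = c(dim(values), 1L),
                    dimnames = c(dimnames(values), list(NULL)))
  nt <- dim(values)[2L]; nr <- dim(values)[3L]
  if (length(librarySizes) == 1L)
    librarySizes <- matrix(librarySizes, nt, nr)
  new("SignalTable", assay = assay, values = values,
      librarySizes = as.matrix(librarySizes), timeGrid = timeGrid,
      normalized = isTRUE(normalized))
}

#' @describeIn SignalTable-class gene identifiers
#' @param object,x A `SignalTable`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SignalTable-class
#' @export
setMethod("geneIds", "SignalTable", function(x) rownames(x@values))

#' Raw value array of a SignalTable
#' @param x A [SignalTable-class].
#' @return The `genes x timepoints x replicates` array.
#' @export
signalValues <- function(x) x@values

#' Library sizes of a SignalTable
#' @param x A [SignalTable-class].
#' @return `timepoints x replicates` matrix.
#' @export
librarySizes <- function(x) x@librarySizes

#' TimeGrid of a SignalTable (or other container carrying one)
#' @param x Object with a `timeGrid` slot.
#' @return A [TimeGrid-class].
#' @export
timeGrid <- function(x) x@timeGrid

#' Assay label of a SignalTable
#' @param x A [SignalTable-class].
#' @return Character scalar.
#' @export
assayName <- function(x) x@assay

setMethod("show", "SignalTable", function(object) {
  d <- dim(object@values)
  cat("SignalTable [", object@assay, "]: ", d[1L], " genes x ", d[2L],
      " timepoints x ", d[3L], " replicates",
      if (object@normalized) " (CPM)" else " (raw)", "\n", sep = "")
})

setMethod("dim", "SignalTable", function(x) dim(x@values))

#' Per-gene promoter / gene-body / TES windows
#'
#' Strand-oriented, pairwise non-overlapping windows derived from a gene
#' annotation. Genes too short to host all three windows are listed in
#' `excluded` and carried with zero-width placeholders.
#'
#' @slot promoter,geneBody,tes `GRanges`, parallel over genes.
#' @slot excluded Character vector of gene ids flagged as too short for
#'   RNAPII modeling.
#' @export
setClass("RegionSet", representation(promoter = "GRanges",
                                     geneBody = "GRanges", tes = "GRanges",
                                     excluded = "character"))

setValidity("RegionSet", function(object) {
  n <- length(object@promoter)
  if (length(object@geneBody) != n || length(object@tes) != n)
    return("promoter/geneBody/tes must be parallel")
  TRUE
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet:", length(object@promoter), "genes,",
      length(object@excluded), "excluded (too short)\n")
})

#' Ground truth of a synthetic MYC-activation cohort
#'
#' Per-gene regulatory class, kinetic rate trajectories (RNA synthesis k1,
#' processing k2, degradation k3), RNAPII compartment parameters (p1 promoter
#' flux, p2 pause-release, p3 elongation, p4 TES release), expected MYC
#' promoter binding, and the noiseless compartment trajectories — the oracle
#' against which every inference stage is tested.
#'
#' @slot geneIds Character vector of gene identifiers.
#' @slot geneClass Factor with levels `induced`, `repressed`, `unresponsive`.
#' @slot grid The [TimeGrid-class] of the cohort.
#' @slot seed Integer seed that produced the cohort.
#' @slot binding `genes x timepoints` expected MYC promoter signal
#'   (normalized units, noiseless), rescaled so the cohort total increases by
#'   the configured global gain at activated timepoints.
#' @slot k1,k2,k3 `genes x timepoints` true rate values at the grid times
#'   (k1 in abundance/h, k2 and k3 in 1/h).
#' @slot p1,p2,p3,p4 `genes x timepoints` true RNAPII parameters at the grid
#'   times (p1 in density/h, others 1/h).
#' @slot fine List with the dense-time evaluation used to generate the data:
#'   `times`, `obsIdx`, and `genes x fine-times` matrices `k1`, `k2`, `k3`,
#'   `Pr`, `Gb`, `Te`, `P`, `M`.
#' @slot specs Per-gene rate-function specifications (list).
#' @export
setClass("GroundTruth", representation(geneIds = "character",
                                       geneClass = "factor",
                                       grid = "TimeGrid", seed = "integer",
                                       binding = "matrix", k1 = "matrix",
                                       k2 = "matrix", k3 = "matrix",
                                       p1 = "matrix", p2 = "matrix",
                                       p3 = "matrix", p4 = "matrix",
                                       fine = "list", specs = "list"))

setValidity("GroundTruth", function(object) {
  n <- length(object@geneIds)
  nt <- length(object@grid@times)
  for (s in c("binding", "k1", "k2", "k3", "p1", "p2", "p3", "p4")) {
    m <- slot(object, s)
    if (nrow(m) != n || ncol(m) != nt)
      return(paste(s, "must be genes x timepoints"))
  }
  if (length(object@geneClass) != n) return("geneClass length mismatch")
  if (!all(levels(object@geneClass) %in%
           c("induced", "repressed", "unresponsive")))
    return("invalid class levels")
  if (any(object@k2 <= 0) || any(object@k3 <= 0))
    return("k2 and k3 must be positive")
  if (any(object@p2 <= 0) || any(object@p3 <= 0) || any(object@p4 <= 0))
    return("p2, p3, p4 must be positive")
  if (any(object@p1[, 1L] < 0)) return("p1 must be non-negative at t = 0")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@geneIds), "genes (",
      paste(names(table(object@geneClass)), table(object@geneClass),
            sep = "=", collapse = ", "),
      ") over", length(object@grid@times), "timepoints; seed",
      object@seed, "\n")
})

#' @rdname GroundTruth-class
#' @param x A `GroundTruth`.
#' @export
setMethod("geneIds", "GroundTruth", function(x) x@geneIds)

#' True regulatory class of each gene
#' @param x A [GroundTruth-class].
#' @return Factor of classes, named by gene.
#' @export
geneClass <- function(x) setNames(x@geneClass, x@geneIds)

#' True RNA kinetic rates at the grid times
#' @param x A [GroundTruth-class].
#' @return List of `genes x timepoints` matrices `k1`, `k2`, `k3`.
#' @export
trueKinetics <- function(x) list(k1 = x@k1, k2 = x@k2, k3 = x@k3)

#' True RNAPII compartment parameters at the grid times
#' @param x A [GroundTruth-class].
#' @return List of `genes x timepoints` matrices `p1`..`p4`.
#' @export
truePolymerase <- function(x) list(p1 = x@p1, p2 = x@p2, p3 = x@p3, p4 = x@p4)

#' Time-resolved RNAPII compartment parameters
#'
#' Node values of the four rates at the grid times, interpreted as a
#' piecewise-linear (default) or piecewise-constant function of time.
#' p1 (promoter flux, density/h) may be negative after activation; p2-p4
#' (pause-release, elongation, TES release; 1/h) are positive.
#'
#' @slot times Node times (hours).
#' @slot p1,p2,p3,p4 Node values, parallel to `times`.
#' @slot interpolation `"linear"` or `"constant"` (left-continuous steps).
#' @export
setClass("PolymeraseRates", representation(times = "numeric", p1 = "numeric",
                                           p2 = "numeric", p3 = "numeric",
                                           p4 = "numeric",
                                           interpolation = "character"))

setValidity("PolymeraseRates", function(object) {
  n <- length(object@times)
  if (any(lengths(list(object@p1, object@p2, object@p3, object@p4)) != n))
    return("rate vectors must be parallel to times")
  if (any(object@p2 <= 0) || any(object@p3 <= 0) || any(object@p4 <= 0))
    return("p2, p3, p4 must be > 0")
  if (!object@interpolation %in% c("linear", "constant"))
    return("interpolation must be 'linear' or 'constant'")
  TRUE
})

#' Construct PolymeraseRates
#' @param times Node times in hours.
#' @param p1,p2,p3,p4 Node values (recycled if scalar).
#' @param interpolation `"linear"` (default) or `"constant"`.
#' @return A [PolymeraseRates-class].
#' @examples
#' PolymeraseRates(c(0, 1, 2), p1 = 60, p2 = 2, p3 = 3, p4 = 6)
#' @export
PolymeraseRates <- function(times, p1, p2, p3, p4,
                            interpolation = c("linear", "constant")) {
  n <- length(times)
  new("PolymeraseRates", times = as.numeric(times),
      p1 = rep_len(as.numeric(p1), n), p2 = rep_len(as.numeric(p2), n),
      p3 = rep_len(as.numeric(p3), n), p4 = rep_len(as.numeric(p4), n),
      interpolation = match.arg(interpolation))
}

setMethod("show", "PolymeraseRates", function(object) {
  cat("PolymeraseRates over", length(object@times), "nodes (",
      object@interpolation, "interpolation )\n")
  print(round(rbind(t = object@times, p1 = object@p1, p2 = object@p2,
                    p3 = object@p3, p4 = object@p4), 4))
})
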