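#' @importFrom BiocGenerics counts
NULL

#' Construct a CountMatrix
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param condition character, one per sample; one of `steady_state`, `Hh`,
#'   `aIL10R`, `Hh_aIL10R`.
#' @param assayType `"DNA"` or `"RNA"`, one per sample (recycled if length 1).
#' @param librarySize positive integer per sample: total aligned reads, the
#'   per-million denominator (may exceed the column sum).
#' @param featureKind what the rows are: `"genus"`, `"NOG"`, `"genus_by_NOG"`
#'   or `"host_gene"`.
#' @return a [CountMatrix-class].
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' CountMatrix(m, condition = c("steady_state", "Hh_aIL10R"),
#'             assayType = "DNA", librarySize = c(10, 10),
#'             featureKind = "genus")
#' @export
CountMatrix <- function(counts, condition, assayType, librarySize, featureKind) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature and sample names")
  assayType <- rep(assayType, length.out = ncol(counts))
  cd <- S4Vectors::DataFrame(condition = condition,
                             assay_type = assayType,
                             library_size = librarySize,
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("CountMatrix", se, featureKind = featureKind)
}

#' @describeIn CountMatrix the raw count matrix.
#' @param object,x a `CountMatrix`.
#' @param ... unused.
#' @export
setMethod("counts", "CountMatrix", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Feature kind of a count or normalized matrix
#' @param x a [CountMatrix-class] or [NormalizedMatrix-class].
#' @return a character scalar.
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname featureKind
#' @export
setMethod("featureKind", "CountMatrix", function(x) x@featureKind)

#' @rdname featureKind
#' @export
setMethod("featureKind", "NormalizedMatrix", function(x) x@featureKind)

#' Per-sample library sizes (total aligned reads)
#' @param x a [CountMatrix-class] or [NormalizedMatrix-class].
#' @return named numeric vector.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

.librarySizes <- function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$library_size, colnames(x))
}

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "CountMatrix", .librarySizes)

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "NormalizedMatrix", .librarySizes)

#' Per-sample condition labels
#' @param x a [CountMatrix-class] or [NormalizedMatrix-class].
#' @return named character vector.
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

.sampleConditions <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$condition),
                  colnames(x))
}

#' @rdname sampleConditions
#' @export
setMethod("sampleConditions", "CountMatrix", .sampleConditions)

#' @rdname sampleConditions
#' @export
setMethod("sampleConditions", "NormalizedMatrix", .sampleConditions)

#' Normalized values of a NormalizedMatrix
#' @param x a [NormalizedMatrix-class].
#' @return numeric matrix.
#' @export
normValues <- function(x) {
  stopifnot(is(x, "NormalizedMatrix"))
  SummarizedExperiment::assay(x, "values")
}

#' Normalization tag of a NormalizedMatrix
#' @param x a [NormalizedMatrix-class].
#' @return `"rpm"` or `"css"`.
#' @export
normMethod <- function(x) {
  stopifnot(is(x, "NormalizedMatrix"))
  x@normalization
}

#' Hit records of a HitTable
#' @param x a [HitTable-class].
#' @return the underlying `data.frame`, one row per hit.
#' @export
hitRecords <- function(x) {
  stopifnot(is(x, "HitTable"))
  x@hits
}

#' Number of distinct reads in a HitTable
#' @param x a [HitTable-class].
#' @return integer.
#' @export
nReads <- function(x) {
  stopifnot(is(x, "HitTable"))
  length(unique(x@hits$read_id))
}

#' Node table of a TaxonomyTree
#' @param x a [TaxonomyTree-class].
#' @return `data.frame` with columns `id`, `parent`, `rank`, `name`.
#' @export
taxNodes <- function(x) {
  stopifnot(is(x, "TaxonomyTree"))
  x@nodes
}

#' Root node id of a TaxonomyTree
#' @param x a [TaxonomyTree-class].
#' @return character scalar.
#' @export
taxRoot <- function(x) {
  nd <- taxNodes(x)
  nd$id[nd$parent == nd$id | is.na(nd$parent)]
}

#' Planted per-genus truth
#' @param x a [GroundTruth-class].
#' @return `data.frame`.
#' @export
genusTruth <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@genera
}

#' Planted per-NOG truth
#' @param x a [GroundTruth-class].
#' @return `data.frame`.
#' @export
nogTruth <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@nogs
}

#' Construct hit-filtering parameters
#'
#' @param minScore minimum bit score, default 50.
#' @param maxEvalue maximum e-value, default 0.01.
#' @param topPercent top-percent retention window, default 50.
#' @return an [AssignmentParams-class].
#' @export
assignmentParams <- function(minScore = 50, maxEvalue = 0.01, topPercent = 50) {
  new("AssignmentParams", minScore = minScore, maxEvalue = maxEvalue,
      topPercent = topPercent)
}

#' Construct a synthetic-community configuration
#'
#' Defaults describe the package's reference colitis scenario: 50 genera with
#' 20 NOGs each, log-normal base abundances (log-sd 1.5), 20% of genera
#' shifted by 2 log2 units in the colitis condition (signs split at random),
#' unit RNA/DNA coupling slope with 0.3 log2 units of coupling noise, 5% of
#' NOGs carrying a 3-log2-unit RNA-only ("responsive") offset, 8 samples per
#' condition and one million reads per sample and assay.
#'
#' @param nGenera,nogsPerGenus community size.
#' @param baseAbundanceLogmean,baseAbundanceLogsd log-normal genus abundances
#'   (natural-log scale).
#' @param couplingSlope,couplingNoiseSd RNA-on-DNA fold-change coupling.
#' @param fracDifferential,differentialLog2fc planted DNA effect.
#' @param fracResponsive,responsiveOffset planted RNA-only offset (log2).
#' @param depthDna,depthRna reads per sample.
#' @param nPerGroup samples per condition.
#' @param sampleJitterSd per-sample log-normal abundance jitter (natural-log
#'   sd), shared between the paired DNA and RNA assay of a sample.
#' @param seed integer seed.
#' @return a [CommunityConfig-class].
#' @export
communityConfig <- function(nGenera = 50, nogsPerGenus = 20,
                            baseAbundanceLogmean = 0, baseAbundanceLogsd = 1.5,
                            couplingSlope = 1, couplingNoiseSd = 0.3,
                            fracDifferential = 0.2, differentialLog2fc = 2,
                            fracResponsive = 0.05, responsiveOffset = 3,
                            depthDna = 1e6, depthRna = 1e6,
                            nPerGroup = 8, sampleJitterSd = 0.3,
                            seed = 1) {
  new("CommunityConfig",
      nGenera = nGenera, nogsPerGenus = nogsPerGenus,
      baseAbundanceLogmean = baseAbundanceLogmean,
      baseAbundanceLogsd = baseAbundanceLogsd,
      couplingSlope = couplingSlope, couplingNoiseSd = couplingNoiseSd,
      fracDifferential = fracDifferential,
      differentialLog2fc = differentialLog2fc,
      fracResponsive = fracResponsive, responsiveOffset = responsiveOffset,
      depthDna = depthDna, depthRna = depthRna,
      nPerGroup = nPerGroup, sampleJitterSd = sampleJitterSd,
      seed = seed)
}
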