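#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

TAXONOMY_RANKS <- c("root", "superkingdom", "phylum", "class", "order",
                    "family", "genus", "species", "no_rank")

CONDITION_LEVELS <- c("steady_state", "Hh", "aIL10R", "Hh_aIL10R")

ASSAY_TYPES <- c("DNA", "RNA")

FEATURE_KINDS <- c("genus", "NOG", "genus_by_NOG", "host_gene")

#' TaxonomyTree: a rooted, ranked taxonomy
#'
#' Holds a rooted taxonomy as a node table with parent links and ranks.  A
#' single root (its own parent) is required, parent links must be acyclic, and
#' every node must be reachable from the root.  Ranks follow the usual NCBI
#' convention (`superkingdom` .. `species`, plus `no_rank`).
#'
#' @slot nodes a `data.frame` with columns `id`, `parent`, `rank`, `name`
#'   (all character except that ids may be given as integers and are coerced).
#' @seealso [loadTaxonomy()], [lca()], [projectToRank()]
#' @export
setClass("TaxonomyTree", slots = c(nodes = "data.frame"))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  req <- c("id", "parent", "rank", "name")
  if (!all(req %in% colnames(nd)))
    return(paste("nodes must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(nd$id))
    return("node ids must be unique")
  if (!all(nd$rank %in% TAXONOMY_RANKS))
    return(paste("unknown rank(s):",
                 paste(setdiff(unique(nd$rank), TAXONOMY_RANKS), collapse = ", ")))
  rootSel <- nd$parent == nd$id | is.na(nd$parent)
  if (sum(rootSel) != 1L)
    return(sprintf("exactly one root required (self-parent or NA parent), found %d",
                   sum(rootSel)))
  orphan <- !is.na(nd$parent) & !(nd$parent %in% nd$id)
  if (any(orphan))
    return(paste("orphan node(s) with undefined parent:",
                 paste(nd$id[orphan], collapse = ", ")))
  # reachability from the root (equivalently: no cycles off the root)
  parent <- stats::setNames(nd$parent, nd$id)
  root <- nd$id[rootSel]
  reached <- stats::setNames(rep(FALSE, nrow(nd)), nd$id)
  reached[root] <- TRUE
  repeat {
    newly <- !reached & reached[parent[names(reached)]]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    reached[newly] <- TRUE
  }
  if (!all(reached))
    return(paste("cycle detected: node(s) not reachable from root, e.g.",
                 names(reached)[!reached][1L]))
  TRUE
})

#' HitTable: per-read tabular protein-alignment hits
#'
#' Stores one row per alignment hit, grouped by read in input order.  The
#' quantities retained are those the assignment-stage filters operate on
#' (bit score, e-value) plus the two annotation channels: a taxonomy node and
#' an orthologous-group (NOG) identifier, either of which may be missing.
#'
#' @slot hits a `data.frame` with columns `read_id`, `subject_id`,
#'   `bit_score`, `e_value`, `taxon_id`, `nog_id`.
#' @seealso [parseTabularAlignment()], [assignReads()]
#' @export
setClass("HitTable", slots = c(hits = "data.frame"))

setValidity("HitTable", function(object) {
  h <- object@hits
  req <- c("read_id", "subject_id", "bit_score", "e_value", "taxon_id", "nog_id")
  if (!all(req %in% colnames(h)))
    return(paste("hits must have columns", paste(req, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$bit_score < 0)) return("bit_score must be >= 0")
    if (any(h$e_value < 0)) return("e_value must be >= 0")
    # grouping by read must be contiguous (exhaustive, non-overlapping)
    r <- rle(h$read_id)$values
    if (anyDuplicated(r))
      return("records of one read must be contiguous")
  }
  TRUE
})

#' CountMatrix: feature-by-sample read counts with assay metadata
#'
#' The universal currency between pipeline stages: a
#' [SummarizedExperiment::SummarizedExperiment] whose single `"counts"` assay
#' holds non-negative integer read counts, whose `colData` carries the sample
#' condition, assay type (DNA or RNA) and library size, and which records what
#' kind of feature the rows are (genus, NOG, genus-by-NOG pair, or host gene).
#'
#' The library size is the total number of aligned reads for the sample and is
#' the denominator of reads-per-million scaling; it may exceed the column sum
#' because not every aligned read is assignable to a feature.  It is carried as
#' metadata and never recomputed from column sums.
#'
#' @slot featureKind one of `"genus"`, `"NOG"`, `"genus_by_NOG"`, `"host_gene"`.
#' @seealso [CountMatrix()], [readCounts()], [cssNormalize()], [rpmNormalize()]
#' @export
setClass("CountMatrix",
         contains = "SummarizedExperiment",
         slots = c(featureKind = "character"))

setValidity("CountMatrix", function(object) {
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% FEATURE_KINDS)
    return(paste("featureKind must be one of",
                 paste(FEATURE_KINDS, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(m != round(m))) return("counts must be integral")
  cd <- SummarizedExperiment::colData(object)
  req <- c("condition", "assay_type", "library_size")
  if (!all(req %in% colnames(cd)))
    return(paste("colData must have columns", paste(req, collapse = ", ")))
  if (!all(cd$condition %in% CONDITION_LEVELS))
    return(paste("condition must be one of",
                 paste(CONDITION_LEVELS, collapse = ", ")))
  if (!all(cd$assay_type %in% ASSAY_TYPES))
    return("assay_type must be 'DNA' or 'RNA'")
  if (any(cd$library_size <= 0)) return("library_size must be positive")
  if (anyDuplicated(rownames(object))) return("feature ids must be unique")
  if (anyDuplicated(colnames(object))) return("sample ids must be unique")
  TRUE
})

#' NormalizedMatrix: normalized (real-valued) abundances
#'
#' Same shape as a [CountMatrix-class] but holding real values in a `"values"`
#' assay, tagged with the normalization that produced it (`"rpm"` or `"css"`).
#' Normalized matrices are a distinct class from count matrices so that a
#' normalized matrix can never be fed back into a stage expecting raw counts.
#'
#' @slot normalization `"rpm"` or `"css"`.
#' @slot cssQuantile quantile used by CSS (NA for rpm).
#' @slot cssScale scale constant used by CSS (NA for rpm).
#' @slot featureKind as in [CountMatrix-class].
#' @export
setClass("NormalizedMatrix",
         contains = "SummarizedExperiment",
         slots = c(normalization = "character",
                   cssQuantile = "numeric",
                   cssScale = "numeric",
                   featureKind = "character"))

setValidity("NormalizedMatrix", function(object) {
  if (!object@normalization %in% c("rpm", "css"))
    return("normalization must be 'rpm' or 'css'")
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    return("a 'values' assay is required")
  if (any(SummarizedExperiment::assay(object, "values") < 0))
    return("normalized values must be >= 0")
  TRUE
})

#' CommunityConfig: parameters of the synthetic paired community
#'
#' Describes the world the generator simulates: a log-normal genus abundance
#' profile, a colitis condition that shifts a fraction of genera by a planted
#' log2 fold change, per-genus NOG weights from a symmetric Dirichlet, an
#' RNA/DNA coupling model `RNA log2FC = beta * DNA log2FC + eps`, and a planted
#' subset of NOGs whose RNA fold change carries an additional offset `delta`
#' (the "responsive" NOGs).  Counts are multinomial at the configured depth,
#' so column sums equal the depth exactly; biological variability enters as a
#' per-sample log-normal jitter on genus abundances shared between the DNA and
#' RNA assay of the same sample.
#'
#' @slot nGenera number of genera.
#' @slot nogsPerGenus NOGs per genus (NOGs are genus-private).
#' @slot baseAbundanceLogmean,baseAbundanceLogsd log-normal genus abundances.
#' @slot couplingSlope beta of the RNA-on-DNA fold-change coupling.
#' @slot couplingNoiseSd sd of eps (log2 units).
#' @slot fracDifferential fraction of genera with a planted DNA effect.
#' @slot differentialLog2fc magnitude of the planted DNA effect (log2 units);
#'   the sign is drawn per genus so that both directions occur.
#' @slot fracResponsive fraction of NOGs with a planted RNA-only offset.
#' @slot responsiveOffset magnitude of delta (log2 units); sign drawn per NOG.
#' @slot depthDna,depthRna reads per sample.
#' @slot nPerGroup samples per condition (>= 2).
#' @slot sampleJitterSd sd of the per-sample log-normal abundance jitter.
#' @slot seed integer seed; identical seeds give bit-identical output.
#' @seealso [communityConfig()], [simulatePairedCounts()]
#' @export
setClass("CommunityConfig",
         slots = c(nGenera = "numeric", nogsPerGenus = "numeric",
                   baseAbundanceLogmean = "numeric", baseAbundanceLogsd = "numeric",
                   couplingSlope = "numeric", couplingNoiseSd = "numeric",
                   fracDifferential = "numeric", differentialLog2fc = "numeric",
                   fracResponsive = "numeric", responsiveOffset = "numeric",
                   depthDna = "numeric", depthRna = "numeric",
                   nPerGroup = "numeric", sampleJitterSd = "numeric",
                   seed = "numeric"))

setValidity("CommunityConfig", function(object) {
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v))
      return(sprintf("%s must be a single non-NA number", s))
  }
  if (object@nGenera < 2) return("nGenera must be >= 2")
  if (object@nogsPerGenus < 1) return("nogsPerGenus must be >= 1")
  if (object@fracDifferential < 0 || object@fracDifferential > 1)
    return("fracDifferential must be in [0, 1]")
  if (object@fracResponsive < 0 || object@fracResponsive > 1)
    return("fracResponsive must be in [0, 1]")
  if (object@depthDna <= 0 || object@depthRna <= 0)
    return("depths must be > 0")
  if (object@nPerGroup < 2) return("nPerGroup must be >= 2")
  if (object@couplingNoiseSd < 0) return("couplingNoiseSd must be >= 0")
  if (object@sampleJitterSd < 0) return("sampleJitterSd must be >= 0")
  TRUE
})

#' GroundTruth: the planted effects behind a simulated community
#'
#' Emitted alongside the simulated count matrices so downstream calls can be
#' scored against what was actually planted: per-genus DNA log2 fold changes
#' and labels, and per-NOG DNA/RNA log2 fold changes, differential labels, the
#' responsive label (sign of the planted RNA-only offset) and each NOG's genus
#' of origin.
#'
#' @slot genera `data.frame`: `genus`, `dna_log2fc`, `label`.
#' @slot nogs `data.frame`: `nog`, `genus`, `dna_log2fc`, `rna_log2fc`,
#'   `dna_label`, `rna_label`, `responsive`.
#' @export
setClass("GroundTruth",
         slots = c(genera = "data.frame", nogs = "data.frame"))

setValidity("GroundTruth", function(object) {
  if (!all(c("genus", "dna_log2fc", "label") %in% colnames(object@genera)))
    return("genera must have columns genus, dna_log2fc, label")
  req <- c("nog", "genus", "dna_log2fc", "rna_log2fc",
           "dna_label", "rna_label", "responsive")
  if (!all(req %in% colnames(object@nogs)))
    return(paste("nogs must have columns", paste(req, collapse = ", ")))
  if (!all(object@nogs$responsive %in% c("up", "down", "none")))
    return("responsive labels must be up/down/none")
  TRUE
})

#' AssignmentParams: hit-filtering parameters for taxonomic binning
#'
#' The three thresholds applied to a read's hits before the lowest common
#' ancestor is taken: a minimum bit score, a maximum e-value, and a
#' "top percent" window that keeps hits scoring at least
#' `best * (1 - topPercent/100)`, where the best score is computed after the
#' score/e-value filter.  Defaults correspond to the standard MEGAN-style
#' invocation (`-ms 50 -me 0.01 -tp 50`).
#'
#' @slot minScore minimum bit score (bits), default 50.
#' @slot maxEvalue maximum e-value, default 0.01.
#' @slot topPercent top-percent window in (0, 100], default 50.
#' @seealso [assignmentParams()], [filterHits()]
#' @export
setClass("AssignmentParams",
         slots = c(minScore = "numeric", maxEvalue = "numeric",
                   topPercent = "numeric"))

setValidity("AssignmentParams", function(object) {
  if (object@minScore < 0) return("minScore must be >= 0")
  if (object@maxEvalue <= 0) return("maxEvalue must be > 0")
  if (object@topPercent <= 0 || object@topPercent > 100)
    return("topPercent must be in (0, 100]")
  TRUE
})

#' FcRegression: OLS fit of RNA fold change on DNA fold change
#'
#' Summary of the ordinary least squares regression of per-feature RNA log2
#' fold change (response) on DNA log2 fold change (predictor), retaining
#' exactly the quantities needed to compute prediction intervals at any new
#' predictor value.
#'
#' @slot slope,intercept OLS coefficients.
#' @slot residualSd residual standard deviation, `sqrt(SSE / (n - 2))`.
#' @slot n number of points.
#' @slot xMean mean of the predictor.
#' @slot sxx centered sum of squares of the predictor.
#' @slot rSquared coefficient of determination.
#' @seealso [fitFcRegression()], [predictionInterval()], [classifyResponsive()]
#' @export
setClass("FcRegression",
         slots = c(slope = "numeric", intercept = "numeric",
                   residualSd = "numeric", n = "numeric",
                   xMean = "numeric", sxx = "numeric", rSquared = "numeric"))

setValidity("FcRegression", function(object) {
  if (object@n < 3) return("n must be >= 3")
  if (object@sxx <= 0) return("Sxx must be > 0")
  if (object@residualSd < 0) return("residualSd must be >= 0")
  TRUE
})

#' GseaResult: pre-ranked GSEA outcome for one query set
#'
#' @slot es signed enrichment score in \[-1, 1\].
#' @slot esPosition rank index at which the running sum attains its extremum.
#' @slot runningSum the full running-sum vector over the ranked list.
#' @slot pEmpirical add-one empirical p from the rank-permutation null.
#' @slot nPerm number of permutations used.
#' @slot leadingEdge query members at or before (after, for negative es) the
#'   extremum.
#' @seealso [enrichmentScore()], [gseaPreranked()], [leadingEdge()]
#' @export
setClass("GseaResult",
         slots = c(es = "numeric", esPosition = "numeric",
                   runningSum = "numeric", pEmpirical = "numeric",
                   nPerm = "numeric", leadingEdge = "character"))

## ---- show methods -----------------------------------------------------------

setMethod("show", "TaxonomyTree", function(object) {
  nd <- object@nodes
  cat("TaxonomyTree with", nrow(nd), "nodes\n")
  tab <- table(factor(nd$rank, levels = TAXONOMY_RANKS))
  tab <- tab[tab > 0]
  cat("  ranks:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "HitTable", function(object) {
  cat("HitTable:", nrow(object@hits), "hits over",
      length(unique(object@hits$read_id)), "reads\n")
})

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix (%s): %d features x %d samples\n",
              object@featureKind, nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  cat("  assays:", paste(unique(cd$assay_type), collapse = ", "),
      "| conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
})

setMethod("show", "NormalizedMatrix", function(object) {
  cat(sprintf("NormalizedMatrix (%s, %s): %d features x %d samples\n",
              object@normalization, object@featureKind,
              nrow(object), ncol(object)))
  if (object@normalization == "css")
    cat(sprintf("  css quantile p=%g, scale N=%g\n",
                object@cssQuantile, object@cssScale))
})

setMethod("show", "CommunityConfig", function(object) {
  cat("CommunityConfig:", object@nGenera, "genera x",
      object@nogsPerGenus, "NOGs/genus,",
      2 * object@nPerGroup, "samples/assay\n")
  cat(sprintf("  coupling beta=%g sd=%g | differential %g%% at %+g log2 | responsive %g%% at %g log2\n",
              object@couplingSlope, object@couplingNoiseSd,
              100 * object@fracDifferential, object@differentialLog2fc,
              100 * object@fracResponsive, object@responsiveOffset))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genera), "genera,", nrow(object@nogs), "NOGs\n")
  cat("  differential genera:", sum(object@genera$label != "none"),
      "| responsive NOGs:", sum(object@nogs$responsive != "none"), "\n")
})

setMethod("show", "AssignmentParams", function(object) {
  cat(sprintf("AssignmentParams: minScore=%g bits, maxEvalue=%g, topPercent=%g%%\n",
              object@minScore, object@maxEvalue, object@topPercent))
})

setMethod("show", "FcRegression", function(object) {
  cat(sprintf("FcRegression: y = %.4f + %.4f x (n=%d, s=%.4f, R2=%.3f)\n",
              object@intercept, object@slope, as.integer(object@n),
              object@residualSd, object@rSquared))
})

setMethod("show", "GseaResult", function(object) {
  cat(sprintf("GseaResult: es=%.4f at rank %d, p=%.4g (%d permutations), leading edge %d features\n",
              object@es, as.integer(object@esPosition), object@pEmpirical,
              as.integer(object@nPerm), length(object@leadingEdge)))
})
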