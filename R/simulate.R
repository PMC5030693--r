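## Synthetic paired-community generator.  The world it states: log-normal
## genus abundances; a colitis condition that multiplies a planted subset of
## genera by 2^(+/- differentialLog2fc); genus-private NOGs with symmetric
## Dirichlet weights; RNA fold change coupled to DNA fold change through
## RNA log2FC = beta * DNA log2FC + eps, plus a +/- delta offset for a
## planted "responsive" subset; per-sample log-normal jitter shared between
## the DNA and RNA assay of a sample (same animal); multinomial counts at
## fixed depth so column sums are exact.  A single seeded stream is consumed
## in a fixed stage order so identical seeds give bit-identical output.

.rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Simulate paired DNA/RNA count matrices with planted effects
#'
#' @param config a [CommunityConfig-class] (see [communityConfig()] for the
#'   default scenario).
#' @return list with elements `dna` and `rna` ([CountMatrix-class], NOG-level,
#'   `2 * nPerGroup` samples each: steady_state then Hh_aIL10R) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' sim <- simulatePairedCounts(communityConfig(nGenera = 5, nogsPerGenus = 3,
#'                                             depthDna = 1e4, depthRna = 1e4,
#'                                             nPerGroup = 2))
#' sim$dna
#' @export
simulatePairedCounts <- function(config) {
  stopifnot(is(config, "CommunityConfig"))
  validObject(config)
  G <- as.integer(config@nGenera)
  K <- as.integer(config@nogsPerGenus)
  nGrp <- as.integer(config@nPerGroup)
  set.seed(as.integer(config@seed))

  genera <- sprintf("G%03d", seq_len(G))
  nogs <- as.vector(t(outer(genera, sprintf("NOG%02d", seq_len(K)),
                            paste, sep = ".")))
  nogGenus <- rep(genera, each = K)

  # stage 1: base genus abundances (relative, log-normal)
  baseAbund <- exp(stats::rnorm(G, config@baseAbundanceLogmean,
                                config@baseAbundanceLogsd))
  names(baseAbund) <- genera

  # stage 2: planted DNA effects (signs split Bernoulli(1/2))
  nDiff <- round(config@fracDifferential * G)
  diffIdx <- if (nDiff > 0) sample.int(G, nDiff) else integer(0)
  dnaFc <- numeric(G)
  if (nDiff > 0)
    dnaFc[diffIdx] <- config@differentialLog2fc *
      sample(c(-1, 1), nDiff, replace = TRUE)
  names(dnaFc) <- genera

  # stage 3: per-genus NOG weights (symmetric Dirichlet)
  weights <- unlist(lapply(seq_len(G), function(g) .rdirichlet1(K)))
  names(weights) <- nogs

  # stage 4: responsive NOGs and coupling noise
  nNog <- G * K
  nResp <- round(config@fracResponsive * nNog)
  respIdx <- if (nResp > 0) sample.int(nNog, nResp) else integer(0)
  delta <- numeric(nNog)
  if (nResp > 0)
    delta[respIdx] <- config@responsiveOffset *
      sample(c(-1, 1), nResp, replace = TRUE)
  eps <- stats::rnorm(nNog, 0, config@couplingNoiseSd)
  nogDnaFc <- dnaFc[nogGenus]
  nogRnaFc <- config@couplingSlope * nogDnaFc + eps + delta

  # stage 5: per-sample genus jitter (shared between paired assays)
  nSamples <- 2L * nGrp
  condition <- rep(c("steady_state", "Hh_aIL10R"), each = nGrp)
  jitter <- matrix(exp(stats::rnorm(G * nSamples, 0, config@sampleJitterSd)),
                   G, nSamples, dimnames = list(genera, NULL))

  colitis <- condition == "Hh_aIL10R"
  sampleIds <- sprintf("%s_%d", ifelse(colitis, "colitis", "steady"),
                       c(seq_len(nGrp), seq_len(nGrp)))

  # per-NOG intensities per sample, then stage 6/7: multinomial counts
  drawAssay <- function(depth, rnaSide) {
    counts <- matrix(0L, nNog, nSamples, dimnames = list(nogs, sampleIds))
    for (s in seq_len(nSamples)) {
      genusAbund <- baseAbund * jitter[, s]
      if (colitis[s]) genusAbund <- genusAbund * 2^dnaFc
      intensity <- genusAbund[nogGenus] * weights
      if (rnaSide && colitis[s])
        intensity <- intensity * 2^(nogRnaFc - nogDnaFc)
      counts[, s] <- stats::rmultinom(1L, size = depth,
                                      prob = intensity / sum(intensity))
    }
    counts
  }
  dnaCounts <- drawAssay(as.integer(config@depthDna), rnaSide = FALSE)
  rnaCounts <- drawAssay(as.integer(config@depthRna), rnaSide = TRUE)

  lab <- function(fc) ifelse(fc > 0, "up", ifelse(fc < 0, "down", "none"))
  genusLabel <- lab(dnaFc)
  planted <- nogDnaFc != 0 | delta != 0
  rnaLabel <- ifelse(planted, lab(nogRnaFc), "none")
  truth <- new("GroundTruth",
               genera = data.frame(genus = genera, dna_log2fc = unname(dnaFc),
                                   label = unname(genusLabel),
                                   stringsAsFactors = FALSE),
               nogs = data.frame(nog = nogs, genus = nogGenus,
                                 dna_log2fc = unname(nogDnaFc),
                                 rna_log2fc = unname(nogRnaFc),
                                 dna_label = unname(lab(nogDnaFc)),
                                 rna_label = unname(rnaLabel),
                                 responsive = unname(lab(delta)),
                                 stringsAsFactors = FALSE))
  asCm <- function(counts, assay, depth) {
    CountMatrix(counts, condition = condition, assayType = assay,
                librarySize = rep(depth, nSamples), featureKind = "NOG")
  }
  list(dna = asCm(dnaCounts, "DNA", as.integer(config@depthDna)),
       rna = asCm(rnaCounts, "RNA", as.integer(config@depthRna)),
       truth = truth)
}

#' Aggregate a NOG-level simulated matrix to genus level
#'
#' Sums NOG counts by each NOG's genus of origin.
#'
#' @param m a NOG-level [CountMatrix-class] from [simulatePairedCounts()].
#' @param truth the matching [GroundTruth-class].
#' @return a genus-level [CountMatrix-class].
#' @export
aggregateToGenus <- function(m, truth) {
  map <- stats::setNames(nogTruth(truth)$genus, nogTruth(truth)$nog)
  genus <- map[rownames(m)]
  if (any(is.na(genus))) stop("features absent from the ground truth")
  agg <- rowsum(counts(m), group = genus)
  cd <- SummarizedExperiment::colData(m)
  CountMatrix(agg, condition = cd$condition, assayType = cd$assay_type,
              librarySize = cd$library_size, featureKind = "genus")
}

#' Simulate a hit table with planted genus truth
#'
#' Each read's best hit targets a species leaf of its true genus with a bit
#' score drawn from Normal(100, 5); with probability `decoyProb` a decoy hit
#' to a uniformly chosen other genus is added at `best - scoreGap` bits.
#' E-values are monotone in score (`10^(-score/10)`), so score and e-value
#' filters act consistently.  A decoy gap larger than the top-percent window
#' guarantees the decoy is filtered and the LCA lands inside the true genus.
#'
#' @param tree a [TaxonomyTree-class] with at least two genera carrying
#'   species leaves.
#' @param nReads number of reads.
#' @param decoyProb probability of adding a decoy hit, default 0.
#' @param scoreGap bits between best hit and decoy, default 60.
#' @param seed integer seed.
#' @return list with `hits` (a [HitTable-class]; records carry `taxon_id` and
#'   a per-genus `nog_id`) and `truth` (named character: read id -> true
#'   genus node id).
#' @export
simulateHitTable <- function(tree, nReads, decoyProb = 0, scoreGap = 60,
                             seed = 1) {
  stopifnot(decoyProb >= 0, decoyProb <= 1, nReads >= 0)
  nd <- taxNodes(tree)
  parent <- stats::setNames(nd$parent, nd$id)
  species <- nd$id[nd$rank == "species"]
  genusOf <- .rankAncestor(tree, "genus")
  leaves <- species[!is.na(genusOf[species])]
  genera <- unique(genusOf[leaves])
  if (length(genera) < 2L)
    stop("tree needs >= 2 genera with species leaves")
  leavesByGenus <- split(leaves, genusOf[leaves])
  emptyHits <- data.frame(read_id = character(), subject_id = character(),
                          bit_score = numeric(), e_value = numeric(),
                          taxon_id = character(), nog_id = character(),
                          stringsAsFactors = FALSE)
  if (nReads == 0)
    return(list(hits = new("HitTable", hits = emptyHits),
                truth = character(0)))
  set.seed(as.integer(seed))
  rows <- vector("list", nReads)
  truth <- character(nReads)
  for (i in seq_len(nReads)) {
    g <- sample(genera, 1L)
    truth[i] <- g
    leaf <- sample(leavesByGenus[[g]], 1L)
    best <- stats::rnorm(1L, 100, 5)
    readId <- sprintf("r%05d", i)
    hit <- data.frame(read_id = readId,
                      subject_id = paste0("s_", leaf),
                      bit_score = best, e_value = 10^(-best / 10),
                      taxon_id = leaf, nog_id = paste0("NOG_", g),
                      stringsAsFactors = FALSE)
    if (decoyProb > 0 && stats::runif(1L) < decoyProb) {
      og <- sample(setdiff(genera, g), 1L)
      oleaf <- sample(leavesByGenus[[og]], 1L)
      ds <- best - scoreGap
      hit <- rbind(hit, data.frame(read_id = readId,
                                   subject_id = paste0("d_", oleaf),
                                   bit_score = ds,
                                   e_value = 10^(-ds / 10),
                                   taxon_id = oleaf,
                                   nog_id = paste0("NOG_", og),
                                   stringsAsFactors = FALSE))
    }
    rows[[i]] <- hit
  }
  names(truth) <- sprintf("r%05d", seq_len(nReads))
  list(hits = new("HitTable", hits = do.call(rbind, rows)), truth = truth)
}

#' Write a simulated scenario to disk
#'
#' Emits the counts TSV pair per assay, a shared metadata TSV and a
#' ground-truth TSV, as plain tab-separated text.
#'
#' @param sim output of [simulatePairedCounts()].
#' @param dir output directory (created if needed).
#' @return invisibly the named vector of paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dna_counts = file.path(dir, "dna_counts.tsv"),
             dna_metadata = file.path(dir, "dna_metadata.tsv"),
             rna_counts = file.path(dir, "rna_counts.tsv"),
             rna_metadata = file.path(dir, "rna_metadata.tsv"),
             truth_nogs = file.path(dir, "truth_nogs.tsv"),
             truth_genera = file.path(dir, "truth_genera.tsv"))
  writeCounts(sim$dna, paths["dna_counts"], paths["dna_metadata"])
  writeCounts(sim$rna, paths["rna_counts"], paths["rna_metadata"])
  utils::write.table(nogTruth(sim$truth), paths["truth_nogs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genusTruth(sim$truth), paths["truth_genera"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
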