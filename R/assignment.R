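## Taxonomic binning: MEGAN-style hit filtering, lowest common ancestor,
## rank projection, best-hit NOG annotation and the alternative-hit
## concordance statistic used to validate the best-hit convention.

.ancestorPath <- function(parent, id) {
  # path from root to id (inclusive)
  path <- character(0)
  cur <- id
  repeat {
    path <- c(cur, path)
    nxt <- parent[[cur]]
    if (is.na(nxt) || nxt == cur) break
    cur <- nxt
  }
  path
}

.parentVector <- function(tree) {
  nd <- taxNodes(tree)
  stats::setNames(nd$parent, nd$id)
}

#' Filter one read's hits by score, e-value and top-percent window
#'
#' Hits failing `bit_score >= minScore` or `e_value <= maxEvalue` are dropped
#' first; the best remaining score defines the retention window
#' `bit_score >= best * (1 - topPercent/100)`.  With the defaults (50, 0.01,
#' 50) this is the conventional MEGAN-style `-ms 50 -me 0.01 -tp 50` rule.
#' The operation is idempotent.
#'
#' @param hits `data.frame` of one read's hit records (rows of
#'   [hitRecords()]).
#' @param params an [AssignmentParams-class].
#' @return the retained rows (possibly zero rows).
#' @export
filterHits <- function(hits, params = assignmentParams()) {
  keep <- hits$bit_score >= params@minScore & hits$e_value <= params@maxEvalue
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  best <- max(hits$bit_score)
  hits[hits$bit_score >= best * (1 - params@topPercent / 100), , drop = FALSE]
}

#' Lowest common ancestor of a set of taxonomy nodes
#'
#' The deepest node that is an ancestor-or-self of every input node.
#'
#' @param nodeIds character vector of node ids (non-empty).
#' @param tree a [TaxonomyTree-class].
#' @return a node id.
#' @examples
#' tr <- loadTaxonomy(c("1\t1\troot\troot",
#'                      "2\t1\tgenus\tClostridium",
#'                      "3\t2\tspecies\tC. difficile"))
#' lca(c("2", "3"), tr)  # "2"
#' @export
lca <- function(nodeIds, tree) {
  parent <- .parentVector(tree)
  nodeIds <- unique(as.character(nodeIds))
  unknown <- setdiff(nodeIds, names(parent))
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (!length(nodeIds)) stop("lca of an empty node set")
  paths <- lapply(nodeIds, .ancestorPath, parent = parent)
  depth <- min(lengths(paths))
  common <- NULL
  for (i in seq_len(depth)) {
    level <- vapply(paths, `[`, character(1), i)
    if (all(level == level[1L])) common <- level[1L] else break
  }
  common
}

#' Assign reads taxonomically (LCA) and functionally (best-hit NOG)
#'
#' Per read: hits are filtered with [filterHits()]; the taxonomic assignment
#' is the LCA of the retained hits' taxon ids (hits without a taxon mapping
#' are ignored for the LCA but stay eligible as NOG best hit); the NOG
#' assignment is the NOG of the retained hit with the highest bit score, ties
#' broken by lexicographically smallest subject id.  Reads with no retained
#' hits are fully unassigned.
#'
#' @param table a [HitTable-class].
#' @param tree a [TaxonomyTree-class].
#' @param params an [AssignmentParams-class].
#' @return `data.frame` with columns `read_id`, `node_id`, `nog_id`
#'   (`NA` = unassigned), one row per read in input order.
#' @export
assignReads <- function(table, tree, params = assignmentParams()) {
  h <- hitRecords(table)
  readIds <- unique(h$read_id)
  byRead <- split(h, factor(h$read_id, levels = readIds))
  rows <- lapply(byRead, function(hr) {
    kept <- filterHits(hr, params)
    if (!nrow(kept))
      return(data.frame(node_id = NA_character_, nog_id = NA_character_,
                        stringsAsFactors = FALSE))
    taxa <- unique(kept$taxon_id[!is.na(kept$taxon_id)])
    node <- if (length(taxa)) lca(taxa, tree) else NA_character_
    ord <- order(-kept$bit_score, kept$subject_id)
    data.frame(node_id = node, nog_id = kept$nog_id[ord[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  data.frame(read_id = readIds, node_id = out$node_id, nog_id = out$nog_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

.rankAncestor <- function(tree, rank) {
  # node id -> ancestor-or-self at `rank`, NA when the node sits above it
  nd <- taxNodes(tree)
  parent <- .parentVector(tree)
  atRank <- stats::setNames(nd$rank == rank, nd$id)
  vapply(nd$id, function(id) {
    cur <- id
    repeat {
      if (atRank[[cur]]) return(cur)
      nxt <- parent[[cur]]
      if (is.na(nxt) || nxt == cur) return(NA_character_)
      cur <- nxt
    }
  }, character(1))
}

#' Project read assignments to a taxonomic rank
#'
#' A read contributes one count to a rank-level taxon iff its LCA node is that
#' taxon or one of its descendants; reads whose LCA sits above the rank (or
#' that are unassigned) are counted to no taxon.  When `samples` is given
#' (a read id -> sample id map) one column per sample is produced.
#'
#' @param assignments output of [assignReads()].
#' @param tree a [TaxonomyTree-class].
#' @param rank target rank, default `"genus"`.
#' @param samples optional named character vector mapping read ids to sample
#'   ids; absent, all reads go into one `"all"` column.
#' @param condition,assayType,librarySize metadata for the resulting
#'   [CountMatrix-class] (recycled across samples); library size defaults to
#'   the number of reads per sample.
#' @return a [CountMatrix-class] of rank-level counts (features named by the
#'   taxon `name`).
#' @export
projectToRank <- function(assignments, tree, rank = "genus", samples = NULL,
                          condition = "steady_state", assayType = "DNA",
                          librarySize = NULL) {
  if (!rank %in% TAXONOMY_RANKS) stop("unknown rank: ", rank)
  toRank <- .rankAncestor(tree, rank)
  nd <- taxNodes(tree)
  nameOf <- stats::setNames(nd$name, nd$id)
  rankNodes <- nd$id[nd$rank == rank]
  sam <- if (is.null(samples)) rep("all", nrow(assignments))
         else unname(samples[assignments$read_id])
  sampleIds <- unique(sam)
  proj <- ifelse(is.na(assignments$node_id), NA_character_,
                 toRank[assignments$node_id])
  m <- matrix(0L, length(rankNodes), length(sampleIds),
              dimnames = list(unname(nameOf[rankNodes]), sampleIds))
  ok <- !is.na(proj)
  if (any(ok)) {
    t2 <- table(factor(unname(nameOf[proj[ok]]), levels = rownames(m)),
                factor(sam[ok], levels = sampleIds))
    m[] <- as.integer(t2)
  }
  nPerSample <- as.integer(table(factor(sam, levels = sampleIds)))
  if (is.null(librarySize)) librarySize <- pmax(nPerSample, 1L)
  CountMatrix(m, condition = rep(condition, length.out = length(sampleIds)),
              assayType = assayType, librarySize = librarySize,
              featureKind = if (rank == "genus") "genus" else "genus")
}

#' Alternative-hit concordance of the best-hit NOG annotation
#'
#' For each read with at least two retained hits, the read is concordant when
#' strictly more than half of its non-best retained hits carry the same NOG as
#' the best hit.  Reads with fewer than two retained hits are excluded from
#' the denominator.  Used to validate that the best hit is a fair
#' representative of a read's function.
#'
#' @param table a [HitTable-class].
#' @param params an [AssignmentParams-class].
#' @return fraction of eligible reads that are concordant, in \[0, 1\];
#'   `NA_real_` (with a warning) when no read is eligible.
#' @export
annotationConcordance <- function(table, params = assignmentParams()) {
  h <- hitRecords(table)
  readIds <- unique(h$read_id)
  byRead <- split(h, factor(h$read_id, levels = readIds))
  verdict <- vapply(byRead, function(hr) {
    kept <- filterHits(hr, params)
    if (nrow(kept) < 2L) return(NA)
    ord <- order(-kept$bit_score, kept$subject_id)
    bestNog <- kept$nog_id[ord[1L]]
    alts <- kept$nog_id[ord[-1L]]
    match <- !is.na(alts) & !is.na(bestNog) & alts == bestNog
    mean(match) > 0.5
  }, logical(1))
  eligible <- verdict[!is.na(verdict)]
  if (!length(eligible)) {
    warning("no reads with >= 2 retained hits; concordance undefined")
    return(NA_real_)
  }
  mean(eligible)
}
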