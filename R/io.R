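## Readers and writers for the plain-text formats the pipeline touches:
## 12-column BLAST/DIAMOND tabular hits, NCBI or simple-TSV taxonomies,
## and count/metadata TSV pairs.  Everything is UTF-8, tab-delimited.

#' Parse 12-column BLAST/DIAMOND tabular alignment output
#'
#' Reads standard `outfmt 6` / m8 alignment output (columns: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore) and
#' attaches the two annotation channels via subject-id lookup maps.  Records
#' are grouped by read in input order; hits whose subject is absent from a map
#' get `NA` in that channel.
#'
#' @param input path to a tabular file, or a character vector of lines.
#' @param taxonMap named character vector, subject id -> taxonomy node id
#'   (optional).
#' @param nogMap named character vector, subject id -> NOG id (optional).
#' @return a [HitTable-class].
#' @examples
#' ht <- parseTabularAlignment(
#'   "r1\ts1\t99\t50\t0\t0\t1\t50\t1\t50\t1e-20\t100.5")
#' hitRecords(ht)
#' @export
parseTabularAlignment <- function(input, taxonMap = NULL, nogMap = NULL) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    empty <- data.frame(read_id = character(), subject_id = character(),
                        bit_score = numeric(), e_value = numeric(),
                        taxon_id = character(), nog_id = character(),
                        stringsAsFactors = FALSE)
    return(new("HitTable", hits = empty))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop(sprintf("parse error at line %d: expected 12 tab-separated columns, found %d",
                 which(nf != 12L)[1L], nf[nf != 12L][1L]))
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  evalue <- suppressWarnings(as.numeric(m[, 11L]))
  bitscore <- suppressWarnings(as.numeric(m[, 12L]))
  bad <- is.na(evalue) | is.na(bitscore)
  if (any(bad))
    stop(sprintf("parse error at line %d: non-numeric evalue/bitscore",
                 which(bad)[1L]))
  lookup <- function(map, keys) {
    if (is.null(map)) return(rep(NA_character_, length(keys)))
    unname(map[keys])
  }
  hits <- data.frame(read_id = m[, 1L], subject_id = m[, 2L],
                     bit_score = bitscore, e_value = evalue,
                     taxon_id = lookup(taxonMap, m[, 2L]),
                     nog_id = lookup(nogMap, m[, 2L]),
                     stringsAsFactors = FALSE)
  new("HitTable", hits = hits)
}

#' Load a taxonomy
#'
#' Two dialects are supported and must be named explicitly (no sniffing):
#' `"simple_tsv"` — four tab-separated columns `node_id`, `parent_id`,
#' `rank`, `name`, no header; `"ncbi_dmp"` — the NCBI `nodes.dmp` convention
#' (fields separated by `\t|\t`), with scientific names supplied through
#' `namesFile` (`names.dmp`; rows flagged `scientific name` are used).
#'
#' @param input path (or character vector of lines) of the node table.
#' @param dialect `"simple_tsv"` or `"ncbi_dmp"`.
#' @param namesFile path or lines of `names.dmp` (ncbi_dmp only, optional —
#'   node ids are used as names when absent).
#' @return a validated [TaxonomyTree-class]; cycles and orphan nodes are
#'   reported as errors naming an offending node.
#' @export
loadTaxonomy <- function(input, dialect = c("simple_tsv", "ncbi_dmp"),
                         namesFile = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(lines)]
  if (dialect == "simple_tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L))
      stop("simple_tsv taxonomy rows need 4 columns: node_id, parent_id, rank, name")
    m <- t(vapply(fields, function(f) f[1:4], character(4)))
    nodes <- data.frame(id = m[, 1], parent = m[, 2], rank = m[, 3],
                        name = m[, 4], stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t|\t", fixed = TRUE)
    m <- t(vapply(fields, function(f) f[1:3], character(3)))
    rank <- m[, 3]
    rank[!rank %in% TAXONOMY_RANKS] <- "no_rank"
    nm <- m[, 1]
    if (!is.null(namesFile)) {
      nlines <- if (length(namesFile) == 1L && file.exists(namesFile))
        readLines(namesFile) else namesFile
      nf <- strsplit(nlines[nzchar(nlines)], "\t|\t", fixed = TRUE)
      sci <- vapply(nf, function(f) length(f) >= 4L &&
                      grepl("scientific name", f[4]), logical(1))
      nameMap <- stats::setNames(vapply(nf[sci], `[`, character(1), 2L),
                                 vapply(nf[sci], `[`, character(1), 1L))
      found <- m[, 1] %in% names(nameMap)
      nm[found] <- unname(nameMap[m[found, 1]])
    }
    nodes <- data.frame(id = m[, 1], parent = m[, 2], rank = rank,
                        name = nm, stringsAsFactors = FALSE)
  }
  new("TaxonomyTree", nodes = nodes)
}

#' Read / write a CountMatrix as TSV
#'
#' The count table is a TSV whose first column (`feature_id`) holds feature
#' ids and whose header names the samples; sample metadata live in a sidecar
#' TSV with columns `sample_id`, `condition`, `assay`, `library_size`.
#' `readCounts(writeCounts(m))` is an identity.
#'
#' @param countsFile path of the count TSV.
#' @param metadataFile path of the metadata TSV.
#' @param featureKind what the rows are (see [CountMatrix-class]).
#' @return `readCounts` a [CountMatrix-class]; `writeCounts` invisibly the
#'   paths written.
#' @export
readCounts <- function(countsFile, metadataFile, featureKind = "genus") {
  tab <- utils::read.delim(countsFile, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate feature id: ", tab[[1]][duplicated(tab[[1]])][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  meta <- utils::read.delim(metadataFile, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "assay", "library_size")
  if (!all(req %in% colnames(meta)))
    stop("metadata must have columns ", paste(req, collapse = ", "))
  missing <- setdiff(meta$sample_id, colnames(m))
  if (length(missing))
    stop("metadata sample(s) missing from count header: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(m), meta$sample_id)
  if (length(extra))
    stop("count column(s) missing from metadata: ", paste(extra, collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample_id), ]
  CountMatrix(m, condition = meta$condition, assayType = meta$assay,
              librarySize = meta$library_size, featureKind = featureKind)
}

#' @rdname readCounts
#' @param m a [CountMatrix-class] to write.
#' @export
writeCounts <- function(m, countsFile, metadataFile) {
  stopifnot(is(m, "CountMatrix"))
  tab <- data.frame(feature_id = rownames(m), counts(m),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, countsFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- SummarizedExperiment::colData(m)
  meta <- data.frame(sample_id = colnames(m),
                     condition = cd$condition,
                     assay = cd$assay_type,
                     library_size = cd$library_size,
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadataFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(countsFile, metadataFile))
}

#' Write a HitTable as 12-column tabular text
#'
#' Inverse of [parseTabularAlignment()] for the columns the package models;
#' the positional alignment columns not carried by [HitRecord][HitTable-class]
#' rows are emitted as zeros.
#'
#' @param ht a [HitTable-class].
#' @param path output path.
#' @return invisibly the path.
#' @export
writeHitTable <- function(ht, path) {
  h <- hitRecords(ht)
  lines <- sprintf("%s\t%s\t0\t0\t0\t0\t0\t0\t0\t0\t%g\t%g",
                   h$read_id, h$subject_id, h$e_value, h$bit_score)
  writeLines(lines, path)
  invisible(path)
}
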