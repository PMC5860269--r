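# GAF 2.x annotation loading with evidence-code / qualifier filtering, and
# construction of ancestor-closed annotation sets with corpus information
# content.

.aspectLetter <- c(biological_process = "P", molecular_function = "F",
                   cellular_component = "C")

#' Load node annotations from a GAF 2.x file
#'
#' Comment lines (`!`) are skipped and each record must carry at least 15
#' tab-separated columns. Rows are filtered by the configured evidence codes
#' (column 7; default drops `IPI` and `RCA`, which are inferred from
#' interaction/omics data and would introduce circularity into interaction-
#' network analysis, and `ND`, which asserts no evidence), by `NOT`
#' qualifiers (column 4, negative associations), and by aspect (column 9 must
#' match the ontology's namespace). Terms are resolved through alternative
#' IDs; records with terms unknown to the ontology are counted and skipped,
#' not fatal.
#'
#' Annotations are keyed on a configurable GAF column (default column 2, the
#' DB object ID); an optional two-column ID map translates those keys to the
#' network's node IDs, and records whose key has no mapping are dropped with
#' a count.
#'
#' @param path path to a GAF file
#' @param ontology a [GeneOntology-class]
#' @param excludedEvidence evidence codes to drop (default
#'   `c("IPI", "RCA", "ND")`)
#' @param dropNot drop records whose qualifier contains `NOT` (default `TRUE`)
#' @param idColumn 1-based GAF column holding the node key (default 2)
#' @param idMap optional named character vector, or path to a two-column TSV,
#'   mapping GAF keys to node IDs
#' @param logBase base for information content (default natural log)
#' @return an [AnnotationSet-class]
#' @seealso [buildAnnotationSet()], [informationContent()]
#' @export
loadAnnotations <- function(path, ontology,
                            excludedEvidence = c("IPI", "RCA", "ND"),
                            dropNot = TRUE, idColumn = 2L, idMap = NULL,
                            logBase = exp(1)) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 15L)
  if (length(short))
    stop("GAF record ", short[1L], " has fewer than 15 columns")

  id <- vapply(fields, `[[`, character(1), as.integer(idColumn))
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)
  aspect <- vapply(fields, `[[`, character(1), 9L)

  keep <- aspect == .aspectLetter[[ontology@namespace]]
  keep <- keep & !(evidence %in% excludedEvidence)
  if (dropNot) keep <- keep & !grepl("(^|\\|)NOT($|\\|)", qualifier)
  id <- id[keep]; term <- term[keep]

  canon <- vapply(term, resolveTerm, character(1), ontology = ontology,
                  USE.NAMES = FALSE)
  unknown <- is.na(canon)
  if (any(unknown))
    message("skipped ", sum(unknown),
            " record(s) with terms unknown to the ontology")
  id <- id[!unknown]; canon <- canon[!unknown]

  if (!is.null(idMap)) {
    if (is.character(idMap) && is.null(names(idMap)) &&
        length(idMap) == 1L) {
      tab <- utils::read.table(idMap, sep = "\t", header = FALSE,
                               colClasses = "character")
      idMap <- stats::setNames(tab[[2L]], tab[[1L]])
    }
    mapped <- idMap[id]
    lost <- is.na(mapped)
    if (any(lost))
      message("dropped ", sum(lost), " record(s) with unmapped IDs")
    id <- unname(mapped[!lost]); canon <- canon[!lost]
  }

  direct <- lapply(split(canon, id), unique)
  buildAnnotationSet(direct, ontology, logBase = logBase)
}

#' Build an annotation set from direct term assignments
#'
#' Computes the ancestor closure of every node's direct terms, the corpus
#' count of each term (number of annotated nodes whose closed set contains
#' it), and per-term information content
#' `-log(corpusCount / nAnnotated)` in the chosen base. Frequencies are taken
#' over the annotated nodes of this set, keeping the corpus self-contained.
#'
#' @param direct named list, node ID -> character vector of term IDs (terms
#'   must belong to the ontology)
#' @param ontology a [GeneOntology-class]
#' @param logBase base for information content (default natural log)
#' @return an [AnnotationSet-class]
#' @export
buildAnnotationSet <- function(direct, ontology, logBase = exp(1)) {
  stopifnot(is.list(direct), !is.null(names(direct)))
  closure <- termAncestors(ontology)
  bad <- setdiff(unique(unlist(direct, use.names = FALSE)), ontology@terms)
  if (length(bad))
    stop("direct annotations contain terms outside the ontology: ",
         paste(utils::head(bad, 3L), collapse = ", "))
  closed <- lapply(direct, function(ts) {
    if (!length(ts)) return(character())
    unique(unlist(closure[ts], use.names = FALSE))
  })
  annotated <- names(closed)[lengths(closed) > 0L]
  counts <- table(unlist(closed[annotated], use.names = FALSE))
  corpusCount <- stats::setNames(as.numeric(counts), names(counts))
  nAnn <- length(annotated)
  ic <- -log(corpusCount / nAnn) / log(logBase)
  ic[ic < 0] <- 0  # guard against -0 on the root
  new("AnnotationSet", direct = direct, closed = closed,
      corpusCount = corpusCount, ic = ic, nAnnotated = as.integer(nAnn),
      root = ontology@root, logBase = logBase)
}

#' Write an annotation set as a GAF 2.1 file
#'
#' One 17-column record per (node, direct term) pair, with synthetic
#' bookkeeping columns (database `SYN`, evidence `IDA`). Round-trips through
#' [loadAnnotations()] for the same ontology.
#'
#' @param annot an [AnnotationSet-class]
#' @param path output path
#' @param aspect GAF aspect letter (default `"P"`)
#' @return `path`, invisibly
#' @export
writeGaf <- function(annot, path, aspect = "P") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  for (n in names(annot@direct)) {
    for (t in annot@direct[[n]]) {
      writeLines(paste(c("SYN", n, n, "", t, "SYN:0000001", "IDA", "",
                         aspect, "", "", "protein", "taxon:9606",
                         "20150801", "SYN", "", ""), collapse = "\t"), con)
    }
  }
  invisible(path)
}
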