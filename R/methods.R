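#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn scoreValue homogeneity score
#' @export
setMethod("scoreValue", "HomogeneityScore", function(x) x@value)

#' @describeIn scoreValue co-expression score
#' @export
setMethod("scoreValue", "CoexpressionScore", function(x) x@value)

#' @describeIn nPairsUsed homogeneity score
#' @export
setMethod("nPairsUsed", "HomogeneityScore", function(x) x@nPairs)

#' @describeIn nPairsUsed co-expression score
#' @export
setMethod("nPairsUsed", "CoexpressionScore", function(x) x@nPairs)

#' @describeIn isDefined homogeneity score
#' @export
setMethod("isDefined", "HomogeneityScore", function(x) !is.na(x@value))

#' @describeIn isDefined co-expression score
#' @export
setMethod("isDefined", "CoexpressionScore", function(x) !is.na(x@value))

#' @describeIn tValue tail probability
#' @export
setMethod("tValue", "TValueResult", function(x) x@tValue)

#' @describeIn tailCounts walk counts
#' @export
setMethod("tailCounts", "TValueResult",
          function(x) c(m = x@m, M = x@M))

#' @describeIn communityHomogeneity stored community FH
#' @export
setMethod("communityHomogeneity", "TValueResult", function(x) x@communityFh)

#' @describeIn backgroundHomogeneity per-walk background FH values
#' @export
setMethod("backgroundHomogeneity", "TValueResult",
          function(x) x@backgroundFh)

#' @describeIn informationContent IC of a term observed in the corpus
#' @export
setMethod("informationContent", "AnnotationSet", function(x, term) {
  if (!term %in% names(x@corpusCount))
    stop("term '", term, "' was never observed in the annotation corpus")
  unname(x@ic[[term]])
})

#' @describeIn annotatedNodes node IDs carried by the set
#' @export
setMethod("annotatedNodes", "AnnotationSet",
          function(x) names(x@closed)[lengths(x@closed) > 0L])

#' @describeIn directTerms asserted terms of one node
#' @export
setMethod("directTerms", "AnnotationSet", function(x, node) {
  d <- x@direct[[node]]
  if (is.null(d)) character() else d
})

#' @describeIn closedTerms ancestor-closed terms of one node
#' @export
setMethod("closedTerms", "AnnotationSet", function(x, node) {
  cl <- x@closed[[node]]
  if (is.null(cl)) character() else cl
})

#' @describeIn ontologyTerms terms of the namespace
#' @export
setMethod("ontologyTerms", "GeneOntology", function(x) x@terms)

#' @describeIn ontologyRoot namespace root
#' @export
setMethod("ontologyRoot", "GeneOntology", function(x) x@root)

#' @describeIn termParents parents of one term
#' @export
setMethod("termParents", "GeneOntology", function(x, term) {
  if (!term %in% x@terms) {
    canon <- x@altIds[term]
    if (is.na(canon)) stop("unknown term '", term, "'")
    term <- unname(canon)
  }
  x@parents[[term]]
})

setMethod("show", "GeneOntology", function(object) {
  cat("GeneOntology:", length(object@terms), "terms in namespace",
      object@namespace, "\n  root:", object@root, "\n")
  if (length(object@altIds))
    cat(" ", length(object@altIds), "alternative IDs mapped\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", object@nAnnotated, "annotated nodes of",
      length(object@closed), "\n  ", length(object@corpusCount),
      "terms in corpus; IC log base", format(object@logBase, digits = 4),
      "\n")
})

setMethod("show", "HomogeneityScore", function(object) {
  if (is.na(object@value)) {
    cat("HomogeneityScore: undefined (", object@reason, ")\n", sep = "")
  } else {
    cat("HomogeneityScore:", format(object@value, digits = 6), "over",
        object@nPairs, "pairs (", object@nIgnored,
        "unannotated members ignored)\n")
  }
})

setMethod("show", "TValueResult", function(object) {
  cat("TValueResult: T =", format(object@tValue, digits = 4),
      sprintf("(m = %d, M = %d)", object@m, object@M),
      "\n  community FH:", format(object@communityFh, digits = 6), "\n")
  if (object@nExcluded > 0L)
    cat(" ", object@nExcluded, "walks excluded (undefined homogeneity)\n")
})

setMethod("show", "CoexpressionScore", function(object) {
  if (is.na(object@value)) {
    cat("CoexpressionScore: undefined\n")
  } else {
    cat("CoexpressionScore:", format(object@value, digits = 4), "over",
        object@nPairs, "pairs (", object@nExcluded, "excluded)\n")
  }
})

setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec:", object@nNodes, "nodes,", object@nCommunities,
      "planted communities of size", object@sizeRange[1L], "-",
      object@sizeRange[2L], "\n  seed:", object@seed, "\n")
})
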