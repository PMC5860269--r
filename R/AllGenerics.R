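#' @include AllClasses.R
NULL

#' Score value of a homogeneity or co-expression result
#'
#' Returns the numeric score held by a [HomogeneityScore-class] or
#' [CoexpressionScore-class] object, or `NA` when the score is undefined
#' (fewer than two usable members).
#'
#' @param x a score object
#' @return a numeric scalar, `NA` when undefined
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))

#' Number of member pairs that entered a score
#' @param x a score object
#' @return integer count
#' @export
setGeneric("nPairsUsed", function(x) standardGeneric("nPairsUsed"))

#' Whether a score is defined
#' @param x a score object
#' @return logical scalar
#' @export
setGeneric("isDefined", function(x) standardGeneric("isDefined"))

#' Empirical tail probability of a community evaluation
#'
#' @param x a [TValueResult-class]
#' @return the T-value `(m + 1) / (M + 1)`
#' @export
setGeneric("tValue", function(x) standardGeneric("tValue"))

#' Walk counts behind a T-value
#'
#' @param x a [TValueResult-class]
#' @return named integer vector `c(m = ..., M = ...)`: walks scoring strictly
#'   above the community and total retained walks
#' @export
setGeneric("tailCounts", function(x) standardGeneric("tailCounts"))

#' Community functional homogeneity stored in a result
#' @param x a [TValueResult-class]
#' @return numeric scalar
#' @export
setGeneric("communityHomogeneity",
           function(x) standardGeneric("communityHomogeneity"))

#' Background homogeneities sampled by the walks
#' @param x a [TValueResult-class]
#' @return numeric vector, one value per retained walk
#' @export
setGeneric("backgroundHomogeneity",
           function(x) standardGeneric("backgroundHomogeneity"))

#' Information content of an ontology term
#'
#' The information content of a term is the negative logarithm of its relative
#' annotation frequency over the annotated nodes of the corpus:
#' `-log(corpusCount(term) / nAnnotated)`. The namespace root therefore has
#' information content 0 and rarer (more specific) terms score higher.
#'
#' @param x an [AnnotationSet-class]
#' @param term a term identifier observed in the corpus
#' @return nonnegative numeric scalar (in units of the set's log base)
#' @export
setGeneric("informationContent",
           function(x, term) standardGeneric("informationContent"))

#' Node identifiers covered by an annotation set
#' @param x an [AnnotationSet-class]
#' @return character vector of node IDs
#' @export
setGeneric("annotatedNodes", function(x) standardGeneric("annotatedNodes"))

#' Direct (asserted) term set of a node
#' @param x an [AnnotationSet-class]
#' @param node a node ID
#' @return character vector of term IDs (empty when the node is unannotated)
#' @export
setGeneric("directTerms", function(x, node) standardGeneric("directTerms"))

#' Ancestor-closed term set of a node
#' @param x an [AnnotationSet-class]
#' @param node a node ID
#' @return character vector of term IDs including all ancestors up to the root
#' @export
setGeneric("closedTerms", function(x, node) standardGeneric("closedTerms"))

#' Terms of an ontology
#' @param x a [GeneOntology-class]
#' @return character vector of term IDs
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' Root term of an ontology namespace
#' @param x a [GeneOntology-class]
#' @return the root term ID
#' @export
setGeneric("ontologyRoot", function(x) standardGeneric("ontologyRoot"))

#' Parent terms (is_a / part_of) of a term
#' @param x a [GeneOntology-class]
#' @param term a term ID
#' @return character vector of parent term IDs (empty for the root)
#' @export
setGeneric("termParents", function(x, term) standardGeneric("termParents"))
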