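# Central S4 containers. Graphs themselves are igraph objects; these classes
# hold the ontology, the annotation corpus, and the evaluation results.

.kahnAcyclic <- function(terms, parents) {
  # Kahn-style peeling over the parent relation; TRUE iff acyclic.
  indeg <- integer(length(terms))
  names(indeg) <- terms
  for (ps in parents) for (p in ps) indeg[[p]] <- indeg[[p]] + 1L
  queue <- terms[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (p in parents[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  removed == length(terms)
}

#' GeneOntology: a single-namespace term DAG
#'
#' Holds the terms of one Gene Ontology namespace together with the parent
#' relation over `is_a` and `part_of` edges, the namespace root, and a map
#' from alternative (merged) IDs to canonical IDs. The parent relation is
#' validated to be acyclic and every term must reach the root.
#'
#' @slot terms character vector of term IDs
#' @slot parents named list, term -> character vector of parent term IDs
#' @slot namespace the namespace, e.g. `"biological_process"`
#' @slot root the namespace root term ID
#' @slot termName named character vector of human-readable term names (may be
#'   empty)
#' @slot altIds named character vector mapping alternative IDs to canonical
#'   term IDs (may be empty)
#'
#' @seealso [loadOntology()], [generateOntology()], [termAncestors()]
#' @export
setClass("GeneOntology",
  representation(terms = "character", parents = "list",
                 namespace = "character", root = "character",
                 termName = "character", altIds = "character"))

setValidity("GeneOntology", function(object) {
  msgs <- character()
  if (length(object@root) != 1L || !(object@root %in% object@terms))
    msgs <- c(msgs, "root must be a single term present in 'terms'")
  if (!setequal(names(object@parents), object@terms))
    msgs <- c(msgs, "'parents' must be named by exactly the terms")
  tgt <- unlist(object@parents, use.names = FALSE)
  if (length(tgt) && !all(tgt %in% object@terms))
    msgs <- c(msgs, "parent targets must be terms of the ontology")
  if (length(object@parents[[object@root]]))
    msgs <- c(msgs, "the root must have no parents")
  if (!.kahnAcyclic(object@terms, object@parents))
    msgs <- c(msgs, "parent relation contains a cycle")
  if (length(msgs)) msgs else TRUE
})

#' AnnotationSet: ancestor-closed node annotations with information content
#'
#' Maps node IDs to their directly asserted ontology terms and to the ancestor
#' closure of those terms (the direct terms unioned with every ancestor up to
#' the namespace root). Corpus term counts and per-term information content
#' are computed over the annotated nodes of the loaded set.
#'
#' @slot direct named list, node ID -> character vector of asserted term IDs
#' @slot closed named list, node ID -> ancestor-closed term IDs
#' @slot corpusCount named numeric, term -> number of annotated nodes whose
#'   closed set contains the term
#' @slot ic named numeric, term -> information content
#'   (`-log(corpusCount / nAnnotated)` in the configured log base)
#' @slot nAnnotated number of nodes with a nonempty closed set
#' @slot root the namespace root term
#' @slot logBase base of the logarithm used for information content
#'
#' @seealso [loadAnnotations()], [buildAnnotationSet()],
#'   [informationContent()]
#' @export
setClass("AnnotationSet",
  representation(direct = "list", closed = "list", corpusCount = "numeric",
                 ic = "numeric", nAnnotated = "integer", root = "character",
                 logBase = "numeric"))

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  if (!identical(names(object@direct), names(object@closed)))
    msgs <- c(msgs, "'direct' and 'closed' must cover the same nodes")
  if (any(object@corpusCount < 1))
    msgs <- c(msgs, "corpus counts must be >= 1")
  if (any(object@ic < -1e-12))
    msgs <- c(msgs, "information content must be nonnegative")
  # closure contains the direct terms, and the root for every annotated node
  sub <- vapply(names(object@direct), function(n) {
    all(object@direct[[n]] %in% object@closed[[n]])
  }, logical(1))
  if (!all(sub)) msgs <- c(msgs, "closed sets must contain the direct sets")
  ann <- names(object@closed)[lengths(object@closed) > 0L]
  hasRoot <- vapply(ann, function(n) object@root %in% object@closed[[n]],
                    logical(1))
  if (!all(hasRoot))
    msgs <- c(msgs, "every annotated node's closed set must contain the root")
  if (length(msgs)) msgs else TRUE
})

#' HomogeneityScore: community functional homogeneity
#'
#' The arithmetic mean of pairwise semantic similarity over all unordered
#' pairs of annotated community members. Undefined (value `NA`) when fewer
#' than two members are annotated; unannotated members are ignored and
#' counted in `nIgnored`.
#'
#' @slot value numeric score (`NA` when undefined), in the units of the chosen
#'   measure
#' @slot nPairs number of member pairs averaged
#' @slot nIgnored number of unannotated members excluded
#' @slot reason explanatory flag when undefined, otherwise `""`
#'
#' @seealso [functionalHomogeneity()]
#' @export
setClass("HomogeneityScore",
  representation(value = "numeric", nPairs = "integer",
                 nIgnored = "integer", reason = "character"))

setValidity("HomogeneityScore", function(object) {
  if (!is.na(object@value) && object@nPairs < 1L)
    return("a defined score must use at least one pair")
  TRUE
})

#' TValueResult: a community's walk-background evaluation
#'
#' Holds the community functional homogeneity, the homogeneities of the
#' random-walk proxy communities retained as the local background, the counts
#' `m` (walks scoring strictly above the community) and `M` (total retained
#' walks), and the tail value `T = (m + 1) / (M + 1)`.
#'
#' @slot communityFh community functional homogeneity
#' @slot backgroundFh numeric vector of background homogeneities (one per
#'   retained walk)
#' @slot m number of background walks with homogeneity strictly greater than
#'   the community's
#' @slot M total number of retained walks
#' @slot tValue `(m + 1) / (M + 1)`
#' @slot nExcluded walks dropped because their proxy module had fewer than two
#'   annotated nodes (or failed to terminate)
#' @slot seed the seed recorded for the evaluation (`NA` when the caller
#'   managed the RNG)
#'
#' @seealso [computeTValue()], [TValueResult()]
#' @export
setClass("TValueResult",
  representation(communityFh = "numeric", backgroundFh = "numeric",
                 m = "integer", M = "integer", tValue = "numeric",
                 nExcluded = "integer", seed = "integer"))

setValidity("TValueResult", function(object) {
  msgs <- character()
  if (object@M != length(object@backgroundFh))
    msgs <- c(msgs, "M must equal the number of background walks")
  m <- sum(object@backgroundFh > object@communityFh)
  if (object@m != m)
    msgs <- c(msgs, "m must count walks strictly above the community FH")
  tv <- (object@m + 1) / (object@M + 1)
  if (abs(object@tValue - tv) > 1e-12)
    msgs <- c(msgs, "tValue must equal (m + 1) / (M + 1)")
  if (object@tValue < 1 / (object@M + 1) - 1e-12 || object@tValue > 1 + 1e-12)
    msgs <- c(msgs, "tValue must lie in [1/(M+1), 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TValueResult from a community score and walk backgrounds
#'
#' Counts the background walks scoring strictly above the community (ties do
#' not count) and applies the tail formula `T = (m + 1) / (M + 1)`.
#'
#' @param communityFh the community functional homogeneity
#' @param backgroundFh numeric vector of background walk homogeneities
#' @param nExcluded number of walks excluded before counting
#' @param seed seed recorded for provenance
#' @return a [TValueResult-class]
#' @examples
#' tValue(TValueResult(3, c(1, 2, 5)))  # one of three walks above: T = 0.5
#' @export
TValueResult <- function(communityFh, backgroundFh, nExcluded = 0L,
                         seed = NA_integer_) {
  stopifnot(is.numeric(communityFh), length(communityFh) == 1L,
            is.numeric(backgroundFh), !anyNA(backgroundFh))
  m <- as.integer(sum(backgroundFh > communityFh))
  M <- length(backgroundFh)
  new("TValueResult", communityFh = as.numeric(communityFh),
      backgroundFh = as.numeric(backgroundFh), m = m, M = M,
      tValue = (m + 1) / (M + 1), nExcluded = as.integer(nExcluded),
      seed = as.integer(seed))
}

#' CoexpressionScore: community co-expression
#'
#' The mean absolute Pearson correlation over all unordered member pairs with
#' both expression profiles present and of nonzero variance.
#'
#' @slot value mean `|r|` in `[0, 1]` (`NA` when undefined)
#' @slot nPairs pairs included
#' @slot nExcluded pairs excluded (missing profile or zero variance)
#'
#' @seealso [communityCoexpression()]
#' @export
setClass("CoexpressionScore",
  representation(value = "numeric", nPairs = "integer",
                 nExcluded = "integer"))

setValidity("CoexpressionScore", function(object) {
  if (!is.na(object@value) &&
      (object@value < -1e-12 || object@value > 1 + 1e-12))
    return("a defined co-expression score must lie in [0, 1]")
  TRUE
})

#' FixtureSpec: parameters of the synthetic test-data generator
#'
#' Describes a planted-partition interaction network whose communities live in
#' a "studied" and an "unstudied" region, a toy ontology, regionally biased
#' annotations, and a factor-model expression matrix. The seed fully
#' determines every generated artifact.
#'
#' @slot nNodes total number of nodes
#' @slot nCommunities number of planted communities
#' @slot sizeRange inclusive community-size range (length-2 integer)
#' @slot pIntra within-community edge probability
#' @slot pBackground edge probability between nodes of the same region
#' @slot crossFactor multiplier on `pBackground` for cross-region pairs
#' @slot biasFraction fraction of communities (and of background nodes)
#'   assigned to the well-studied region
#' @slot studiedSharedTerms community-specific deep terms shared within each
#'   studied community
#' @slot studiedShareProb probability a studied member carries each shared term
#' @slot studiedExtraMean Poisson mean of additional random deep terms per
#'   studied-region node
#' @slot unstudiedSharedTerms community-specific mid-depth terms per unstudied
#'   community
#' @slot unstudiedAnnotProb probability an unstudied member carries its
#'   community's terms (otherwise root-only)
#' @slot ontologyDepth levels below the root of the generated term tree
#' @slot ontologyBranching children per term
#' @slot targetCor target within-module expression correlation
#' @slot nSamples expression samples
#' @slot seed master seed
#'
#' @seealso [fixtureSpec()], [generatePin()], [generateAnnotations()],
#'   [generateExpression()]
#' @export
setClass("FixtureSpec",
  representation(nNodes = "integer", nCommunities = "integer",
                 sizeRange = "integer", pIntra = "numeric",
                 pBackground = "numeric", crossFactor = "numeric",
                 biasFraction = "numeric", studiedSharedTerms = "integer",
                 studiedShareProb = "numeric", studiedExtraMean = "numeric",
                 unstudiedSharedTerms = "integer",
                 unstudiedAnnotProb = "numeric", ontologyDepth = "integer",
                 ontologyBranching = "integer", targetCor = "numeric",
                 nSamples = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
  msgs <- character()
  probs <- c(object@pIntra, object@pBackground, object@crossFactor *
               object@pBackground, object@biasFraction,
             object@studiedShareProb, object@unstudiedAnnotProb)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "all probabilities must lie in [0, 1]")
  if (length(object@sizeRange) != 2L ||
      object@sizeRange[1L] > object@sizeRange[2L])
    msgs <- c(msgs, "sizeRange must be an ordered length-2 integer vector")
  if (object@nCommunities * object@sizeRange[1L] > object@nNodes)
    msgs <- c(msgs, "communities cannot hold more nodes than nNodes")
  if (object@targetCor < 0 || object@targetCor >= 1)
    msgs <- c(msgs, "targetCor must lie in [0, 1)")
  if (object@nSamples < 3L) msgs <- c(msgs, "nSamples must be >= 3")
  if (length(msgs)) msgs else TRUE
})
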