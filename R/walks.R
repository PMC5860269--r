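# Short-random-walk background sampling and the CommWalker T-value.
#
# A walk terminates once it has visited a target number of distinct nodes
# (steps revisiting known nodes do not terminate it); the distinct visit set
# is a "proxy module" — an alternative choice of community in the same local
# network environment.

# index structures shared by the C++ engine: 0-based adjacency, per-node
# sorted term-index closed sets, IC vector, beyond-root flags
.walkContext <- function(g, annot = NULL) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) stop("graph vertices must be named")
  adj <- lapply(igraph::as_adj_list(g, mode = "all"),
                function(v) as.integer(v) - 1L)
  ctx <- list(nodes = nodes, adj = unname(adj))
  if (!is.null(annot)) {
    termU <- names(annot@ic)
    ctx$closed <- lapply(nodes, function(n) {
      cl <- annot@closed[[n]]
      if (is.null(cl) || !length(cl)) return(integer())
      sort(match(cl, termU)) - 1L
    })
    ctx$ic <- unname(annot@ic)
    ctx$beyond <- vapply(nodes, function(n) {
      d <- annot@direct[[n]]
      !is.null(d) && length(setdiff(d, annot@root)) > 0L
    }, logical(1), USE.NAMES = FALSE)
  }
  ctx
}

.defaultMaxSteps <- function(nDistinct) 1e4 * nDistinct

#' Sample one short random walk
#'
#' A simple random walk from `start`, uniform over neighbors at each step,
#' terminated when `nDistinct` distinct nodes (including the start) have been
#' visited. The connected component of the start must hold at least
#' `nDistinct` nodes; exceeding `maxSteps` is a (diagnostic) error.
#'
#' @param g an igraph graph with named vertices
#' @param start start node ID
#' @param nDistinct number of distinct nodes to collect
#' @param maxSteps step budget (default `1e4 * nDistinct`)
#' @param restartProb probability of jumping back to the start before each
#'   step (default 0; a positive value keeps walks local in large graphs)
#' @return character vector of the distinct nodes in visit order; the first
#'   element is `start`
#' @export
sampleWalk <- function(g, start, nDistinct,
                       maxSteps = .defaultMaxSteps(nDistinct),
                       restartProb = 0) {
  ctx <- .walkContext(g)
  si <- match(start, ctx$nodes)
  if (is.na(si)) stop("start node '", start, "' not in graph")
  comp <- igraph::components(g)
  if (comp$csize[comp$membership[si]] < nDistinct)
    stop("component of '", start, "' has fewer than ", nDistinct, " nodes")
  vis <- cpp_sample_walks(ctx$adj, si - 1L, 1L, as.integer(nDistinct),
                          as.numeric(maxSteps), restartProb)
  if (anyNA(vis))
    stop("walk from '", start, "' exceeded ", maxSteps, " steps")
  ctx$nodes[vis[1L, ] + 1L]
}

#' Number of walks needed for a target T-value standard error
#'
#' The T-value is an empirical tail probability, so its standard error at a
#' true value `t` is `sqrt(t (1 - t) / M)`. This returns the smallest walk
#' count `M` meeting the target at the assumed worst case; the defaults
#' (`targetSe = 0.005`, `worstCaseT = 0.5`) give `M = 10000`.
#'
#' @param targetSe target standard error, in `(0, 0.5]`
#' @param worstCaseT T-value at which the binomial variance is evaluated
#'   (default 0.5, the maximum)
#' @return integer walk count
#' @examples
#' calibrateWalkCount()            # 10000
#' calibrateWalkCount(0.05, 0.5)   # 100
#' @export
calibrateWalkCount <- function(targetSe = 0.005, worstCaseT = 0.5) {
  stopifnot(targetSe > 0, targetSe <= 0.5,
            worstCaseT > 0, worstCaseT < 1)
  as.integer(ceiling(worstCaseT * (1 - worstCaseT) / targetSe^2))
}

#' Evaluate a community against its local walk background
#'
#' Performs short random walks from each community member, each terminated at
#' `N_C` distinct nodes (`N_C` = community size), scores every proxy module
#' by functional homogeneity, and returns the tail value
#' `T = (m + 1) / (M + 1)` where `m` counts walks whose homogeneity is
#' strictly greater than the community's. Walks are allocated as
#' `ceiling(totalWalks / N_C)` per member so each community is sampled to a
#' similar extent regardless of its size. Walks whose proxy module has fewer
#' than two annotated nodes have undefined homogeneity and are excluded from
#' both `m` and `M` (their count is recorded).
#'
#' @param g an igraph graph with named vertices
#' @param community character vector of member node IDs (all present in `g`)
#' @param annot an [AnnotationSet-class]
#' @param measure similarity measure, see [pairwiseSimilarity()]
#' @param totalWalks total walks to aim for; default
#'   [calibrateWalkCount()] (10000, targeting a T-value standard error of
#'   0.005)
#' @param restartProb restart probability (default 0, plain walks)
#' @param maxSteps per-walk step budget (default `1e4 * N_C`)
#' @param seed optional seed; when given, set before sampling and recorded in
#'   the result
#' @return a [TValueResult-class]
#' @examples
#' # the tail formula itself: one of three walks above the community
#' tValue(TValueResult(3, c(1, 2, 5)))  # 0.5
#' @export
computeTValue <- function(g, community, annot,
                          measure = c("pandey", "simUI", "simGIC"),
                          totalWalks = NULL, restartProb = 0,
                          maxSteps = NULL, seed = NULL) {
  measure <- match.arg(measure)
  if (!is.null(seed)) set.seed(seed)
  members <- unique(community)
  ctx <- .walkContext(g, annot)
  mi <- match(members, ctx$nodes)
  if (anyNA(mi))
    stop("community members not in graph: ",
         paste(utils::head(members[is.na(mi)], 3L), collapse = ", "))
  nC <- length(members)
  comp <- igraph::components(g)
  if (any(comp$csize[comp$membership[mi]] < nC))
    stop("a member's connected component is smaller than the community")
  fh <- functionalHomogeneity(members, annot, measure)
  if (!isDefined(fh))
    stop("community functional homogeneity is undefined (", fh@reason, ")")
  if (is.null(totalWalks)) totalWalks <- calibrateWalkCount()
  walksPer <- as.integer(ceiling(totalWalks / nC))
  if (is.null(maxSteps)) maxSteps <- .defaultMaxSteps(nC)
  prof <- cpp_walk_profiles(ctx$adj, mi - 1L, walksPer, as.integer(nC),
                            ctx$closed, ctx$ic, .measureCode(measure),
                            ctx$beyond, as.numeric(maxSteps), restartProb)
  bg <- prof$fh[prof$ok & !is.na(prof$fh)]
  nExcluded <- length(prof$fh) - length(bg)
  if (!length(bg))
    stop("evaluation failed: no walk produced a defined homogeneity")
  TValueResult(scoreValue(fh), bg, nExcluded = nExcluded,
               seed = if (is.null(seed)) NA_integer_ else seed)
}
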