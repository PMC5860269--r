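# Co-expression validation: community co-expression scores, random-walk
# background distributions, and the quantile-overlap statistic.

#' Read a node x sample expression matrix from TSV
#'
#' First column holds node IDs, header row holds sample IDs. Rows mapped to
#' the same node ID are averaged (duplicate source transcripts collapse onto
#' one profile per node).
#'
#' @param path path to a TSV file
#' @return numeric matrix with node-ID rownames and sample colnames
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs id column plus samples")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(ids)) {
    n <- table(ids)
    m <- rowsum(m, group = ids)
    m <- m / as.numeric(n[rownames(m)])
  } else {
    rownames(m) <- ids
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix with node-ID rownames
#' @param path output path
#' @return `path`, invisibly
#' @export
writeExpressionMatrix <- function(expr, path) {
  df <- data.frame(node = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Community co-expression score
#'
#' The mean absolute Pearson correlation over all unordered member pairs
#' whose expression profiles are both present in the matrix and both of
#' nonzero variance. Pairs failing either condition are excluded (the
#' correlation is undefined, which is not the same as 0) and counted. With
#' fewer than two usable members the score is undefined.
#'
#' @param community character vector of member node IDs
#' @param expr numeric matrix with node-ID rownames (samples in columns)
#' @return a [CoexpressionScore-class]
#' @export
communityCoexpression <- function(community, expr) {
  members <- unique(community)
  nPairsAll <- length(members) * (length(members) - 1L) / 2L
  present <- members[members %in% rownames(expr)]
  usable <- present[apply(expr[present, , drop = FALSE], 1L,
                          stats::sd) > 0]
  k <- length(usable)
  if (k < 2L) {
    return(new("CoexpressionScore", value = NA_real_, nPairs = 0L,
               nExcluded = as.integer(nPairsAll)))
  }
  cc <- abs(stats::cor(t(expr[usable, , drop = FALSE])))
  vals <- cc[upper.tri(cc)]
  nPairs <- as.integer(k * (k - 1L) / 2L)
  new("CoexpressionScore", value = mean(vals), nPairs = nPairs,
      nExcluded = as.integer(nPairsAll - nPairs))
}

#' Random-walk background co-expression distribution
#'
#' From every node whose component is large enough, samples `walksPerNode`
#' short random walks of `walkSize` distinct nodes and scores each proxy
#' module by [communityCoexpression()]. Walks with undefined scores (fewer
#' than two usable profiles) are dropped, with their count reported.
#'
#' @param g an igraph graph with named vertices
#' @param expr numeric matrix with node-ID rownames
#' @param walksPerNode walks per start node (default 1000)
#' @param walkSize distinct nodes per walk (default 6)
#' @param seed optional seed set before sampling
#' @param maxSteps per-walk step budget
#' @return data.frame with columns `start`, `value`, `n_pairs`,
#'   `n_excluded`, one row per walk with a defined score; the number of
#'   undefined walks is attached as attribute `n_undefined` and the skipped
#'   (infeasible) nodes as `n_skipped`
#' @export
backgroundCoexpression <- function(g, expr, walksPerNode = 1000,
                                   walkSize = 6, seed = NULL,
                                   maxSteps = .defaultMaxSteps(walkSize)) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- .walkContext(g)
  comp <- igraph::components(g)
  feasible <- which(comp$csize[comp$membership] >= walkSize)
  nSkipped <- igraph::vcount(g) - length(feasible)
  if (nSkipped > 0L)
    warning(nSkipped, " node(s) skipped: component smaller than walkSize")
  if (!length(feasible)) stop("no feasible start node")
  vis <- cpp_sample_walks(ctx$adj, feasible - 1L, as.integer(walksPerNode),
                          as.integer(walkSize), as.numeric(maxSteps), 0)
  ok <- !is.na(vis[, 1L])
  starts <- rep(ctx$nodes[feasible], each = walksPerNode)[ok]
  scores <- lapply(which(ok), function(w) {
    communityCoexpression(ctx$nodes[vis[w, ] + 1L], expr)
  })
  defined <- vapply(scores, isDefined, logical(1))
  out <- data.frame(
    start = starts[defined],
    value = vapply(scores[defined], scoreValue, numeric(1)),
    n_pairs = vapply(scores[defined], nPairsUsed, integer(1)),
    n_excluded = vapply(scores[defined], function(s) s@nExcluded,
                        integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(!defined) + sum(!ok)
  attr(out, "n_skipped") <- nSkipped
  out
}

#' Overlap between community and background co-expression distributions
#'
#' Sets a threshold at the given empirical quantile of the community score
#' distribution (linear interpolation between order statistics) and returns
#' the percentage of background scores strictly exceeding it. 0% indicates a
#' strong community-specific co-expression signal; when both samples come
#' from the same distribution the expected value is `100 * (1 - quantile)`.
#'
#' @param communityScores numeric vector of community co-expression scores
#' @param backgroundScores numeric vector of background (walk) scores
#' @param quantile quantile of the community distribution used as threshold
#'   (default 0.25)
#' @param type quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation)
#' @return percentage in `[0, 100]`
#' @export
overlapScore <- function(communityScores, backgroundScores,
                         quantile = 0.25, type = 7) {
  stopifnot(length(communityScores) > 0L, length(backgroundScores) > 0L)
  thr <- stats::quantile(communityScores, probs = quantile, type = type,
                         names = FALSE, na.rm = TRUE)
  100 * mean(backgroundScores > thr)
}
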