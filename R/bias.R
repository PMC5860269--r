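# Inspection-bias diagnostics: research-focus scores of walk-sampled proxy
# modules, node-level profiles, hypergeometric functional enrichment, and the
# focus-homogeneity correlation.

#' Research focus of a proxy module
#'
#' The fraction of module nodes that carry at least one direct annotation
#' beyond the namespace root — a proxy for how well-studied the module's
#' proteins are. Root-only (and entirely unannotated) nodes do not count.
#'
#' @param proxyModule character vector of node IDs
#' @param annot an [AnnotationSet-class]
#' @param root root term (default the annotation set's root)
#' @return numeric in `[0, 1]`
#' @export
researchFocus <- function(proxyModule, annot, root = annot@root) {
  stopifnot(length(proxyModule) >= 1L)
  beyond <- vapply(proxyModule, function(v) {
    d <- annot@direct[[v]]
    !is.null(d) && length(setdiff(d, root)) > 0L
  }, logical(1))
  mean(beyond)
}

#' Per-node research-focus and homogeneity profiles
#'
#' From every feasible node, samples `walksPerNode` proxy modules of
#' `moduleSize` distinct nodes and maps the module-level measurements back to
#' the node by averaging: `mean_fh` over the walks with defined functional
#' homogeneity, `research_focus` over all completed walks. Nodes whose
#' connected component is smaller than `moduleSize` are reported with
#' `feasible = FALSE` and `NA` scores. Both fields are computed from the same
#' walk set.
#'
#' @param g an igraph graph with named vertices
#' @param annot an [AnnotationSet-class]
#' @param measure similarity measure, see [pairwiseSimilarity()]
#' @param moduleSize distinct nodes per proxy module (default 3)
#' @param walksPerNode walks per node (default 1000; heavier sampling
#'   sharpens the profiles at linear cost)
#' @param seed optional seed set before sampling
#' @param restartProb restart probability (default 0)
#' @param maxSteps per-walk step budget
#' @return data.frame with columns `node`, `mean_fh`, `research_focus`,
#'   `n_walks`, `n_defined`, `feasible`
#' @export
nodeProfiles <- function(g, annot, measure = c("pandey", "simUI", "simGIC"),
                         moduleSize = 3, walksPerNode = 1000, seed = NULL,
                         restartProb = 0,
                         maxSteps = .defaultMaxSteps(moduleSize)) {
  measure <- match.arg(measure)
  stopifnot(moduleSize >= 2)
  if (!is.null(seed)) set.seed(seed)
  ctx <- .walkContext(g, annot)
  comp <- igraph::components(g)
  feasible <- comp$csize[comp$membership] >= moduleSize
  idx <- which(feasible)
  out <- data.frame(node = ctx$nodes, mean_fh = NA_real_,
                    research_focus = NA_real_, n_walks = 0L,
                    n_defined = 0L, feasible = feasible,
                    stringsAsFactors = FALSE)
  if (!length(idx)) return(out)
  prof <- cpp_walk_profiles(ctx$adj, idx - 1L, as.integer(walksPerNode),
                            as.integer(moduleSize), ctx$closed, ctx$ic,
                            .measureCode(measure), ctx$beyond,
                            as.numeric(maxSteps), restartProb)
  byStart <- prof$start + 1L
  okFh <- prof$ok & !is.na(prof$fh)
  walkSets <- split(seq_along(byStart), byStart)
  for (key in names(walkSets)) {
    i <- as.integer(key)
    sel <- walkSets[[key]][prof$ok[walkSets[[key]]]]
    out$n_walks[i] <- length(sel)
    if (length(sel)) out$research_focus[i] <- mean(prof$focus[sel])
    selFh <- sel[okFh[sel]]
    out$n_defined[i] <- length(selFh)
    if (length(selFh)) out$mean_fh[i] <- mean(prof$fh[selFh])
  }
  out
}

#' Hypergeometric functional enrichment of a community
#'
#' For every term present in the ancestor-closed annotation of the community,
#' tests whether the term is carried by more community members than expected
#' when drawing the community uniformly from the universe: the upper-tail
#' hypergeometric p-value of the observed member count, given the term's
#' count in the universe. P-values are Benjamini-Hochberg adjusted across the
#' tested terms.
#'
#' @param community character vector of member node IDs
#' @param annot an [AnnotationSet-class]
#' @param universe character vector of node IDs containing the community
#' @return data.frame with columns `term`, `k` (community count), `K`
#'   (universe count), `p_value`, `adjusted_p`, ordered by `p_value`; empty
#'   for an empty community
#' @export
functionalEnrichment <- function(community, annot, universe) {
  members <- unique(community)
  universe <- unique(universe)
  if (!all(members %in% universe))
    stop("universe must contain every community member")
  if (!length(members))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      p_value = numeric(), adjusted_p = numeric()))
  N <- length(universe)
  n <- length(members)
  commTerms <- table(unlist(annot@closed[members], use.names = FALSE))
  if (!length(commTerms))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      p_value = numeric(), adjusted_p = numeric()))
  uniTerms <- table(unlist(annot@closed[universe], use.names = FALSE))
  terms <- names(commTerms)
  k <- as.integer(commTerms)
  K <- as.integer(uniTerms[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = terms, k = k, K = K, p_value = p,
                    adjusted_p = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res[order(res$p_value, res$term), , drop = FALSE]
}

#' Walk-background enrichment of a single term
#'
#' An alternative to the hypergeometric test that judges a term's frequency
#' in the community against its frequencies in random-walk proxy modules from
#' the same local environment, using the same tail statistic as the
#' community-level evaluation: `T = (m + 1) / (M + 1)` with `m` the walks in
#' which the term is strictly more frequent than in the community.
#'
#' @param g an igraph graph with named vertices
#' @param community character vector of member node IDs
#' @param annot an [AnnotationSet-class]
#' @param term a term ID
#' @param totalWalks total walks (default [calibrateWalkCount()])
#' @param seed optional seed
#' @return list with `community_freq`, `m`, `M`, `t_value`
#' @export
enrichmentTValue <- function(g, community, annot, term, totalWalks = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  members <- unique(community)
  ctx <- .walkContext(g, annot)
  mi <- match(members, ctx$nodes)
  if (anyNA(mi)) stop("community members not in graph")
  hasTerm <- vapply(ctx$nodes, function(n) term %in% annot@closed[[n]],
                    logical(1), USE.NAMES = FALSE)
  nC <- length(members)
  if (is.null(totalWalks)) totalWalks <- calibrateWalkCount()
  walksPer <- as.integer(ceiling(totalWalks / nC))
  vis <- cpp_sample_walks(ctx$adj, mi - 1L, walksPer, as.integer(nC),
                          .defaultMaxSteps(nC), 0)
  ok <- !is.na(vis[, 1L])
  freqs <- vapply(which(ok), function(w) mean(hasTerm[vis[w, ] + 1L]),
                  numeric(1))
  commFreq <- mean(hasTerm[mi])
  m <- sum(freqs > commFreq)
  M <- length(freqs)
  list(community_freq = commFreq, m = m, M = M,
       t_value = (m + 1) / (M + 1))
}

#' Correlation between research focus and local homogeneity
#'
#' Rank (Spearman) correlation between the `research_focus` and `mean_fh`
#' columns of a [nodeProfiles()] table, restricted to profiles with a defined
#' homogeneity. Spearman is the default because the Pandey homogeneity scale
#' is unbounded; Pearson is available. A constant input yields an undefined
#' correlation, flagged with `NA` and a warning.
#'
#' @param profiles a data.frame from [nodeProfiles()]
#' @param method `"spearman"` (default) or `"pearson"`
#' @return list with `estimate`, `p_value`, `method`, `n`
#' @export
biasCorrelation <- function(profiles, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(profiles$mean_fh) & !is.na(profiles$research_focus)
  x <- profiles$research_focus[ok]
  y <- profiles$mean_fh[ok]
  if (length(x) < 3L) stop("need at least 3 profiles with defined mean_fh")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, method = method,
                n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x))
}
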