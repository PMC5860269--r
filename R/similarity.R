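# Pairwise protein functional similarity over ancestor-closed GO term sets,
# community functional homogeneity, and the network background threshold.

.measureCode <- function(measure) {
  switch(match.arg(measure, c("pandey", "simUI", "simGIC")),
         simUI = 1L, simGIC = 2L, pandey = 3L)
}

# set-based similarity of two closed term sets (character vectors)
.setSimilarity <- function(cp, cq, ic, measure) {
  inter <- intersect(cp, cq)
  switch(measure,
    simUI = {
      nUnion <- length(cp) + length(cq) - length(inter)
      if (nUnion == 0L) 0 else length(inter) / nUnion
    },
    simGIC = {
      icUnion <- sum(ic[union(cp, cq)])
      if (icUnion <= 0) 0 else sum(ic[inter]) / icUnion
    },
    pandey = sum(ic[inter]))
}

#' Pairwise functional similarity of two annotated nodes
#'
#' All three measures operate on the ancestor-closed GO term sets of the two
#' nodes. With intersection `I` and union `U` of the closed sets and
#' information content `ic`:
#' \describe{
#'   \item{simUI}{`|I| / |U|`, in `[0, 1]`}
#'   \item{simGIC}{`sum(ic[I]) / sum(ic[U])`, in `[0, 1]`; defined as 0 when
#'     the union carries no information (both sets reduce to the root)}
#'   \item{pandey}{`sum(ic[I])`, an unbounded information-content sum}
#' }
#' A node without annotation yields `NA` — an undefined similarity, distinct
#' from a score of 0.
#'
#' @param p,q node IDs
#' @param annot an [AnnotationSet-class]
#' @param measure `"pandey"` (default), `"simUI"`, or `"simGIC"`
#' @return numeric similarity, or `NA` when either node is unannotated
#' @export
pairwiseSimilarity <- function(p, q, annot,
                               measure = c("pandey", "simUI", "simGIC")) {
  measure <- match.arg(measure)
  cp <- annot@closed[[p]]
  cq <- annot@closed[[q]]
  if (is.null(cp) || is.null(cq) || !length(cp) || !length(cq))
    return(NA_real_)
  .setSimilarity(cp, cq, annot@ic, measure)
}

#' Functional homogeneity of a community
#'
#' The arithmetic mean of pairwise similarity over all unordered pairs of
#' annotated community members. Members without any annotation are ignored
#' (not scored as 0) and counted; with fewer than two annotated members the
#' score is undefined.
#'
#' @param community character vector of member node IDs
#' @param annot an [AnnotationSet-class]
#' @param measure similarity measure, see [pairwiseSimilarity()]
#' @return a [HomogeneityScore-class]
#' @export
functionalHomogeneity <- function(community, annot,
                                  measure = c("pandey", "simUI", "simGIC")) {
  measure <- match.arg(measure)
  stopifnot(length(community) >= 1L)
  members <- unique(community)
  ann <- members[vapply(members, function(n) {
    cl <- annot@closed[[n]]
    !is.null(cl) && length(cl) > 0L
  }, logical(1))]
  nIgnored <- length(members) - length(ann)
  if (length(ann) < 2L) {
    return(new("HomogeneityScore", value = NA_real_, nPairs = 0L,
               nIgnored = as.integer(nIgnored),
               reason = "fewer than two annotated members"))
  }
  k <- length(ann)
  total <- 0
  for (i in seq_len(k - 1L)) {
    ci <- annot@closed[[ann[i]]]
    for (j in seq.int(i + 1L, k)) {
      total <- total + .setSimilarity(ci, annot@closed[[ann[j]]],
                                      annot@ic, measure)
    }
  }
  nPairs <- k * (k - 1L) / 2
  new("HomogeneityScore", value = total / nPairs,
      nPairs = as.integer(nPairs), nIgnored = as.integer(nIgnored),
      reason = "")
}

#' Network background similarity threshold
#'
#' The mean or median of pairwise similarity over all edges of the network
#' whose endpoints are both annotated; edges with an unannotated endpoint are
#' excluded. This is the network-wide reference against which community
#' functional homogeneity is judged.
#'
#' @param g an igraph graph with named vertices
#' @param annot an [AnnotationSet-class]
#' @param measure similarity measure, see [pairwiseSimilarity()]
#' @param statistic `"median"` (default) or `"mean"`
#' @return numeric threshold
#' @export
backgroundThreshold <- function(g, annot,
                                measure = c("pandey", "simUI", "simGIC"),
                                statistic = c("median", "mean")) {
  measure <- match.arg(measure)
  statistic <- match.arg(statistic)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) stop("graph has no edges")
  annOk <- function(n) {
    cl <- annot@closed[[n]]
    !is.null(cl) && length(cl) > 0L
  }
  ok1 <- vapply(el[, 1L], annOk, logical(1))
  ok2 <- vapply(el[, 2L], annOk, logical(1))
  el <- el[ok1 & ok2, , drop = FALSE]
  if (nrow(el) == 0L)
    stop("no edge with both endpoints annotated")
  sims <- vapply(seq_len(nrow(el)), function(i) {
    .setSimilarity(annot@closed[[el[i, 1L]]], annot@closed[[el[i, 2L]]],
                   annot@ic, measure)
  }, numeric(1))
  if (statistic == "median") stats::median(sims) else mean(sims)
}
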