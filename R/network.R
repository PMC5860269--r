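# Edge-list input, filtering, and summary statistics for undirected
# interaction networks. Graphs are igraph objects with a 'name' vertex
# attribute; node IDs are opaque strings.

#' Read an undirected network from a two-column edge list
#'
#' Lines starting with `#` and blank lines are ignored. Each remaining line
#' must carry at least two fields; only the first two are used. Self-loops
#' are dropped and duplicate edges (in either orientation) are collapsed,
#' with counts reported via `message()`.
#'
#' @param path path to the edge-list file
#' @param delimiter field separator; `NULL` (default) splits on any
#'   whitespace, otherwise a single character such as `"\t"`
#' @return an undirected, simple igraph graph with named vertices
#' @seealso [writeEdgeList()], [largestConnectedComponent()], [graphStats()]
#' @export
readEdgeList <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- if (is.null(delimiter)) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    strsplit(lines, delimiter, fixed = TRUE)
  }
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("malformed edge-list line ", lineNo[bad[1L]], " in ", path,
         ": fewer than two fields")
  }
  u <- vapply(fields, `[[`, character(1), 1L)
  v <- vapply(fields, `[[`, character(1), 2L)
  .buildGraph(u, v)
}

# shared constructor: drops self-loops, deduplicates unordered pairs
.buildGraph <- function(u, v, quiet = FALSE) {
  self <- u == v
  nSelf <- sum(self)
  u <- u[!self]; v <- v[!self]
  a <- pmin(u, v); b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  if (!quiet && (nSelf || nDup))
    message("dropped ", nSelf, " self-loop record(s) and ", nDup,
            " duplicate edge record(s)")
  nodes <- sort(unique(c(a, b)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(a))
    g <- igraph::add_edges(g, rbind(match(a, nodes), match(b, nodes)))
  g
}

#' Write a graph as a two-column TSV edge list
#'
#' @param g an igraph graph with named vertices
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict a graph to its largest connected component
#'
#' Ties between equally sized components are broken deterministically by the
#' lexicographically smallest member node ID. An empty graph is returned
#' unchanged.
#'
#' @param g an igraph graph with named vertices
#' @return the induced subgraph on the largest component
#' @export
largestConnectedComponent <- function(g) {
  if (igraph::vcount(g) == 0L) return(g)
  comp <- igraph::components(g)
  maxSize <- max(comp$csize)
  cand <- which(comp$csize == maxSize)
  if (length(cand) > 1L) {
    nm <- igraph::V(g)$name
    firstMember <- vapply(cand, function(ci) min(nm[comp$membership == ci]),
                          character(1))
    cand <- cand[order(firstMember)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand[1L]))
}

#' Network summary statistics from node and edge counts
#'
#' Density is `2 E / (N (N - 1))` and the average degree is `2 E / N`.
#' Formatted columns round density to 5 and degree to 2 decimals, the
#' presentation convention for interaction-network summary tables; the
#' unrounded values are kept alongside.
#'
#' @param nodeCount number of nodes
#' @param edgeCount number of edges
#' @return a one-row data.frame with columns `nodes`, `edges`, `density`,
#'   `avg_degree`, `density_fmt`, `avg_degree_fmt`; density is `NA` when
#'   `nodeCount < 2`
#' @examples
#' networkStats(10927, 49301)   # density 0.00083, average degree 9.02
#' @export
networkStats <- function(nodeCount, edgeCount) {
  n <- as.numeric(nodeCount); e <- as.numeric(edgeCount)
  dens <- if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_
  deg <- if (n >= 1) 2 * e / n else NA_real_
  data.frame(nodes = nodeCount, edges = edgeCount,
             density = dens, avg_degree = deg,
             density_fmt = round(dens, 5), avg_degree_fmt = round(deg, 2))
}

#' Summary statistics of a graph
#'
#' @param g an igraph graph
#' @return see [networkStats()]
#' @export
graphStats <- function(g) {
  networkStats(igraph::vcount(g), igraph::ecount(g))
}
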