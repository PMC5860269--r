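# End-to-end evaluation: read candidate communities, compute functional
# homogeneity and T-values, classify into the four acceptance sets, write
# reports.

#' Read candidate communities from a text file
#'
#' One community per line, whitespace-separated node IDs, optionally with a
#' leading community label. With `labels = "auto"` (default) the first token
#' of a line is treated as a label iff it does not reappear among the
#' remaining tokens of that line; `"yes"`/`"no"` force the interpretation.
#' Duplicate IDs within a line are collapsed; empty lines are skipped with a
#' warning. Unlabelled communities are named `c001`, `c002`, ...
#'
#' @param path path to the community file
#' @param labels `"auto"`, `"yes"`, or `"no"`
#' @return named list of character vectors
#' @export
readCommunities <- function(path, labels = c("auto", "yes", "no")) {
  labels <- match.arg(labels)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) warning("skipped ", sum(blank), " empty line(s)")
  lines <- lines[!blank]
  tokens <- strsplit(trimws(lines), "[ \t]+")
  out <- vector("list", length(tokens))
  nm <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tk <- tokens[[i]]
    labelled <- switch(labels,
      yes = TRUE,
      no = FALSE,
      auto = length(tk) > 1L && !(tk[1L] %in% tk[-1L]))
    if (labelled && length(tk) > 1L) {
      nm[i] <- tk[1L]
      out[[i]] <- unique(tk[-1L])
    } else {
      nm[i] <- sprintf("c%03d", i)
      out[[i]] <- unique(tk)
    }
  }
  names(out) <- nm
  out
}

#' Write communities as a labelled text file
#'
#' @param communities named list of character vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCommunities <- function(communities, path) {
  lines <- vapply(names(communities), function(nm) {
    paste(c(nm, communities[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Retain communities within an inclusive size range
#'
#' Communities proposed as functional modules are conventionally restricted
#' to 6-35 members: large enough to be non-trivial associations, small
#' enough to be experimentally testable.
#'
#' @param communities list of character vectors
#' @param minSize inclusive lower bound (default 6)
#' @param maxSize inclusive upper bound (default 35)
#' @return the filtered list
#' @export
filterBySize <- function(communities, minSize = 6, maxSize = 35) {
  stopifnot(minSize <= maxSize)
  sizes <- lengths(communities)
  communities[sizes >= minSize & sizes <= maxSize]
}

#' Evaluate communities and classify them into four acceptance sets
#'
#' Computes one network-wide functional-homogeneity threshold (the
#' [backgroundThreshold()] of interacting-protein similarities), then for
#' each community its functional homogeneity and walk-background T-value,
#' and classifies it:
#' \describe{
#'   \item{both}{FH strictly above the threshold and `T <= tThreshold`}
#'   \item{cw_only}{accepted only by the walk evaluation (`T <= tThreshold`)}
#'   \item{fh_only}{accepted only by functional homogeneity}
#'   \item{neither}{rejected by both, or FH undefined}
#' }
#' Failures are contained per community: a community that cannot be
#' evaluated (members missing from the graph, undefined homogeneity, walk
#' infeasibility) is reported as `neither` with a reason in `note` rather
#' than aborting the run.
#'
#' @param g an igraph graph with named vertices
#' @param communities named list of character vectors
#' @param annot an [AnnotationSet-class]
#' @param measure similarity measure, see [pairwiseSimilarity()]
#' @param tThreshold T-value acceptance threshold (default 0.5; acceptance is
#'   `T <= tThreshold`, so a community matching the threshold exactly is
#'   accepted)
#' @param fhStatistic `"median"` (default) or `"mean"` for the FH threshold
#' @param totalWalks walks per community (default [calibrateWalkCount()])
#' @param seed optional seed, set once before the run and recorded per row
#' @param restartProb restart probability for the walks (default 0)
#' @return data.frame with one row per community: `community_id`, `size`,
#'   `n_annotated`, `n_missing`, `fh`, `fh_threshold`, `m`, `M`, `t_value`,
#'   `fh_accepted`, `cw_accepted`, `class`, `note`, `seed`
#' @export
evaluateCommunities <- function(g, communities, annot,
                                measure = c("pandey", "simUI", "simGIC"),
                                tThreshold = 0.5,
                                fhStatistic = c("median", "mean"),
                                totalWalks = NULL, seed = NULL,
                                restartProb = 0) {
  measure <- match.arg(measure)
  fhStatistic <- match.arg(fhStatistic)
  stopifnot(tThreshold > 0, tThreshold <= 1)
  if (!is.null(seed)) set.seed(seed)
  fhThr <- backgroundThreshold(g, annot, measure, fhStatistic)
  nodes <- igraph::V(g)$name
  rows <- lapply(names(communities), function(id) {
    members <- unique(communities[[id]])
    present <- members[members %in% nodes]
    nMissing <- length(members) - length(present)
    row <- data.frame(community_id = id, size = length(members),
                      n_annotated = NA_integer_, n_missing = nMissing,
                      fh = NA_real_, fh_threshold = fhThr, m = NA_integer_,
                      M = NA_integer_, t_value = NA_real_,
                      fh_accepted = FALSE, cw_accepted = FALSE,
                      class = "neither", note = "",
                      seed = if (is.null(seed)) NA_integer_ else seed,
                      stringsAsFactors = FALSE)
    if (nMissing > 0L)
      row$note <- paste0(nMissing, " member(s) not in network")
    tryCatch({
      fh <- functionalHomogeneity(present, annot, measure)
      row$n_annotated <- length(present) - fh@nIgnored
      if (!isDefined(fh)) {
        row$note <- paste0(row$note, if (nzchar(row$note)) "; ",
                           "fh undefined: ", fh@reason)
        return(row)
      }
      row$fh <- scoreValue(fh)
      tv <- computeTValue(g, present, annot, measure,
                          totalWalks = totalWalks,
                          restartProb = restartProb)
      row$m <- tv@m
      row$M <- tv@M
      row$t_value <- tValue(tv)
      row$fh_accepted <- row$fh > fhThr
      row$cw_accepted <- row$t_value <= tThreshold
      row$class <- if (row$fh_accepted && row$cw_accepted) "both"
        else if (row$cw_accepted) "cw_only"
        else if (row$fh_accepted) "fh_only"
        else "neither"
      row
    }, error = function(e) {
      row$note <- paste0(row$note, if (nzchar(row$note)) "; ",
                         conditionMessage(e))
      row
    })
  })
  do.call(rbind, rows)
}

#' Write an evaluation table as TSV
#'
#' @param records data.frame from [evaluateCommunities()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEvaluation <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
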