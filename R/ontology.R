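# Minimal OBO 1.2 reader for a single ontology namespace, plus ancestor
# closure and depth utilities. Only [Term] stanzas are interpreted; is_a and
# "relationship: part_of" edges form the parent relation.

#' Load one namespace of an ontology from an OBO file
#'
#' Obsolete terms are dropped, alternative IDs are mapped to canonical IDs,
#' and only terms of the selected namespace are retained. Parent edges are
#' taken from `is_a` and `relationship: part_of` lines; edges pointing outside
#' the retained namespace are ignored. The namespace must contain exactly one
#' parentless (root) term; a cyclic parent relation is a structural error.
#'
#' @param path path to an OBO file
#' @param namespace namespace to retain (default `"biological_process"`)
#' @return a [GeneOntology-class]
#' @export
loadOntology <- function(path, namespace = "biological_process") {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(which(startsWith(lines, "[")), length(lines) + 1L)

  ids <- character(); ns <- character(); nm <- character()
  parents <- list(); alt <- character(); altOwner <- character()
  for (s in starts) {
    end <- min(bounds[bounds > s]) - 1L
    stanza <- lines[s:end]
    getv <- function(key) {
      sel <- startsWith(stanza, paste0(key, ": "))
      sub("\\s*!.*$", "", substring(stanza[sel], nchar(key) + 3L))
    }
    id <- getv("id")
    if (length(id) != 1L) next
    if (any(getv("is_obsolete") == "true")) next
    tns <- getv("namespace")
    isa <- getv("is_a")
    rel <- getv("relationship")
    partOf <- sub("^part_of\\s+", "",
                  rel[startsWith(rel, "part_of ")])
    ids <- c(ids, id)
    ns <- c(ns, if (length(tns)) tns[1L] else NA_character_)
    name1 <- getv("name")
    nm <- c(nm, if (length(name1)) name1[1L] else NA_character_)
    parents[[id]] <- trimws(c(isa, partOf))
    aids <- getv("alt_id")
    if (length(aids)) {
      alt <- c(alt, aids)
      altOwner <- c(altOwner, rep(id, length(aids)))
    }
  }
  keep <- !is.na(ns) & ns == namespace
  if (!any(keep)) stop("namespace '", namespace, "' not present in ", path)
  terms <- ids[keep]
  parents <- lapply(parents[terms],
                    function(p) unique(p[p %in% terms & p != ""]))
  names(parents) <- terms
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop("namespace '", namespace, "' must have exactly one root, found ",
         length(roots))
  termName <- stats::setNames(nm[keep], terms)
  keepAlt <- altOwner %in% terms
  altIds <- stats::setNames(altOwner[keepAlt], alt[keepAlt])
  onto <- new("GeneOntology", terms = terms, parents = parents,
              namespace = namespace, root = roots, termName = termName,
              altIds = altIds)
  # validity (run by new()) rejects cyclic parent relations
  onto
}

#' Resolve a term ID against an ontology, following alternative IDs
#'
#' @param ontology a [GeneOntology-class]
#' @param term a term or alt_id
#' @return the canonical term ID, or `NA_character_` when unknown
#' @export
resolveTerm <- function(ontology, term) {
  if (term %in% ontology@terms) return(term)
  canon <- ontology@altIds[term]
  if (is.na(canon)) NA_character_ else unname(canon)
}

#' Ancestor closure of every term
#'
#' For each term, the set containing the term itself and all ancestors
#' reachable over `is_a`/`part_of` parent edges up to the namespace root.
#' Computed once for the whole ontology by memoized traversal.
#'
#' @param ontology a [GeneOntology-class]
#' @return named list, term -> character vector (term included)
#' @export
termAncestors <- function(ontology) {
  memo <- new.env(parent = emptyenv(), size = length(ontology@terms))
  parents <- ontology@parents
  anc <- function(t) {
    hit <- memo[[t]]
    if (!is.null(hit)) return(hit)
    res <- unique(c(t, unlist(lapply(parents[[t]], anc), use.names = FALSE)))
    memo[[t]] <- res
    res
  }
  out <- lapply(ontology@terms, anc)
  names(out) <- ontology@terms
  out
}

#' Depth of every term below the namespace root
#'
#' The shortest parent-edge distance from each term to the root (root depth
#' 0), by breadth-first traversal of the child relation.
#'
#' @param ontology a [GeneOntology-class]
#' @return named integer vector
#' @export
termDepths <- function(ontology) {
  children <- .childMap(ontology)
  depth <- stats::setNames(rep(NA_integer_, length(ontology@terms)),
                           ontology@terms)
  depth[ontology@root] <- 0L
  frontier <- ontology@root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

.childMap <- function(ontology) {
  ch <- lapply(stats::setNames(ontology@terms, ontology@terms),
               function(t) character())
  for (t in ontology@terms) {
    for (p in ontology@parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  }
  ch
}

#' Write an ontology as a minimal OBO 1.2 file
#'
#' Emits one `[Term]` stanza per term with `is_a` lines for its parents (the
#' reader treats is_a and part_of identically, so all parent edges are written
#' as is_a). Round-trips through [loadOntology()].
#'
#' @param ontology a [GeneOntology-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeObo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in ontology@terms) {
    nmv <- ontology@termName[t]
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", if (is.na(nmv)) t else nmv),
                 paste0("namespace: ", ontology@namespace),
                 paste0("is_a: ", ontology@parents[[t]]),
                 ""), con)
  }
  invisible(path)
}
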