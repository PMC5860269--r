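# Shared builders and independent brute-force oracles. The oracles
# deliberately use naive algorithms (repeated expansion, double loops,
# exhaustive enumeration) so they share no code path with the package.

# small ontology from an explicit parent map; root is the unique parentless
# term
makeOntology <- function(parents, namespace = "biological_process") {
  terms <- names(parents)
  root <- terms[lengths(parents) == 0L]
  new("GeneOntology", terms = terms,
      parents = lapply(parents, as.character), namespace = namespace,
      root = root, termName = stats::setNames(terms, terms),
      altIds = character())
}

# diamond-with-tail ontology used across similarity tests:
#   root <- a <- b ; root <- c ; a <- d ; c <- d (d has two parents)
toyOntology <- function() {
  makeOntology(list(root = character(), a = "root", b = "a", c = "root",
                    d = c("a", "c")))
}

# naive ancestor closure: repeated parent expansion to a fixed point
oracleClosure <- function(ontology, term) {
  cur <- term
  repeat {
    nxt <- unique(c(cur, unlist(ontology@parents[cur], use.names = FALSE)))
    if (setequal(nxt, cur)) return(sort(cur))
    cur <- nxt
  }
}

# brute-force similarity from closed sets and an IC table
oracleSim <- function(cp, cq, ic, measure) {
  inter <- cp[cp %in% cq]
  uni <- unique(c(cp, cq))
  switch(measure,
         simUI = length(inter) / length(uni),
         simGIC = if (sum(ic[uni]) > 0) sum(ic[inter]) / sum(ic[uni]) else 0,
         pandey = sum(ic[inter]))
}

# brute-force functional homogeneity: explicit double loop over annotated
# members
oracleFH <- function(members, annot, measure) {
  ann <- members[vapply(members,
                        function(n) length(annot@closed[[n]]) > 0,
                        logical(1))]
  if (length(ann) < 2) return(NA_real_)
  vals <- c()
  for (i in seq_along(ann)) for (j in seq_along(ann)) {
    if (i < j) {
      vals <- c(vals, oracleSim(annot@closed[[ann[i]]],
                                annot@closed[[ann[j]]], annot@ic, measure))
    }
  }
  mean(vals)
}

# annotation set straight from direct term lists over the toy ontology
toyAnnotations <- function(direct, ontology = toyOntology()) {
  buildAnnotationSet(direct, ontology)
}

# path graph a-b-c-... as igraph with names
pathGraph <- function(n) {
  nodes <- letters[seq_len(n)]
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- nodes
  g
}

completeGraph <- function(n) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# default fixture shared by heavier tests (built once per test file load)
defaultFixture <- function(seed = 7) {
  spec <- fixtureSpec(seed = seed)
  pin <- suppressMessages(generatePin(spec))
  onto <- generateOntology(spec@ontologyDepth, spec@ontologyBranching)
  ann <- generateAnnotations(pin, onto, spec)
  list(spec = spec, pin = pin, onto = onto, ann = ann$annotations,
       studied = ann$studied)
}
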