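oboLines <- c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: root process",
  "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: a", "alt_id: GO:0000099",
  "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
  "[Term]", "id: GO:0000003", "name: b",
  "namespace: biological_process",
  "relationship: part_of GO:0000002 ! a", "",
  "[Term]", "id: GO:0000004", "name: gone",
  "namespace: biological_process", "is_a: GO:0000001",
  "is_obsolete: true", "",
  "[Term]", "id: GO:0000005", "name: other-namespace",
  "namespace: molecular_function", "")

test_that("OBO parsing keeps the namespace, drops obsoletes, maps alt_ids", {
  f <- withr::local_tempfile(lines = oboLines)
  onto <- loadOntology(f)
  expect_setequal(ontologyTerms(onto),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(ontologyRoot(onto), "GO:0000001")
  # part_of treated as a parent edge
  expect_equal(termParents(onto, "GO:0000003"), "GO:0000002")
  # alt_id lookups resolve to the canonical term
  expect_equal(resolveTerm(onto, "GO:0000099"), "GO:0000002")
  expect_equal(termParents(onto, "GO:0000099"), "GO:0000001")
  # every term reaches the root
  anc <- termAncestors(onto)
  expect_true(all(vapply(anc, function(a) "GO:0000001" %in% a,
                         logical(1))))
})

test_that("a cyclic parent relation is rejected as a structural error", {
  expect_error(
    makeOntology(list(root = character(), x = c("root", "y"), y = "x")),
    "cycle")
})

test_that("generated DAGs admit a topological order (Kahn oracle)", {
  onto <- generateOntology(4, 2, crossEdges = 5, seed = 3)
  # independent Kahn's algorithm over child -> parent edges
  terms <- ontologyTerms(onto)
  edges <- do.call(rbind, lapply(terms, function(t) {
    ps <- termParents(onto, t)
    if (length(ps)) cbind(t, ps) else NULL
  }))
  indeg <- table(factor(edges[, 2], levels = terms))
  order <- character()
  active <- terms
  repeat {
    src <- active[indeg[active] == 0]
    if (!length(src)) break
    order <- c(order, src)
    active <- setdiff(active, src)
    for (s in src) {
      ps <- edges[edges[, 1] == s, 2]
      indeg[ps] <- indeg[ps] - 1
    }
  }
  expect_equal(sort(order), sort(terms))  # all removed => acyclic
})

test_that("ancestor closure matches naive repeated expansion", {
  onto <- generateOntology(4, 2, crossEdges = 6, seed = 8)
  anc <- termAncestors(onto)
  for (t in ontologyTerms(onto)) {
    expect_equal(sort(anc[[t]]), oracleClosure(onto, t), info = t)
  }
})

test_that("ontology round-trips through the OBO writer", {
  onto <- generateOntology(3, 3)
  f <- withr::local_tempfile()
  writeObo(onto, f)
  onto2 <- loadOntology(f)
  expect_setequal(ontologyTerms(onto2), ontologyTerms(onto))
  expect_equal(ontologyRoot(onto2), ontologyRoot(onto))
  for (t in ontologyTerms(onto)) {
    expect_setequal(termParents(onto2, t), termParents(onto, t))
  }
})

gafRecord <- function(id, term, evidence = "IDA", qualifier = "",
                      aspect = "P") {
  paste(c("SYN", id, id, qualifier, term, "SYN:1", evidence, "", aspect,
          "", "", "protein", "taxon:9606", "20150801", "SYN", "", ""),
        collapse = "\t")
}

test_that("GAF loading applies evidence and NOT-qualifier filters", {
  f <- withr::local_tempfile(lines = c(
    "!gaf-version: 2.1",
    gafRecord("p1", "GO:0000002"),
    gafRecord("p1", "GO:0000003", evidence = "IPI"),   # circular, dropped
    gafRecord("p2", "GO:0000003", qualifier = "NOT"),  # negative, dropped
    gafRecord("p2", "GO:0000002", evidence = "RCA"),   # dropped
    gafRecord("p2", "GO:0000001", evidence = "ND"),    # dropped
    gafRecord("p2", "GO:0000003"),
    gafRecord("p3", "GO:0000002", aspect = "F"),       # other namespace
    gafRecord("p3", "GO:0000001")))
  onto <- loadOntology(withr::local_tempfile(lines = oboLines))
  ann <- loadAnnotations(f, onto)
  expect_equal(sort(directTerms(ann, "p1")), "GO:0000002")
  expect_equal(sort(directTerms(ann, "p2")), "GO:0000003")
  # root-only protein: closed set is exactly the root
  expect_equal(closedTerms(ann, "p3"), "GO:0000001")
  # closure: p2's part_of chain reaches the root
  expect_setequal(closedTerms(ann, "p2"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
})

test_that("unknown terms are skipped, not fatal; alt_ids resolve", {
  onto <- loadOntology(withr::local_tempfile(lines = oboLines))
  f <- withr::local_tempfile(lines = c(
    gafRecord("p1", "GO:0000099"),   # alt_id of GO:0000002
    gafRecord("p1", "GO:9999999")))  # unknown
  expect_message(ann <- loadAnnotations(f, onto), "skipped 1")
  expect_equal(directTerms(ann, "p1"), "GO:0000002")
})

test_that("information content is -log relative corpus frequency", {
  onto <- toyOntology()
  direct <- c(
    stats::setNames(rep(list("b"), 5), sprintf("p%02d", 1:5)),
    stats::setNames(rep(list("c"), 5), sprintf("p%02d", 6:10)))
  ann <- buildAnnotationSet(direct, onto)
  # term 'a' sits in the closure of the 5 'b' proteins
  expect_equal(informationContent(ann, "a"), -log(5 / 10))
  expect_equal(informationContent(ann, "root"), 0)
  expect_error(informationContent(ann, "d"), "never observed")

  # single carrier scores log N
  direct$p01 <- c("b", "d")
  ann2 <- buildAnnotationSet(direct, onto)
  expect_equal(informationContent(ann2, "d"), log(10))

  # log base is configurable
  ann3 <- buildAnnotationSet(direct, onto, logBase = 2)
  expect_equal(informationContent(ann3, "d"), log2(10))
})

test_that("IC values match a brute-force counting pass on a random corpus", {
  set.seed(21)
  onto <- generateOntology(3, 3)
  terms <- ontologyTerms(onto)
  direct <- lapply(stats::setNames(1:15, sprintf("q%02d", 1:15)),
                   function(i) sample(terms, sample(1:3, 1)))
  ann <- buildAnnotationSet(direct, onto)
  # independent pass: closures by naive expansion, counts by loop
  for (t in names(ann@corpusCount)) {
    cnt <- sum(vapply(direct, function(d) {
      any(vapply(d, function(dt) t %in% oracleClosure(onto, dt),
                 logical(1)))
    }, logical(1)))
    expect_equal(unname(ann@corpusCount[t]), cnt, info = t)
    expect_equal(informationContent(ann, t), -log(cnt / 15), info = t)
  }
})

test_that("IC is monotone from parent to child wherever both are observed", {
  fx <- defaultFixture()
  ann <- fx$ann
  for (t in names(ann@corpusCount)) {
    for (p in termParents(fx$onto, t)) {
      if (p %in% names(ann@corpusCount)) {
        expect_lte(informationContent(ann, p), informationContent(ann, t))
      }
    }
  }
})

test_that("excluding an evidence code never increases a corpus count", {
  onto <- loadOntology(withr::local_tempfile(lines = oboLines))
  f <- withr::local_tempfile(lines = c(
    gafRecord("p1", "GO:0000002"),
    gafRecord("p2", "GO:0000002", evidence = "IEA"),
    gafRecord("p2", "GO:0000003"),
    gafRecord("p3", "GO:0000003", evidence = "IEA")))
  full <- loadAnnotations(f, onto, excludedEvidence = character())
  cut <- loadAnnotations(f, onto, excludedEvidence = "IEA")
  for (t in names(cut@corpusCount)) {
    expect_lte(cut@corpusCount[[t]], full@corpusCount[[t]])
  }
})

test_that("GAF writing round-trips annotated nodes and direct sets", {
  fx <- defaultFixture()
  f <- withr::local_tempfile()
  writeGaf(fx$ann, f)
  back <- loadAnnotations(f, fx$onto)
  expect_setequal(annotatedNodes(back), annotatedNodes(fx$ann))
  for (n in annotatedNodes(fx$ann)) {
    expect_setequal(directTerms(back, n), directTerms(fx$ann, n))
  }
})

test_that("an ID map rekeys annotations onto network identifiers", {
  onto <- loadOntology(withr::local_tempfile(lines = oboLines))
  f <- withr::local_tempfile(lines = c(gafRecord("U1", "GO:0000002"),
                                       gafRecord("U2", "GO:0000003"),
                                       gafRecord("U3", "GO:0000002")))
  ann <- suppressMessages(
    loadAnnotations(f, onto, idMap = c(U1 = "101", U2 = "102")))
  expect_setequal(names(ann@direct), c("101", "102"))
  expect_equal(directTerms(ann, "101"), "GO:0000002")
})
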