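test_that("fixture generation is fully determined by the seed", {
  spec <- fixtureSpec(seed = 55)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(writeFixtures(spec, d1))
  suppressMessages(writeFixtures(spec, d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the network
  spec2 <- fixtureSpec(seed = 56)
  p1 <- suppressMessages(generatePin(spec))
  p2 <- suppressMessages(generatePin(spec2))
  expect_false(igraph::ecount(p1$graph) == igraph::ecount(p2$graph) &&
                 identical(igraph::as_edgelist(p1$graph),
                           igraph::as_edgelist(p2$graph)))
})

test_that("extreme edge probabilities produce cliques", {
  spec <- fixtureSpec(nNodes = 10, nCommunities = 1, sizeRange = c(10, 10),
                      pIntra = 1, pBackground = 0, seed = 2)
  pin <- suppressMessages(generatePin(spec))
  expect_equal(igraph::ecount(pin$graph), choose(10, 2))
  # several cliques plus connector edges
  spec2 <- fixtureSpec(nNodes = 20, nCommunities = 4, sizeRange = c(5, 5),
                       pIntra = 1, pBackground = 0, seed = 2)
  pin2 <- suppressMessages(generatePin(spec2))
  expect_equal(igraph::ecount(pin2$graph),
               4 * choose(5, 2) + pin2$nAugmented)
  expect_equal(igraph::components(pin2$graph)$no, 1L)
})

test_that("generated ontologies have the closed-form size and reach the root", {
  expect_equal(length(ontologyTerms(generateOntology(1, 3))), 4L)
  expect_equal(length(ontologyTerms(generateOntology(3, 2))), 15L)
  onto <- generateOntology(4, 3, crossEdges = 4, seed = 1)
  anc <- termAncestors(onto)
  expect_true(all(vapply(anc, function(a) ontologyRoot(onto) %in% a,
                         logical(1))))
  d <- termDepths(generateOntology(4, 3))
  expect_equal(as.integer(table(d)), as.integer(3^(0:4)))
})

test_that("annotation bias plants denser annotation in studied regions", {
  fx <- defaultFixture()
  nDirect <- lengths(fx$ann@direct)
  region <- fx$pin$region[names(fx$ann@direct)]
  tt <- stats::t.test(nDirect[region == "studied"],
                      nDirect[region == "unstudied"],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # full bias: everyone richly annotated, focus ~ 1 everywhere
  specAll <- fixtureSpec(biasFraction = 1, unstudiedAnnotProb = 1,
                         seed = 12)
  pinAll <- suppressMessages(generatePin(specAll))
  onto <- generateOntology(4, 3)
  annAll <- generateAnnotations(pinAll, onto, specAll)$annotations
  commNodes <- unlist(pinAll$communities, use.names = FALSE)
  focus <- researchFocus(commNodes, annAll)
  expect_gt(focus, 0.75)
  # zero bias: communities nearly root-only, homogeneity collapses
  spec0 <- fixtureSpec(biasFraction = 0, unstudiedAnnotProb = 0, seed = 12)
  pin0 <- suppressMessages(generatePin(spec0))
  ann0 <- generateAnnotations(pin0, onto, spec0)$annotations
  fh0 <- vapply(pin0$communities, function(cm)
    scoreValue(functionalHomogeneity(cm, ann0, "pandey")), numeric(1))
  expect_true(all(fh0 < 0.3))
})

test_that("planted partitions beat a degree-preserving rewiring null", {
  fx <- defaultFixture()
  memb <- rep(NA_integer_, igraph::vcount(fx$pin$graph))
  names(memb) <- igraph::V(fx$pin$graph)$name
  for (i in seq_along(fx$pin$communities)) {
    memb[fx$pin$communities[[i]]] <- i
  }
  memb[is.na(memb)] <- seq.int(length(fx$pin$communities) + 1,
                               length.out = sum(is.na(memb)))
  q0 <- igraph::modularity(fx$pin$graph, memb)
  set.seed(40)
  qNull <- vapply(1:30, function(i) {
    gr <- igraph::rewire(fx$pin$graph,
                         igraph::keeping_degseq(niter = 2000))
    igraph::modularity(gr, memb)
  }, numeric(1))
  z <- (q0 - mean(qNull)) / stats::sd(qNull)
  expect_gt(z, 3)
})

test_that("noise-free expression gives |r| = 1 within modules", {
  spec <- fixtureSpec(nNodes = 40, nCommunities = 3, sizeRange = c(6, 8),
                      targetCor = 0.999, nSamples = 30, seed = 4)
  pin <- suppressMessages(generatePin(spec))
  expr <- generateExpression(pin, spec)
  for (cm in pin$communities) {
    sc <- scoreValue(communityCoexpression(cm, expr))
    expect_gt(sc, 0.99)
  }
})

test_that("expression hits the target within-module correlation", {
  # 50 modules at n = 200 samples: the factor model's mean |r| must sit
  # within 0.05 of the target 0.6
  spec <- fixtureSpec(nNodes = 520, nCommunities = 50,
                      sizeRange = c(8, 12), targetCor = 0.6,
                      nSamples = 200, seed = 77)
  pin <- suppressMessages(generatePin(spec))
  expr <- generateExpression(pin, spec)
  rs <- vapply(pin$communities, function(cm)
    scoreValue(communityCoexpression(cm, expr)), numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("null expression makes modules indistinguishable from background", {
  spec <- fixtureSpec(nNodes = 60, nCommunities = 5, sizeRange = c(6, 8),
                      targetCor = 0, nSamples = 40, seed = 9)
  pin <- suppressMessages(generatePin(spec))
  expr <- generateExpression(pin, spec)
  commScores <- vapply(pin$communities, function(cm)
    scoreValue(communityCoexpression(cm, expr)), numeric(1))
  set.seed(2)
  randScores <- vapply(1:40, function(i)
    scoreValue(communityCoexpression(
      sample(rownames(expr), 7), expr)), numeric(1))
  ks <- suppressWarnings(stats::ks.test(commScores, randScores))
  expect_gt(ks$p.value, 0.01)
})

test_that("fixture files round-trip through the package readers", {
  spec <- fixtureSpec(seed = 31)
  d <- withr::local_tempdir()
  paths <- suppressMessages(writeFixtures(spec, d))
  pin <- suppressMessages(generatePin(spec))

  g <- readEdgeList(paths[["network"]])
  expect_equal(igraph::ecount(g), igraph::ecount(pin$graph))
  cs <- readCommunities(paths[["communities"]])
  expect_equal(length(cs), length(pin$communities))
  expect_setequal(cs[["comm01"]], pin$communities[["comm01"]])
  onto <- loadOntology(paths[["ontology"]])
  expect_equal(length(ontologyTerms(onto)), sum(3^(0:4)))
  ann <- loadAnnotations(paths[["annotations"]], onto)
  orig <- generateAnnotations(pin, onto, spec)$annotations
  expect_setequal(annotatedNodes(ann), annotatedNodes(orig))
  n0 <- annotatedNodes(orig)[5]
  expect_setequal(directTerms(ann, n0), directTerms(orig, n0))
  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(sum(truth$studied), 10L)
})
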