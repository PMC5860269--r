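test_that("the three measures reproduce the worked hand example", {
  # closed(p) = {root, a, b}, closed(q) = {root, a, c},
  # ic = root 0, a 1, b 2, c 2; the IC table is imposed directly so the
  # example is exact
  ann <- new("AnnotationSet",
             direct = list(p = c("b"), q = c("c")),
             closed = list(p = c("root", "a", "b"),
                           q = c("root", "a", "c")),
             corpusCount = c(root = 2, a = 2, b = 1, c = 1),
             ic = c(root = 0, a = 1, b = 2, c = 2),
             nAnnotated = 2L, root = "root", logBase = exp(1))
  expect_equal(pairwiseSimilarity("p", "q", ann, "simUI"), 2 / 4)
  expect_equal(pairwiseSimilarity("p", "q", ann, "simGIC"), 1 / 5)
  expect_equal(pairwiseSimilarity("p", "q", ann, "pandey"), 1)
})

test_that("identical profiles maximise simUI/simGIC; root-only overlap scores zero", {
  onto <- toyOntology()
  ann <- toyAnnotations(list(p = "b", q = "b", r = "c", s = character()))
  expect_equal(pairwiseSimilarity("p", "q", ann, "simUI"), 1)
  expect_equal(pairwiseSimilarity("p", "q", ann, "simGIC"), 1)
  # p closure {b,a,root}, r closure {c,root}: shared non-root 'root' only?
  # 'a' is not an ancestor of c, so the intersection is {root}
  expect_equal(pairwiseSimilarity("p", "r", ann, "simGIC"), 0)
  expect_equal(pairwiseSimilarity("p", "r", ann, "pandey"), 0)
  # unannotated partner: undefined, not zero
  expect_true(is.na(pairwiseSimilarity("p", "s", ann, "pandey")))
  expect_true(is.na(pairwiseSimilarity("p", "missing", ann, "simUI")))
})

test_that("all measures are symmetric and self-similarity is maximal", {
  fx <- defaultFixture()
  nodes <- sample(annotatedNodes(fx$ann), 8)
  for (m in c("simUI", "simGIC", "pandey")) {
    for (i in 1:4) {
      p <- nodes[i]; q <- nodes[i + 4]
      expect_equal(pairwiseSimilarity(p, q, fx$ann, m),
                   pairwiseSimilarity(q, p, fx$ann, m))
    }
    # self-similarity bounds
    p <- nodes[1]
    self <- pairwiseSimilarity(p, p, fx$ann, m)
    if (m == "pandey") {
      expect_equal(self, sum(fx$ann@ic[closedTerms(fx$ann, p)]))
    } else {
      expect_equal(self, 1)
    }
    others <- vapply(nodes[-1], pairwiseSimilarity, numeric(1), q = p,
                     annot = fx$ann, measure = m)
    expect_true(all(others <= self + 1e-12))
  }
})

test_that("adding a shared informative term never decreases any measure", {
  onto <- makeOntology(list(root = character(), a = "root", b = "root",
                            c = "root"))
  base <- toyAnnotations(list(p = "a", q = c("a", "b"), f1 = "a", f2 = "b",
                              f3 = "c"), onto)
  # p and q additionally share c (carried by f3 so IC is defined and > 0)
  richer <- toyAnnotations(list(p = c("a", "c"), q = c("a", "b", "c"),
                                f1 = "a", f2 = "b", f3 = "c"), onto)
  for (m in c("simUI", "simGIC", "pandey")) {
    expect_gte(pairwiseSimilarity("p", "q", richer, m),
               pairwiseSimilarity("p", "q", base, m))
  }
})

test_that("functional homogeneity averages pairs and ignores unannotated members", {
  onto <- makeOntology(list(root = character(), a = "root", b = "root",
                            c = "root"))
  ann <- toyAnnotations(list(p = c("a", "b"), q = c("a", "c"),
                             r = c("b", "c"), bare = character()), onto)
  fh <- functionalHomogeneity(c("p", "q", "r", "bare"), ann, "pandey")
  expect_true(isDefined(fh))
  expect_equal(nPairsUsed(fh), 3L)
  expect_equal(fh@nIgnored, 1L)
  byHand <- mean(c(pairwiseSimilarity("p", "q", ann, "pandey"),
                   pairwiseSimilarity("p", "r", ann, "pandey"),
                   pairwiseSimilarity("q", "r", ann, "pandey")))
  expect_equal(scoreValue(fh), byHand)

  # identical annotation profiles under simUI average to exactly 1
  same <- toyAnnotations(list(x = "a", y = "a", z = "a"), onto)
  expect_equal(scoreValue(functionalHomogeneity(c("x", "y", "z"), same,
                                                "simUI")), 1)

  # fewer than two annotated members: undefined with a reason
  und <- functionalHomogeneity(c("p", "bare"), ann, "pandey")
  expect_false(isDefined(und))
  expect_match(und@reason, "fewer than two")
})

test_that("homogeneity equals the brute-force double loop and is order-invariant", {
  fx <- defaultFixture()
  set.seed(5)
  for (rep in 1:5) {
    comm <- sample(igraph::V(fx$pin$graph)$name, 6)
    for (m in c("simUI", "simGIC", "pandey")) {
      got <- scoreValue(functionalHomogeneity(comm, fx$ann, m))
      expect_equal(got, oracleFH(comm, fx$ann, m))
      expect_equal(scoreValue(functionalHomogeneity(rev(comm), fx$ann, m)),
                   got)
    }
  }
})

test_that("background threshold takes the statistic over annotated edges only", {
  onto <- makeOntology(list(root = character(), a = "root", b = "root",
                            c = "root"))
  # engineered pairwise pandey scores: need ρ = {1, 2, 9}? exact magnitudes
  # are corpus-dependent, so check the statistic logic on computed sims
  f <- withr::local_tempfile(lines = c("p q", "q r", "p r", "p bare"))
  g <- readEdgeList(f)
  ann <- toyAnnotations(list(p = c("a", "b"), q = c("a", "c"),
                             r = c("b", "c"), bare = character()), onto)
  sims <- c(pairwiseSimilarity("p", "q", ann, "pandey"),
            pairwiseSimilarity("q", "r", ann, "pandey"),
            pairwiseSimilarity("p", "r", ann, "pandey"))
  expect_equal(backgroundThreshold(g, ann, "pandey", "median"),
               median(sims))
  expect_equal(backgroundThreshold(g, ann, "pandey", "mean"), mean(sims))
  # no eligible edge is an error
  f2 <- withr::local_tempfile(lines = "bare bare2")
  expect_error(backgroundThreshold(readEdgeList(f2), ann, "pandey"),
               "no edge")
})

test_that("median threshold matches a sort-and-pick oracle on the fixture", {
  fx <- defaultFixture()
  got <- backgroundThreshold(fx$pin$graph, fx$ann, "pandey", "median")
  el <- igraph::as_edgelist(fx$pin$graph)
  sims <- vapply(seq_len(nrow(el)), function(i) {
    oracleSim(closedTerms(fx$ann, el[i, 1]), closedTerms(fx$ann, el[i, 2]),
              fx$ann@ic, "pandey")
  }, numeric(1))
  sims <- sort(sims)
  n <- length(sims)
  oracle <- if (n %% 2 == 1) sims[(n + 1) / 2]
            else mean(sims[n / 2 + 0:1])
  expect_equal(got, oracle)
  expect_gt(n, 200)  # fixture provides a substantive edge sample
})
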