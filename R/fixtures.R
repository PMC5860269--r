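# Seeded synthetic fixtures: planted-partition networks whose communities
# live in a well-studied and a poorly studied region, toy ontologies,
# regionally biased annotations, and module-correlated expression. The spec
# seed fully determines every artifact; each generator derives its stream
# from the seed with a fixed offset so the artifacts are independent of the
# order in which they are generated.

#' Construct a fixture specification
#'
#' Defaults describe the standing study conditions for the package's tests:
#' a 300-node planted-partition network with 20 communities of 8-12 nodes,
#' within-community edge probability 0.6 against a regional background of
#' 0.01 (cross-region pairs 10x rarer), half of the communities (and
#' background nodes) in the well-studied region. Studied communities share 3
#' community-specific deep terms (each member carries each with probability
#' 0.8) plus Poisson(2) random deep terms per node; unstudied members carry
#' their community's 2 mid-depth terms with probability 0.35 and are
#' otherwise root-only. Expression follows a one-factor model targeting a
#' within-module correlation of 0.6 over 50 samples.
#'
#' @param nNodes,nCommunities,sizeRange,pIntra,pBackground,crossFactor,biasFraction
#'   network structure, see [FixtureSpec-class]
#' @param studiedSharedTerms,studiedShareProb,studiedExtraMean,unstudiedSharedTerms,unstudiedAnnotProb
#'   annotation structure
#' @param ontologyDepth,ontologyBranching toy ontology shape
#' @param targetCor,nSamples expression structure
#' @param seed master seed
#' @return a [FixtureSpec-class]
#' @export
fixtureSpec <- function(nNodes = 300, nCommunities = 20,
                        sizeRange = c(8, 12), pIntra = 0.6,
                        pBackground = 0.01, crossFactor = 0.1,
                        biasFraction = 0.5, studiedSharedTerms = 3,
                        studiedShareProb = 0.8, studiedExtraMean = 2,
                        unstudiedSharedTerms = 2, unstudiedAnnotProb = 0.35,
                        ontologyDepth = 4, ontologyBranching = 3,
                        targetCor = 0.6, nSamples = 50, seed = 1) {
  new("FixtureSpec", nNodes = as.integer(nNodes),
      nCommunities = as.integer(nCommunities),
      sizeRange = as.integer(sizeRange), pIntra = pIntra,
      pBackground = pBackground, crossFactor = crossFactor,
      biasFraction = biasFraction,
      studiedSharedTerms = as.integer(studiedSharedTerms),
      studiedShareProb = studiedShareProb,
      studiedExtraMean = studiedExtraMean,
      unstudiedSharedTerms = as.integer(unstudiedSharedTerms),
      unstudiedAnnotProb = unstudiedAnnotProb,
      ontologyDepth = as.integer(ontologyDepth),
      ontologyBranching = as.integer(ontologyBranching),
      targetCor = targetCor, nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

#' Generate a planted-partition interaction network with two regions
#'
#' Nodes are split into planted communities (sizes drawn uniformly from
#' `sizeRange`) plus unassigned background nodes; communities and background
#' nodes are divided between a "studied" and an "unstudied" region according
#' to `biasFraction`. Edges appear with probability `pIntra` within a
#' community, `pBackground` between nodes of the same region, and
#' `pBackground * crossFactor` across regions — annotation bias in real
#' interaction networks is spatially clustered, so the fixture gives each
#' study regime its own neighbourhood. If the resulting graph is
#' disconnected, one edge per extra component is added towards the largest
#' component (deterministically, smallest node IDs), so that restriction to
#' the largest connected component never drops planted communities.
#'
#' @param spec a [FixtureSpec-class]
#' @return list with `graph` (igraph), `communities` (named list of member
#'   vectors), `studied` (named logical per community), `region` (named
#'   character per node, `"studied"`/`"unstudied"`), `nAugmented`
#' @export
generatePin <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  set.seed(spec@seed)
  nodes <- sprintf("n%04d", seq_len(spec@nNodes))
  pool <- seq.int(spec@sizeRange[1L], spec@sizeRange[2L])
  sizes <- if (length(pool) == 1L) rep(pool, spec@nCommunities)
           else sample(pool, spec@nCommunities, replace = TRUE)
  # a heavy draw may overshoot nNodes: shrink the largest communities back
  # towards the lower bound until the sizes fit
  while (sum(sizes) > spec@nNodes) {
    i <- which.max(sizes)
    if (sizes[i] <= spec@sizeRange[1L])
      stop("infeasible spec: planted communities exceed nNodes")
    sizes[i] <- sizes[i] - 1L
  }
  commIds <- sprintf("comm%02d", seq_len(spec@nCommunities))
  membership <- rep(NA_character_, spec@nNodes)
  names(membership) <- nodes
  membership[seq_len(sum(sizes))] <- rep(commIds, times = sizes)
  communities <- split(nodes[seq_len(sum(sizes))],
                       membership[seq_len(sum(sizes))])[commIds]

  nStudied <- round(spec@biasFraction * spec@nCommunities)
  studied <- stats::setNames(seq_len(spec@nCommunities) <= nStudied,
                             commIds)
  region <- stats::setNames(rep("unstudied", spec@nNodes), nodes)
  region[unlist(communities[studied], use.names = FALSE)] <- "studied"
  bg <- nodes[is.na(membership)]
  if (length(bg)) {
    nBgStudied <- round(spec@biasFraction * length(bg))
    region[bg[seq_len(nBgStudied)]] <- "studied"
  }

  # Bernoulli edges over all unordered pairs, probability by pair type
  pairs <- utils::combn(spec@nNodes, 2L)
  u <- pairs[1L, ]; v <- pairs[2L, ]
  sameComm <- !is.na(membership[u]) & !is.na(membership[v]) &
    membership[u] == membership[v]
  sameRegion <- region[u] == region[v]
  p <- ifelse(sameComm, spec@pIntra,
              ifelse(sameRegion, spec@pBackground,
                     spec@pBackground * spec@crossFactor))
  keep <- stats::runif(length(p)) < p
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, spec@nNodes, name = nodes)
  g <- igraph::add_edges(g, rbind(u[keep], v[keep]))

  comp <- igraph::components(g)
  nAugmented <- 0L
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    anchor <- min(which(comp$membership == main))
    for (ci in setdiff(seq_len(comp$no), main)) {
      tail <- min(which(comp$membership == ci))
      g <- igraph::add_edges(g, c(anchor, tail))
      nAugmented <- nAugmented + 1L
    }
    message("added ", nAugmented, " connector edge(s) to join components")
  }
  list(graph = g, communities = communities, studied = studied,
       region = region, nAugmented = nAugmented)
}

#' Generate a toy ontology as a rooted term tree
#'
#' A complete tree of the given depth and branching factor (depth 0 is the
#' root), optionally with extra `part_of`-style cross edges from deeper terms
#' to random shallower terms (acyclic by construction).
#'
#' @param depth levels below the root
#' @param branching children per term
#' @param crossEdges number of extra parent edges to add (default 0)
#' @param seed optional seed (only relevant with `crossEdges > 0`)
#' @return a [GeneOntology-class]
#' @export
generateOntology <- function(depth, branching, crossEdges = 0,
                             seed = NULL) {
  stopifnot(depth >= 1, branching >= 1)
  if (!is.null(seed)) set.seed(seed)
  nTerms <- sum(branching^(0:depth))
  terms <- sprintf("T:%05d", seq_len(nTerms))
  parents <- vector("list", nTerms)
  names(parents) <- terms
  parents[[1L]] <- character()
  depths <- integer(nTerms)
  # term i > 1 has parent ceiling((i - 1) / branching) in a complete tree
  for (i in seq.int(2L, nTerms)) {
    pi <- ceiling((i - 1L) / branching)
    parents[[i]] <- terms[pi]
    depths[i] <- depths[pi] + 1L
  }
  if (crossEdges > 0) {
    deep <- which(depths >= 2L)
    for (k in seq_len(crossEdges)) {
      child <- sample(deep, 1L)
      shallower <- which(depths < depths[child])
      extra <- terms[sample(shallower, 1L)]
      parents[[child]] <- unique(c(parents[[child]], extra))
    }
  }
  new("GeneOntology", terms = terms, parents = parents,
      namespace = "biological_process", root = terms[1L],
      termName = stats::setNames(terms, terms), altIds = character())
}

#' Generate regionally biased annotations for a planted network
#'
#' Every node is directly annotated with the root (so functional homogeneity
#' is defined everywhere; root-only nodes simply score 0 against others and
#' do not count towards research focus). Members of studied communities
#' additionally receive their community's shared deep terms (each with
#' probability `studiedShareProb`) plus `Poisson(studiedExtraMean)` random
#' deep terms; studied-region background nodes receive random deep terms at
#' the same Poisson rate. Members of unstudied communities carry their
#' community's mid-depth terms with probability `unstudiedAnnotProb` and are
#' otherwise root-only, as are most unstudied background nodes — the planted
#' communities there remain topologically coherent but nearly invisible to
#' annotation-based scoring.
#'
#' @param pin result of [generatePin()]
#' @param ontology a [GeneOntology-class] (use [generateOntology()] with the
#'   spec's depth/branching)
#' @param spec the [FixtureSpec-class]
#' @return list with `annotations` (an [AnnotationSet-class]) and `studied`
#'   (the per-community ground-truth labels)
#' @export
generateAnnotations <- function(pin, ontology, spec) {
  set.seed(spec@seed + 1000L)
  depths <- termDepths(ontology)
  maxDepth <- max(depths)
  deepTerms <- names(depths)[depths == maxDepth]
  midTerms <- names(depths)[depths == maxDepth - 1L]
  root <- ontology@root
  nodes <- igraph::V(pin$graph)$name
  direct <- stats::setNames(rep(list(root), length(nodes)), nodes)

  for (ci in names(pin$communities)) {
    members <- pin$communities[[ci]]
    if (pin$studied[[ci]]) {
      shared <- sample(deepTerms, spec@studiedSharedTerms)
      for (v in members) {
        carry <- shared[stats::runif(length(shared)) < spec@studiedShareProb]
        extra <- sample(deepTerms, stats::rpois(1L, spec@studiedExtraMean),
                        replace = TRUE)
        direct[[v]] <- unique(c(root, carry, extra))
      }
    } else {
      shared <- sample(midTerms, spec@unstudiedSharedTerms)
      for (v in members) {
        if (stats::runif(1L) < spec@unstudiedAnnotProb)
          direct[[v]] <- unique(c(root, shared))
      }
    }
  }
  bgNodes <- setdiff(nodes, unlist(pin$communities, use.names = FALSE))
  for (v in bgNodes) {
    if (pin$region[[v]] == "studied") {
      extra <- sample(deepTerms, stats::rpois(1L, spec@studiedExtraMean),
                      replace = TRUE)
      direct[[v]] <- unique(c(root, extra))
    } else if (stats::runif(1L) < 0.2) {
      direct[[v]] <- unique(c(root, sample(midTerms, 1L)))
    }
  }
  list(annotations = buildAnnotationSet(direct, ontology),
       studied = pin$studied)
}

#' Generate module-correlated expression for a planted network
#'
#' One latent factor per planted community: member profiles are
#' `b * factor + noise` with `b = sqrt(targetCor / (1 - targetCor))` and unit
#' noise, so the expected within-module Pearson correlation equals
#' `targetCor`; non-members are independent noise. Profiles are shifted by a
#' constant (+8) and floored at 0 to keep expression levels nonnegative —
#' the shift leaves Pearson correlations untouched and the floor sits about
#' five standard deviations below the mean.
#'
#' @param pin result of [generatePin()]
#' @param spec the [FixtureSpec-class]
#' @return numeric matrix, nodes x samples
#' @export
generateExpression <- function(pin, spec) {
  set.seed(spec@seed + 2000L)
  nodes <- igraph::V(pin$graph)$name
  nS <- spec@nSamples
  b <- sqrt(spec@targetCor / (1 - spec@targetCor))
  expr <- matrix(stats::rnorm(length(nodes) * nS), nrow = length(nodes),
                 dimnames = list(nodes, sprintf("s%03d", seq_len(nS))))
  for (members in pin$communities) {
    f <- stats::rnorm(nS)
    expr[members, ] <- expr[members, , drop = FALSE] +
      matrix(b * f, nrow = length(members), ncol = nS, byrow = TRUE)
  }
  pmax(expr + 8, 0)
}

#' Write a complete fixture set to a directory
#'
#' Generates the network, ontology, annotations, and expression matrix for a
#' spec and writes them in the exact dialects the package reads: edge-list
#' TSV, labelled community text file, OBO, GAF, expression TSV, plus a
#' ground-truth TSV of per-community study labels. Byte-identical across
#' runs with the same spec.
#'
#' @param spec a [FixtureSpec-class]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
writeFixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pin <- generatePin(spec)
  onto <- generateOntology(spec@ontologyDepth, spec@ontologyBranching)
  ann <- generateAnnotations(pin, onto, spec)
  expr <- generateExpression(pin, spec)
  paths <- c(network = file.path(dir, "network.tsv"),
             communities = file.path(dir, "communities.txt"),
             ontology = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.gaf"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeEdgeList(pin$graph, paths[["network"]])
  writeCommunities(pin$communities, paths[["communities"]])
  writeObo(onto, paths[["ontology"]])
  writeGaf(ann$annotations, paths[["annotations"]])
  writeExpressionMatrix(expr, paths[["expression"]])
  utils::write.table(
    data.frame(community = names(pin$studied), studied = pin$studied),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
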