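test_that("generator is byte-identical under a fixed seed", {
  cfg <- smallSimConfig(seed = 9, nFamilies = 150L)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2"); d3 <- tempfile("sim3")
  p1 <- simulateAll(cfg, d1)
  p2 <- simulateAll(cfg, d2)
  p3 <- simulateAll(smallSimConfig(seed = 10, nFamilies = 150L), d3)
  for (nm in names(p1)) {
    expect_equal(unname(tools::md5sum(p1[[nm]])),
                 unname(tools::md5sum(p2[[nm]])), label = nm)
  }
  expect_false(unname(tools::md5sum(p1$orthogroups)) ==
                 unname(tools::md5sum(p3$orthogroups)))
})

test_that("simulated taxonomy is consistent with the species tree", {
  cfg <- smallSimConfig()
  tax <- simulateTaxonomyAndTree(cfg)
  n <- cfg$nScleractinia + cfg$nHexaOther + cfg$nCnidariaOther +
    cfg$nOutgroup
  expect_equal(length(tax$tree$tip.label), n)
  expect_equal(nrow(tax$lineages), n)
  expect_setequal(tax$tree$tip.label, tax$lineages$dataset_id)
  # patristic matrix: symmetric, zero diagonal
  D <- patristicDistances(tax$tree)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # nested groups with the configured sizes
  g <- groupsFromLineages(tax$lineages)
  expect_equal(lengths(g),
               c(Scleractinia = 8L, Hexacorallia = 12L, Cnidaria = 16L))
  expect_true(all(g$Scleractinia %in% g$Hexacorallia))
  expect_true(all(g$Hexacorallia %in% g$Cnidaria))
  # both coral suborders are present
  expect_setequal(unique(na.omit(tax$lineages$suborder)),
                  c("Complex", "Robust"))
})

test_that("planted darkness is recovered exactly by the classifier", {
  cfg <- smallSimConfig(seed = 3, nFamilies = 150L)
  tax <- simulateTaxonomyAndTree(cfg)
  fam <- simulateFamilies(cfg, tax)
  ogs <- OrthogroupSet(fam$members)
  calls <- classifyProteins(ogs, fam$annotationHits)
  ogs <- classifyOrthogroups(ogs, calls)
  got <- setNames(ogTable(ogs)$darkness, ogIds(ogs))
  want <- setNames(fam$truth$darkness, fam$truth$og_id)
  expect_equal(got[names(want)], want)
})

test_that("family origin clades are recovered by the LCA scan", {
  cfg <- smallSimConfig(seed = 5, nFamilies = 200L)
  tax <- simulateTaxonomyAndTree(cfg)
  fam <- simulateFamilies(cfg, tax)
  ogs <- assignLCAAll(OrthogroupSet(fam$members), tax$lineages)
  o <- ogTable(ogs)
  # LCA equals the oracle on every simulated OG
  byog <- split(fam$members$dataset_id, fam$members$og_id)
  for (id in sample(o$og_id, 50)) {
    want <- oracleLCA(byog[[id]], tax$lineages, defaultRankLadder())
    i <- match(id, o$og_id)
    expect_equal(c(o$lca_rank[i], o$lca_taxon[i]), unname(want))
  }
  # families that kept members in both suborders resolve to the order
  tr <- fam$truth
  sclerOgs <- tr$og_id[tr$origin == "Scleractinia"]
  spansBoth <- vapply(sclerOgs, function(id) {
    sub <- tax$lineages$suborder[match(unique(byog[[id]]),
                                       tax$lineages$dataset_id)]
    all(c("Complex", "Robust") %in% sub)
  }, logical(1))
  i <- match(sclerOgs[spansBoth], o$og_id)
  expect_true(all(o$lca_taxon[i] == "Scleractinia"))
})

test_that("bitscore observations follow the planted decay model", {
  cfg <- smallSimConfig(seed = 8, nFamilies = 300L, bitscoreSd = 5)
  tax <- simulateTaxonomyAndTree(cfg)
  fam <- simulateFamilies(cfg, tax)
  tr <- fam$truth
  big <- tr[tr$n_datasets >= 10, ]
  fits <- lapply(big$og_id, function(id) {
    o <- fam$bitscoreObs[fam$bitscoreObs$og_id == id, ]
    tryCatch(fitDecay(o$distance, o$bitscore), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  relErrA <- abs(vapply(fits[ok], function(f) f@a, 1) - big$a[ok]) /
    big$a[ok]
  expect_lt(median(relErrA), 0.1)
})

test_that("planted expression enrichment emerges; a null config does not", {
  cfg <- smallSimConfig(seed = 13, nFamilies = 500L)
  tax <- simulateTaxonomyAndTree(cfg)
  fam <- simulateFamilies(cfg, tax)
  expr <- simulateExpression(cfg, fam)
  sc <- callCellTypeExpression(
    within(expr$sc, gene_id <- sub("^old_", "", gene_id)))
  grp <- setNames(expr$genes$group, expr$genes$gene_id)
  s <- sc[sc$significant & sc$granularity == "cell",
          c("gene_id", "cell_type")]
  names(s) <- c("gene_id", "unit")
  out <- proportionBias(s, grp)
  expect_gt(out$delta$delta[out$delta$unit == "calicoblast"], 0)

  nullCfg <- smallSimConfig(seed = 13, nFamilies = 500L,
    enrichment = within(simConfig()$enrichment, {
      pDark <- c(default = 0.2); pLight <- c(default = 0.2)
    }))
  exprN <- simulateExpression(nullCfg, fam)
  scN <- callCellTypeExpression(
    within(exprN$sc, gene_id <- sub("^old_", "", gene_id)))
  sN <- scN[scN$significant & scN$granularity == "cell",
            c("gene_id", "cell_type")]
  names(sN) <- c("gene_id", "unit")
  outN <- proportionBias(sN, grp)
  # null deltas stay inside a generous two-proportion band around 0
  expect_true(all(abs(outN$delta$delta) < 0.25))
})

test_that("the planted hub-and-burst network survives the pipeline filters", {
  cfg <- smallSimConfig(seed = 21, nFamilies = 500L)
  tax <- simulateTaxonomyAndTree(cfg)
  fam <- simulateFamilies(cfg, tax)
  net <- simulateRemoteHomology(cfg, fam)
  edges <- deduplicateHits(normalizeScore(filterHits(net$hits)))
  g <- buildHomologyGraph(edges)
  s <- componentStats(g)
  expect_equal(s$n_components, cfg$network$nHubs)
  expect_equal(s$largest_component_size,
               cfg$network$satellitesPerHub + 1L)
  # decoys below the thresholds never appear as edges
  planted <- unique(c(net$truth$hub, net$truth$satellite))
  expect_true(all(c(edges$query, edges$target) %in% planted))
})
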