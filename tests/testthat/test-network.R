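mkHH <- function(q, t, prob, qfrac = 0.8, tfrac = 0.8, score = 100,
                 qlen = 200, tlen = 200) {
  data.frame(query = q, target = t, probability = prob, evalue = 1e-5,
             score = score, qstart = 1L,
             qend = as.integer(round(qfrac * qlen)),
             tstart = 1L, tend = as.integer(round(tfrac * tlen)),
             alnlen = as.integer(round(max(qfrac, tfrac) * qlen)),
             qlen = qlen, tlen = tlen, stringsAsFactors = FALSE)
}

test_that("hit filtering applies inclusive thresholds and drops self-hits", {
  hits <- rbind(
    mkHH("A", "B", 95, 0.7, 0.65),
    mkHH("C", "D", 50.0, 0.6, 0.6),   # exactly on every threshold: kept
    mkHH("E", "F", 49.9, 0.9, 0.9),   # below probability
    mkHH("G", "H", 80, 0.59, 0.9),    # below query coverage
    mkHH("I", "I", 99, 0.9, 0.9))     # self-hit
  out <- filterHits(hits, networkConfig())
  expect_equal(out$query, c("A", "C"))
  # results preset raises the probability floor to 90
  out90 <- filterHits(hits, networkConfig(preset = "results"))
  expect_equal(out90$query, "A")
})

test_that("raising the probability floor never adds edges", {
  set.seed(31)
  hits <- randomHomologyHits(300)
  n <- vapply(seq(0, 100, 10), function(p)
    nrow(filterHits(hits, networkConfig(minProbability = p))), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("score normalization divides by alignment length", {
  h <- mkHH("A", "B", 90)
  h$score <- 120; h$alnlen <- 60
  expect_equal(normalizeScore(h)$norm_score, 2)
  h$score <- 0
  expect_equal(normalizeScore(h)$norm_score, 0)
  h$alnlen <- 0
  expect_error(normalizeScore(h), "alnlen")
})

test_that("deduplication keeps the best hit per unordered pair", {
  h1 <- mkHH("A", "B", 90); h1$score <- 120; h1$alnlen <- 60   # 2.0
  h2 <- mkHH("B", "A", 95); h2$score <- 102; h2$alnlen <- 60   # 1.7
  out <- deduplicateHits(normalizeScore(rbind(h1, h2)))
  expect_equal(nrow(out), 1L)
  expect_equal(out$norm_score, 2.0)
  # idempotent
  expect_equal(deduplicateHits(out), out)
})

test_that("deduplication equals the exhaustive per-pair oracle", {
  set.seed(41)
  for (i in 1:20) {
    hits <- normalizeScore(randomHomologyHits(60, nOgs = 8))
    got <- deduplicateHits(hits)
    want <- oracleDedup(hits)
    ord <- function(x) {
      k <- paste(pmin(x$query, x$target), pmax(x$query, x$target))
      x <- x[order(k), c("query", "target", "norm_score", "probability")]
      rownames(x) <- NULL
      x
    }
    expect_equal(ord(got), ord(want))
    # row order of the input must not matter
    shuffled <- hits[sample.int(nrow(hits)), ]
    expect_equal(ord(deduplicateHits(shuffled)), ord(got))
  }
})

test_that("graph construction and component statistics", {
  edges <- normalizeScore(rbind(mkHH("A", "B", 90), mkHH("B", "C", 90),
                                mkHH("D", "E", 90)))
  g <- buildHomologyGraph(edges)
  s <- componentStats(g)
  expect_equal(s$n_components, 2L)
  expect_equal(s$largest_component_size, 3L)
  # a supplied node universe keeps isolated nodes
  attrs <- data.frame(og_id = c("A", "B", "C", "D", "E", "lonely"),
                      darkness = c("dark", "dark", "light", "dark",
                                   "light", "dark"),
                      lca_rank = c("species", "tax_id", "phylum",
                                   "species", "class", "species"))
  g2 <- buildHomologyGraph(edges, attrs)
  expect_equal(componentStats(g2)$n_nodes, 6L)
  expect_equal(componentStats(g2)$n_components, 3L)
  # an edge outside the universe is an error
  expect_error(buildHomologyGraph(edges, attrs[1:3, ]), "outside")
})

test_that("components match a BFS oracle on random graphs", {
  set.seed(51)
  for (i in 1:50) {
    nodes <- sprintf("n%02d", 1:sample(5:25, 1))
    ne <- sample(0:30, 1)
    edges <- data.frame(
      from = sample(nodes, ne, replace = TRUE),
      to = sample(nodes, ne, replace = TRUE))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    hh <- if (nrow(edges)) normalizeScore(mkHH(edges$from, edges$to, 90))
      else normalizeScore(mkHH("x", "y", 90))[0, ]
    g <- buildHomologyGraph(hh, data.frame(og_id = nodes))
    memb <- componentMembership(g)
    oracle <- bfsComponents(nodes, edges)
    # same partition: co-membership must agree pairwise
    gk <- setNames(memb$component_id, memb$og_id)
    for (j in 1:20) {
      p <- sample(nodes, 2)
      expect_equal(gk[[p[1]]] == gk[[p[2]]],
                   oracle[[p[1]]] == oracle[[p[2]]])
    }
    # sum of component sizes equals node count
    expect_equal(sum(table(memb$component_id)), length(nodes))
  }
})

test_that("attribute mixing and burst summary describe components", {
  edges <- normalizeScore(rbind(mkHH("hub", "s1", 95), mkHH("hub", "s2", 95),
                                mkHH("hub", "s3", 95)))
  attrs <- data.frame(og_id = c("hub", "s1", "s2", "s3"),
                      darkness = c("light", "dark", "dark", "dark"),
                      lca_rank = c("phylum", "species", "tax_id",
                                   "species"))
  g <- buildHomologyGraph(edges, attrs)
  mix <- attributeMixing(g)
  dark1 <- mix[mix$attribute == "darkness" & mix$value == "dark", ]
  expect_equal(dark1$n, 3L)
  expect_equal(burstSummary(g), 3L)
  expect_error(attributeMixing(buildHomologyGraph(edges)), "attributes")
})

test_that("GraphML export writes a readable file", {
  g <- buildHomologyGraph(normalizeScore(mkHH("A", "B", 90)))
  path <- tempfile(fileext = ".graphml")
  writeGraphML(g, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
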