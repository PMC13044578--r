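#' Remote-homology network filter configuration
#'
#' Thresholds for keeping HMM-HMM hits: probability (percent) and query /
#' subject coverage, all inclusive (`>=`). Two presets reflect the two
#' thresholds used for the same corpus: `"methods"` keeps probability >= 50,
#' `"results"` keeps probability >= 90; coverage is >= 60% in both.
#'
#' @param minProbability percent, default 50.
#' @param minQCov,minSCov coverage fractions in [0, 1], default 0.6.
#' @param dropSelf remove self-hits (query OG == target OG), default TRUE.
#' @param preset `"methods"` or `"results"`; overrides `minProbability`.
#' @return list of class `NetworkConfig`.
#' @export
networkConfig <- function(minProbability = 50, minQCov = 0.6,
                          minSCov = 0.6, dropSelf = TRUE, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("methods", "results"))
    minProbability <- if (preset == "methods") 50 else 90
  }
  if (minProbability < 0 || minProbability > 100)
    stop("minProbability must be in [0, 100]")
  if (any(c(minQCov, minSCov) < 0) || any(c(minQCov, minSCov) > 1))
    stop("coverages must be in [0, 1]")
  structure(list(minProbability = minProbability, minQCov = minQCov,
                 minSCov = minSCov, dropSelf = dropSelf),
            class = "NetworkConfig")
}

#' Filter HMM-HMM hits on probability and coverage
#'
#' Coverage is computed from the 1-based inclusive alignment columns:
#' `q_cov = (qend - qstart + 1) / qlen`, likewise for the target. All
#' thresholds are inclusive.
#'
#' @param hits data.frame as returned by [readHomologyHits()].
#' @param cfg a [networkConfig()].
#' @return filtered hits data.frame.
#' @export
filterHits <- function(hits, cfg = networkConfig()) {
  qcov <- (hits$qend - hits$qstart + 1) / hits$qlen
  scov <- (hits$tend - hits$tstart + 1) / hits$tlen
  keep <- hits$probability >= cfg$minProbability &
    qcov >= cfg$minQCov & scov >= cfg$minSCov
  if (cfg$dropSelf) keep <- keep & hits$query != hits$target
  hits[keep, , drop = FALSE]
}

#' Length-normalized alignment score
#'
#' @param hits hits data.frame with `score` and `alnlen` columns.
#' @return `hits` with a `norm_score` column (`score / alnlen`).
#' @export
normalizeScore <- function(hits) {
  if (any(hits$alnlen < 1)) stop("alnlen must be >= 1")
  hits$norm_score <- hits$score / hits$alnlen
  hits
}

#' Deduplicate hits to one edge per unordered OG pair
#'
#' For each unordered pair (including the reciprocal query/target
#' redundancy), keeps the single hit with the maximal length-normalized
#' score; ties break by higher probability, then lexicographic query id.
#' Idempotent and independent of input row order.
#'
#' @param hits filtered hits with a `norm_score` column
#'   (see [normalizeScore()]).
#' @return deduplicated hits data.frame.
#' @export
deduplicateHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  a <- pmin(hits$query, hits$target)
  b <- pmax(hits$query, hits$target)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -hits$norm_score, -hits$probability, hits$query,
               hits$target)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the OG remote-homology graph
#'
#' Nodes are OGs, edges the deduplicated hits weighted by normalized score.
#' When `nodeAttrs` is supplied its `og_id` column defines the node
#' universe: OGs with no surviving edges are kept as isolated nodes, and an
#' edge referencing an OG outside the universe is an error.
#'
#' @param edges deduplicated hits data.frame (see [deduplicateHits()]).
#' @param nodeAttrs optional data.frame keyed by `og_id` with node
#'   attributes (e.g. darkness, lca_rank, lca_taxon, expression flags).
#' @return a [HomologyGraph-class].
#' @export
buildHomologyGraph <- function(edges, nodeAttrs = NULL) {
  el <- data.frame(from = edges$query, to = edges$target,
                   weight = edges$norm_score,
                   probability = edges$probability,
                   stringsAsFactors = FALSE)
  if (!is.null(nodeAttrs)) {
    unknown <- setdiff(unique(c(el$from, el$to)), nodeAttrs$og_id)
    if (length(unknown))
      stop("edge references OG outside node universe: ", unknown[1])
    vertices <- nodeAttrs
    names(vertices)[names(vertices) == "og_id"] <- "name"
  } else {
    vertices <- NULL
    nodeAttrs <- data.frame(og_id = character())
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = vertices)
  new("HomologyGraph", graph = g, nodeAttrs = nodeAttrs)
}

#' Component statistics of a homology graph
#'
#' @param g a [HomologyGraph-class].
#' @return one-row data.frame: `n_nodes`, `n_edges`, `n_components`,
#'   `largest_component_size`.
#' @export
componentStats <- function(g) {
  comp <- igraph::components(g@graph)
  data.frame(n_nodes = igraph::vcount(g@graph),
             n_edges = igraph::ecount(g@graph),
             n_components = comp$no,
             largest_component_size =
               if (comp$no) max(comp$csize) else 0L)
}

#' Component membership of every node
#'
#' @param g a [HomologyGraph-class].
#' @return data.frame: `og_id`, `component_id`.
#' @export
componentMembership <- function(g) {
  comp <- igraph::components(g@graph)
  data.frame(og_id = igraph::V(g@graph)$name,
             component_id = unname(comp$membership),
             stringsAsFactors = FALSE)
}

#' Per-component node-attribute tallies
#'
#' Counts, for each connected component and each requested attribute, how
#' many member nodes carry each value — the summaries behind "burst"
#' interpretation (e.g. many narrow-LCA dark OGs in one component with a few
#' broad-LCA light OGs).
#'
#' @param g a [HomologyGraph-class] built with node attributes.
#' @param attributes attribute column names from the node table.
#' @return data.frame: `component_id`, `attribute`, `value`, `n`.
#' @export
attributeMixing <- function(g, attributes = c("darkness", "lca_rank")) {
  if (nrow(g@nodeAttrs) == 0L) stop("graph was built without node attributes")
  memb <- componentMembership(g)
  attrs <- g@nodeAttrs[match(memb$og_id, g@nodeAttrs$og_id), , drop = FALSE]
  out <- lapply(attributes, function(a) {
    if (!a %in% names(attrs)) stop("unknown attribute: ", a)
    t <- as.data.frame(table(component_id = memb$component_id,
                             value = attrs[[a]]))
    t <- t[t$Freq > 0, ]
    data.frame(component_id = as.integer(as.character(t$component_id)),
               attribute = a, value = as.character(t$value), n = t$Freq,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count narrow-LCA dark OGs adjacent to broad-LCA light OGs
#'
#' The hub-and-burst signature: dark OGs assigned to a narrow taxonomic
#' level that are directly connected to at least one light OG assigned to a
#' broad level.
#'
#' @param g a [HomologyGraph-class] with `darkness` and `lca_rank` node
#'   attributes.
#' @param narrowRanks ranks counted as narrow (default tax_id/isolate/
#'   species).
#' @param broadRanks ranks counted as broad (default class and above).
#' @return integer count of such dark OGs.
#' @export
burstSummary <- function(g,
                         narrowRanks = c("tax_id", "isolate", "species"),
                         broadRanks = c("class", "subphylum", "phylum",
                                        "clade1", "kingdom", "clade",
                                        "superkingdom", "no rank", "root")) {
  na <- g@nodeAttrs
  if (!all(c("darkness", "lca_rank") %in% names(na)))
    stop("needs darkness and lca_rank node attributes")
  nm <- igraph::V(g@graph)$name
  att <- na[match(nm, na$og_id), ]
  isNarrowDark <- att$darkness == "dark" & att$lca_rank %in% narrowRanks
  isBroadLight <- att$darkness == "light" & att$lca_rank %in% broadRanks
  adj <- igraph::adjacent_vertices(g@graph, which(isNarrowDark))
  sum(vapply(adj, function(v) any(isBroadLight[as.integer(v)]), logical(1)))
}

#' Export a homology graph as GraphML
#'
#' @param g a [HomologyGraph-class].
#' @param path output file path.
#' @export
writeGraphML <- function(g, path) {
  igraph::write_graph(g@graph, path, format = "graphml")
  invisible(path)
}
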