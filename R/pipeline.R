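#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold as a named, defaulted
#' parameter: the default profile is the standard recipe (darkness e-value
#' 1e-5; conserved coverage 0.5; HDF classes 0.05/0.95 with a 0.5 call
#' majority; DEG |log2FC| > 0.5 and padj < 0.05; single-cell FC > 2.0;
#' low-expression filter count > 10 in > 10% of samples; network
#' probability >= 50 and coverage >= 0.6). All referenced files must exist.
#'
#' @param paths named list of input files: `orthogroups`, `lineages`,
#'   `tree`, `annotation_hits`, `bitscore_obs`, `representatives`,
#'   `db_lengths`, `de`, `sc`, `rbh_ab`, `rbh_ba`, `intensities`, `design`,
#'   `hh_hits` (a `SimPaths` object from [simulateAll()] works directly).
#' @param eValueCutoff darkness e-value cutoff.
#' @param minCoverage conserved-selection coverage threshold (inclusive).
#' @param eThreshold HDF detection e-value threshold (> 0).
#' @param networkPreset `"methods"` (probability >= 50) or `"results"`
#'   (>= 90).
#' @param rbhMinCov RBH coverage threshold (strict).
#' @param scFcCutoff single-cell FC threshold (strict).
#' @param seed seed for any stochastic step.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(paths, eValueCutoff = 1e-5, minCoverage = 0.5,
                           eThreshold = 1e-3, networkPreset = "methods",
                           rbhMinCov = 0.6, scFcCutoff = 2.0, seed = 1L) {
  need <- c("orthogroups", "lineages", "tree", "annotation_hits",
            "bitscore_obs", "representatives", "db_lengths", "de", "sc",
            "rbh_ab", "rbh_ba", "intensities", "design", "hh_hits")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stop("missing input paths: ", paste(miss, collapse = ", "))
  for (nm in need)
    if (!file.exists(paths[[nm]]))
      stop("input file does not exist: ", nm, " = ", paths[[nm]])
  structure(list(paths = paths[need], eValueCutoff = eValueCutoff,
                 minCoverage = minCoverage, eThreshold = eThreshold,
                 networkPreset = networkPreset, rbhMinCov = rbhMinCov,
                 scFcCutoff = scFcCutoff, seed = seed),
            class = "PipelineConfig")
}

.freadDf <- function(path, sep = "\t") {
  data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
}

#' Derived corpus ratios
#'
#' Arithmetic used in the pipeline report: per-category conserved counts sum
#' to the total; HDF supported/rejected percentages over the conserved
#' total (1 decimal place); annotated percentage over the total and
#' membrane-associated percentage over the annotated count (2 decimal
#' places).
#'
#' @param categoryCounts named integer vector of conserved-dark-OG counts
#'   per lineage category.
#' @param hdfSupported,hdfRejected OG-level HDF call counts.
#' @param nAnnotated number of conserved OGs with any domain/structure
#'   annotation (optional).
#' @param nMembrane number of annotated OGs flagged membrane associated
#'   (optional).
#' @return list of totals and percentages.
#' @export
darkOgRatios <- function(categoryCounts, hdfSupported, hdfRejected,
                         nAnnotated = NA_integer_,
                         nMembrane = NA_integer_) {
  total <- sum(categoryCounts)
  out <- list(
    total_conserved = total,
    pct_hdf_supported = round(100 * hdfSupported / total, 1),
    pct_hdf_rejected = round(100 * hdfRejected / total, 1))
  if (!is.na(nAnnotated)) {
    out$pct_annotated <- round(100 * nAnnotated / total, 2)
    if (!is.na(nMembrane)) {
      out$pct_membrane <- round(100 * nMembrane / nAnnotated, 2)
      out$pct_other <- round(100 * (nAnnotated - nMembrane) / nAnnotated, 2)
    }
  }
  out
}

.inLcaClade <- function(datasetIds, lineages, rank, taxon) {
  if (rank == "root") return(rep(TRUE, length(datasetIds)))
  v <- lineages[[rank]][match(datasetIds, lineages$dataset_id)]
  !is.na(v) & v == taxon
}

#' Run the full dark-orthogroup pipeline
#'
#' Executes classify, LCA assignment, conserved-dark selection, HDF
#' inference (on the conserved OGs), expression-bias statistics and the
#' remote-homology network, in order, and returns a machine-readable
#' report. Stage outputs are content-addressed by a hash of the
#' configuration: when `outDir` already holds a report for this exact
#' configuration it is reloaded instead of recomputed (`force = TRUE`
#' recomputes).
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory for the report (created if needed).
#' @param force recompute even when a cached report exists.
#' @return report list (invisibly written to
#'   `outDir/report-<hash>.json`).
#' @export
runPipeline <- function(config, outDir = tempfile("darkog-run"),
                        force = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config)
  cacheFile <- file.path(outDir, paste0("report-", hash, ".json"))
  if (file.exists(cacheFile) && !force) {
    rep <- jsonlite::read_json(cacheFile, simplifyVector = TRUE)
    rep$cached <- TRUE
    return(rep)
  }
  paths <- config$paths

  # stage: darkness classification
  ogs <- readOrthogroups(paths$orthogroups)
  lineages <- readLineages(paths$lineages)
  hits <- .freadDf(paths$annotation_hits)
  cfg <- darknessConfig(eValueCutoff = config$eValueCutoff)
  calls <- classifyProteins(ogs, hits, cfg)
  ogs <- classifyOrthogroups(ogs, calls)
  corpus <- darknessSummary(ogs, calls)

  # stage: LCA + conserved selection
  ogs <- assignLCAAll(ogs, lineages)
  groups <- groupsFromLineages(lineages)
  conserved <- selectConservedDark(ogs, groups, config$minCoverage)
  ogs <- markConserved(ogs, conserved)
  catCounts <- table(factor(conserved$category,
                            levels = c("Scleractinia", "Hexacorallia",
                                       "Cnidaria")))

  # stage: HDF inference over conserved dark OGs
  tree <- ape::read.tree(paths$tree)
  D <- patristicDistances(tree)
  obs <- .freadDf(paths$bitscore_obs)
  reps <- .freadDf(paths$representatives)
  dbl <- .freadDf(paths$db_lengths)
  dbLengths <- setNames(dbl$db_length, dbl$dataset_id)
  allDs <- lineages$dataset_id
  o <- ogTable(ogs)
  assessments <- list()
  for (id in conserved$og_id) {
    ro <- obs[obs$og_id == id, ]
    rr <- reps[reps$og_id == id, ]
    if (!nrow(rr)) next
    repDs <- rr$dataset_id[1]
    if (!"distance" %in% names(ro) || anyNA(ro$distance))
      ro$distance <- D[repDs, ro$dataset_id]
    absentDs <- setdiff(allDs, ro$dataset_id)
    oi <- match(id, o$og_id)
    absent <- data.frame(
      dataset_id = absentDs,
      distance = D[repDs, absentDs],
      in_lca = .inLcaClade(absentDs, lineages, o$lca_rank[oi],
                           o$lca_taxon[oi]),
      stringsAsFactors = FALSE)
    a <- hdfAssessOg(id, ro, absent, rr$rep_length[1], dbLengths,
                     config$eThreshold)
    if (!is.null(a)) assessments[[id]] <- a
  }
  hdfSum <- hdfCallSummary(assessments)
  ratios <- darkOgRatios(
    as.integer(catCounts), hdfSum$n_supported, hdfSum$n_rejected)

  # stage: expression bias
  m <- ogMembers(ogs)
  geneGroup <- setNames(
    o$darkness[match(m$og_id, o$og_id)], m$protein_id)
  de <- callDegs(.freadDf(paths$de))
  deSig <- de[de$significant, c("gene_id", "comparison")]
  names(deSig) <- c("gene_id", "unit")
  deBias <- proportionBias(deSig, geneGroup)

  idMap <- mapIdsRBH(.freadDf(paths$rbh_ab), .freadDf(paths$rbh_ba),
                     minCov = config$rbhMinCov)
  sc <- .freadDf(paths$sc)
  sc$gene_id <- idMap$id_b[match(sc$gene_id, idMap$id_a)]
  sc <- sc[!is.na(sc$gene_id), ]
  sc <- callCellTypeExpression(sc, config$scFcCutoff)
  scBias <- lapply(split(sc, sc$granularity), function(x) {
    s <- x[x$significant, c("gene_id", "cell_type")]
    names(s) <- c("gene_id", "unit")
    if (!nrow(s)) return(NULL)
    proportionBias(s, geneGroup)
  })

  intens <- .freadDf(paths$intensities)
  mat <- as.matrix(intens[, -1, drop = FALSE])
  rownames(mat) <- intens[[1]]
  design <- .freadDf(paths$design, sep = ",")
  protCalls <- callDifferentialProteins(mat, design)

  # stage: remote-homology network
  hh <- readHomologyHits(paths$hh_hits)
  net <- deduplicateHits(normalizeScore(
    filterHits(hh, networkConfig(preset = config$networkPreset))))
  graph <- buildHomologyGraph(net)
  netStats <- componentStats(graph)

  report <- list(
    config_hash = hash,
    cached = FALSE,
    corpus = as.list(corpus),
    conserved = list(
      by_category = as.list(setNames(as.integer(catCounts),
                                     names(catCounts))),
      total = sum(catCounts)),
    hdf = c(as.list(hdfSum), ratios[c("pct_hdf_supported",
                                      "pct_hdf_rejected")],
            list(calls = data.frame(
              og_id = names(assessments),
              call = vapply(assessments, function(a) a@call, ""),
              row.names = NULL, stringsAsFactors = FALSE))),
    expression = list(
      de_delta = deBias$delta,
      sc_delta = lapply(scBias, function(b) if (is.null(b)) NULL
                        else b$delta),
      n_diff_proteins = sum(protCalls$significant)),
    network = as.list(netStats))
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", null = "null")
  writeLines(json, cacheFile)
  writeLines(json, file.path(outDir, "report.json"))
  report
}

#' One-paragraph human-readable report summary
#'
#' @param report list returned by [runPipeline()].
#' @return character scalar (also printed).
#' @export
reportSummary <- function(report) {
  txt <- sprintf(paste0(
    "Corpus: %d proteins (%.1f%% dark), %d OGs (%d dark). ",
    "Conserved dark OGs: %d (Scleractinia %d / Hexacorallia %d / ",
    "Cnidaria %d). HDF: %d assessed, %s%% supported, %s%% rejected. ",
    "Network: %d nodes, %d edges, %d components (largest %d)."),
    report$corpus$n_proteins, 100 * report$corpus$fraction_dark,
    report$corpus$n_ogs, report$corpus$n_dark_ogs,
    report$conserved$total,
    report$conserved$by_category$Scleractinia,
    report$conserved$by_category$Hexacorallia,
    report$conserved$by_category$Cnidaria,
    report$hdf$n_assessed, report$hdf$pct_hdf_supported,
    report$hdf$pct_hdf_rejected,
    report$network$n_nodes, report$network$n_edges,
    report$network$n_components, report$network$largest_component_size)
  cat(txt, "\n")
  invisible(txt)
}
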