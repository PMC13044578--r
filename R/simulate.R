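#' Synthetic-corpus configuration
#'
#' Defines the study conditions the generator emulates: a nested corpus of
#' datasets (Scleractinia within Hexacorallia within Cnidaria, plus
#' outgroups) on an ultrametric species tree, gene families with planted
#' darkness, origin clades and exponential bitscore decay, planted cell-type
#' enrichment of dark genes, and a hub-and-burst remote-homology network.
#' A single integer seed drives per-module substreams so every stage can be
#' regenerated independently and byte-identically.
#'
#' @param seed integer master seed.
#' @param nScleractinia,nHexaOther,nCnidariaOther,nOutgroup dataset counts
#'   (Scleractinia is split evenly into Complex and Robust suborders).
#' @param nFamilies number of gene families.
#' @param darkFraction planted fraction of dark families.
#' @param fastFraction fraction of families in the fast-evolving regime.
#' @param aRange range of the distance-zero bitscore `a`.
#' @param bFast,bSlow decay-rate ranges for the two regimes
#'   (substitutions/site^-1).
#' @param bitscoreSd Gaussian bitscore noise (bits).
#' @param lossProb per-branch gene-loss probability.
#' @param originProbs named probabilities for the family origin clade
#'   (`dataset`, `Scleractinia`, `Hexacorallia`, `Cnidaria`, `root`).
#' @param paralogRate Poisson rate of extra paralogs per present dataset.
#' @param meanLength,sdLength protein length distribution (residues).
#' @param enrichment list: `cellTypes`, `granularities`, `pDark`/`pLight`
#'   (named per-cell-type probabilities of FC > 2, with a `default`),
#'   `deComparisons`, `pDeDark`, `pDeLight`.
#' @param network list: `nHubs`, `satellitesPerHub`, `nDecoys`.
#' @param proteome list: `nProteins`, `nReps`, `shiftProbDark`,
#'   `shiftProbLight`.
#' @param eThreshold homology-search e-value threshold emulated.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(
    seed = 1L,
    nScleractinia = 16L, nHexaOther = 12L, nCnidariaOther = 8L,
    nOutgroup = 4L,
    nFamilies = 2000L,
    darkFraction = 0.25,
    fastFraction = 0.5,
    aRange = c(150, 400),
    bFast = c(1.2, 2.5),
    bSlow = c(0.05, 0.3),
    bitscoreSd = 10,
    lossProb = 0.12,
    originProbs = c(dataset = 0.35, Scleractinia = 0.25,
                    Hexacorallia = 0.15, Cnidaria = 0.15, root = 0.10),
    paralogRate = 0.3,
    meanLength = 300, sdLength = 60,
    enrichment = list(
      cellTypes = c("calicoblast", "gastrodermis", "epidermis",
                    "neuron", "cnidocyte"),
      granularities = c("broadcell", "cell", "metacell"),
      pDark = c(calicoblast = 0.4, default = 0.15),
      pLight = c(calicoblast = 0.1, default = 0.15),
      deComparisons = c("heat_vs_ambient_TP1", "heat_vs_ambient_TP2",
                        "lowpH_vs_ambient_TP1", "lowpH_vs_ambient_TP2"),
      pDeDark = 0.15, pDeLight = 0.25),
    network = list(nHubs = 3L, satellitesPerHub = 10L, nDecoys = 30L),
    proteome = list(nProteins = 300L, nReps = 3L,
                    shiftProbDark = 0.2, shiftProbLight = 0.2),
    eThreshold = 1e-3) {
  probs <- c(darkFraction, fastFraction, lossProb, originProbs,
             enrichment$pDark, enrichment$pLight,
             enrichment$pDeDark, enrichment$pDeLight)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (nScleractinia < 2L || nHexaOther < 2L || nCnidariaOther < 2L ||
      nOutgroup < 2L)
    stop("need at least 2 datasets per lineage group")
  if (abs(sum(originProbs) - 1) > 1e-8)
    stop("originProbs must sum to 1")
  structure(as.list(environment()), class = "SimConfig")
}

# deterministic per-module substream seed derived from the master seed
.substreamSeed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) %% 1e6 * 7919 + h * 104729) %% 2147483629)
}

# random ultrametric clade of given tip-depth as a newick fragment
.scaledClade <- function(tips, height) {
  if (length(tips) == 1L) return(sprintf("%s:%g", tips, height))
  t <- ape::rcoal(length(tips), tip.label = tips)
  depth <- max(ape::branching.times(t))
  t$edge.length <- t$edge.length * height / depth
  sub("; *$", "", ape::write.tree(t))
}

#' Simulate the dataset corpus: taxonomy lineages and species tree
#'
#' Builds an ultrametric species tree with nested monophyletic groups
#' (Complex and Robust suborders within Scleractinia, Scleractinia within
#' Hexacorallia within Cnidaria, plus outgroups) and the matching lineage
#' table over the default rank ladder. Branch lengths are in
#' substitutions/site; crown depths are 0.5 (Scleractinia), 1.0
#' (Hexacorallia), 1.5 (Cnidaria) and 2.2 (root).
#'
#' @param cfg a [simConfig()].
#' @return list: `lineages` (data.frame as from [readLineages()]), `tree`
#'   (`ape::phylo`), `newick` (string).
#' @export
simulateTaxonomyAndTree <- function(cfg) {
  set.seed(.substreamSeed(cfg$seed, "tree"))
  nC <- cfg$nScleractinia %/% 2L
  nR <- cfg$nScleractinia - nC
  complexTips <- sprintf("scler_C%02d", seq_len(nC))
  robustTips <- sprintf("scler_R%02d", seq_len(nR))
  hexaTips <- sprintf("hexa_%02d", seq_len(cfg$nHexaOther))
  cnidTips <- sprintf("cnid_%02d", seq_len(cfg$nCnidariaOther))
  outTips <- sprintf("outg_%02d", seq_len(cfg$nOutgroup))

  scler <- sprintf("(%s:0.2,%s:0.2)",
                   .scaledClade(complexTips, 0.3),
                   .scaledClade(robustTips, 0.3))
  hexa <- sprintf("(%s:0.5,%s:0.3)", scler, .scaledClade(hexaTips, 0.7))
  cnid <- sprintf("(%s:0.5,%s:0.3)", hexa, .scaledClade(cnidTips, 1.2))
  nw <- sprintf("(%s:0.7,%s:0.4);", cnid, .scaledClade(outTips, 1.8))
  tree <- ape::read.tree(text = nw)

  ds <- c(complexTips, robustTips, hexaTips, cnidTips, outTips)
  n <- length(ds)
  grp <- rep(c("complex", "robust", "hexa", "cnid", "outg"),
             c(nC, nR, cfg$nHexaOther, cfg$nCnidariaOther, cfg$nOutgroup))
  outPhyla <- rep(c("Porifera", "Placozoa", "Ctenophora", "Chordata"),
                  length.out = cfg$nOutgroup)
  lineages <- data.frame(
    dataset_id = ds,
    source_kind = sample(c("genome", "transcriptome"), n, replace = TRUE),
    tax_id = as.character(1000L + seq_len(n)),
    isolate = NA_character_,
    species = paste0("sp_", ds),
    genus = paste0("gen_", ds),
    family = paste0("fam_", ds),
    suborder = ifelse(grp == "complex", "Complex",
                      ifelse(grp == "robust", "Robust", NA_character_)),
    order = ifelse(grp %in% c("complex", "robust"), "Scleractinia",
                   ifelse(grp == "hexa", "Actiniaria",
                          ifelse(grp == "cnid", "Anthoathecata",
                                 paste0("ord_", ds)))),
    class = ifelse(grp %in% c("complex", "robust", "hexa"), "Hexacorallia",
                   ifelse(grp == "cnid", "Hydrozoa", paste0("cls_", ds))),
    subphylum = NA_character_,
    phylum = ifelse(grp == "outg", outPhyla[match(ds, outTips)], "Cnidaria"),
    clade1 = NA_character_,
    kingdom = "Metazoa",
    clade = "Opisthokonta",
    superkingdom = "Eukaryota",
    stringsAsFactors = FALSE, check.names = FALSE)
  lineages[["no rank"]] <- "cellular organisms"
  list(lineages = lineages, tree = tree, newick = nw)
}

# per-edge descendant tip labels of a subtree
.edgeDescendants <- function(tree) {
  ntip <- length(tree$tip.label)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    child <- tree$edge[i, 2]
    if (child <= ntip) tree$tip.label[child]
    else {
      keep <- ape::extract.clade(tree, child)$tip.label
      keep
    }
  })
}

.AMBIGUOUS_POOL <- c("hypothetical protein", "Hypothetical protein",
                     "uncharacterized protein", "Uncharacterized Protein",
                     "PREDICTED protein", "predicted protein",
                     "expressed protein", "unnamed protein product")
.INFORMATIVE_POOL <- c("calmodulin-like protein", "EF-hand domain protein",
                       "green fluorescent protein", "collagen alpha chain",
                       "carbonic anhydrase 2", "galaxin-like protein",
                       "heat shock protein 70", "toxin-like peptide",
                       "von Willebrand factor type A domain protein",
                       "C-type lectin receptor")

#' Simulate gene families with planted ground truth
#'
#' Each family draws an origin clade, suffers per-branch gene loss inside
#' it, gets a planted darkness label (driving hit descriptions
#' deterministically: dark families receive only ambiguous or above-cutoff
#' descriptions), a decay regime with parameters `(a, b)`, and best
#' bitscores `B = a exp(-b d) + N(0, sd^2)` (truncated just above 0)
#' between the representative's dataset and every member dataset.
#'
#' @param cfg a [simConfig()].
#' @param tax output of [simulateTaxonomyAndTree()].
#' @return list: `members` (og/dataset/protein/length data.frame),
#'   `annotationHits`, `bitscoreObs`, `truth` (per-family ground truth),
#'   `reps` (og_id, representative protein, dataset, length),
#'   `dbLengths` (dataset_id, db_length).
#' @export
simulateFamilies <- function(cfg, tax) {
  set.seed(.substreamSeed(cfg$seed, "families"))
  allDs <- tax$lineages$dataset_id
  scler <- grep("^scler_", allDs, value = TRUE)
  hexa <- c(scler, grep("^hexa_", allDs, value = TRUE))
  cnid <- c(hexa, grep("^cnid_", allDs, value = TRUE))
  clades <- list(Scleractinia = scler, Hexacorallia = hexa,
                 Cnidaria = cnid, root = allDs)
  subtrees <- lapply(clades, function(tp) ape::keep.tip(tax$tree, tp))
  edgeDesc <- lapply(subtrees, .edgeDescendants)
  D <- patristicDistances(tax$tree)

  origins <- sample(names(cfg$originProbs), cfg$nFamilies, replace = TRUE,
                    prob = cfg$originProbs)
  dark <- runif(cfg$nFamilies) < cfg$darkFraction
  fast <- runif(cfg$nFamilies) < cfg$fastFraction
  a <- runif(cfg$nFamilies, cfg$aRange[1], cfg$aRange[2])
  b <- ifelse(fast, runif(cfg$nFamilies, cfg$bFast[1], cfg$bFast[2]),
              runif(cfg$nFamilies, cfg$bSlow[1], cfg$bSlow[2]))

  mem <- vector("list", cfg$nFamilies)
  obs <- vector("list", cfg$nFamilies)
  reps <- vector("list", cfg$nFamilies)
  nds <- integer(cfg$nFamilies)
  repds <- character(cfg$nFamilies)
  for (f in seq_len(cfg$nFamilies)) {
    og <- sprintf("OG%06d", f)
    if (origins[f] == "dataset") {
      members <- sample(allDs, 1L)
    } else {
      tips <- clades[[origins[f]]]
      desc <- edgeDesc[[origins[f]]]
      lost <- runif(length(desc)) < cfg$lossProb
      absent <- unique(unlist(desc[lost]))
      members <- setdiff(tips, absent)
      if (!length(members)) members <- sample(tips, 1L)
    }
    nds[f] <- length(members)
    repds[f] <- if (length(members) == 1L) members else sample(members, 1L)
    npar <- 1L + rpois(length(members), cfg$paralogRate)
    dsv <- rep(members, npar)
    prot <- paste0("g", sprintf("%06d", f), ".",
                   unlist(lapply(npar, seq_len)))
    len <- pmax(50L, round(rnorm(length(dsv), cfg$meanLength,
                                 cfg$sdLength)))
    mem[[f]] <- data.frame(og_id = og, dataset_id = dsv, protein_id = prot,
                           length = len, stringsAsFactors = FALSE)
    d <- D[repds[f], members]
    B <- a[f] * exp(-b[f] * d) + rnorm(length(members), 0, cfg$bitscoreSd)
    obs[[f]] <- data.frame(og_id = og, dataset_id = members,
                           distance = unname(d),
                           bitscore = pmax(unname(B), 0.5),
                           stringsAsFactors = FALSE)
    ri <- which(dsv == repds[f])[1]
    reps[[f]] <- data.frame(og_id = og, protein_id = prot[ri],
                            dataset_id = repds[f], rep_length = len[ri],
                            stringsAsFactors = FALSE)
  }
  members <- data.table::rbindlist(mem)
  bitscoreObs <- as.data.frame(data.table::rbindlist(obs))
  reps <- as.data.frame(data.table::rbindlist(reps))
  truth <- data.frame(
    og_id = sprintf("OG%06d", seq_len(cfg$nFamilies)),
    darkness = ifelse(dark, "dark", "light"),
    origin = origins, regime = ifelse(fast, "fast", "slow"),
    a = a, b = b, rep_dataset = repds, n_datasets = nds,
    stringsAsFactors = FALSE)

  # annotation hits, vectorized over the full protein table
  pm <- as.data.frame(members)
  fidx <- as.integer(sub("^OG", "", pm$og_id))
  pdark <- dark[fidx]
  noHit <- pdark & runif(nrow(pm)) < 0.2   # some dark proteins hit nothing
  base <- pm[!noHit, ]
  bdark <- pdark[!noHit]
  h1 <- data.frame(
    dataset_id = base$dataset_id, protein_id = base$protein_id,
    subject_id = sprintf("nr|%07d", sample.int(9999999, nrow(base), TRUE)),
    e_value = 10^runif(nrow(base), -30, -6),
    bitscore = round(runif(nrow(base), 60, 500), 1),
    description = ifelse(
      bdark,
      paste(sample(.AMBIGUOUS_POOL, nrow(base), TRUE),
            sprintf("LOC%05d", sample.int(99999, nrow(base), TRUE))),
      sample(.INFORMATIVE_POOL, nrow(base), TRUE)),
    stringsAsFactors = FALSE)
  # decoy informative hits above the e-value cutoff for some dark proteins
  dk <- base[bdark & runif(nrow(base)) < 0.3, ]
  h2 <- if (nrow(dk)) data.frame(
    dataset_id = dk$dataset_id, protein_id = dk$protein_id,
    subject_id = sprintf("nr|%07d", sample.int(9999999, nrow(dk), TRUE)),
    e_value = 10^runif(nrow(dk), -4, -1),
    bitscore = round(runif(nrow(dk), 30, 60), 1),
    description = sample(.INFORMATIVE_POOL, nrow(dk), TRUE),
    stringsAsFactors = FALSE) else NULL
  # extra ambiguous hits on some light proteins
  lt <- base[!bdark & runif(nrow(base)) < 0.3, ]
  h3 <- if (nrow(lt)) data.frame(
    dataset_id = lt$dataset_id, protein_id = lt$protein_id,
    subject_id = sprintf("nr|%07d", sample.int(9999999, nrow(lt), TRUE)),
    e_value = 10^runif(nrow(lt), -20, -6),
    bitscore = round(runif(nrow(lt), 60, 300), 1),
    description = paste(sample(.AMBIGUOUS_POOL, nrow(lt), TRUE),
                        sprintf("LOC%05d", sample.int(99999, nrow(lt),
                                                      TRUE))),
    stringsAsFactors = FALSE) else NULL
  annotationHits <- rbind(h1, h2, h3)
  rownames(annotationHits) <- NULL

  dbl <- tapply(pm$length, pm$dataset_id, sum)
  dbLengths <- data.frame(dataset_id = names(dbl),
                          db_length = unname(dbl) + 500000,
                          stringsAsFactors = FALSE)
  list(members = pm, annotationHits = annotationHits,
       bitscoreObs = bitscoreObs, truth = truth, reps = reps,
       dbLengths = dbLengths)
}

.enrichP <- function(spec, cellType) {
  if (cellType %in% names(spec)) spec[[cellType]] else spec[["default"]]
}

#' Simulate expression evidence with planted dark-gene enrichment
#'
#' Uses the focal dataset (first Complex Scleractinia dataset) as the
#' species with expression data. Per-unit significance is Bernoulli with
#' group-specific probabilities; single-cell tables are emitted under old
#' gene ids together with reciprocal-best-hit tables mapping them to the
#' current ids; proteomic intensities are log-normal with planted treatment
#' shifts.
#'
#' @param cfg a [simConfig()].
#' @param fam output of [simulateFamilies()].
#' @return list: `genes` (gene_id, og_id, group), `de`, `sc`, `rbhAB`,
#'   `rbhBA`, `idMapTruth`, `intensities`, `design`.
#' @export
simulateExpression <- function(cfg, fam) {
  set.seed(.substreamSeed(cfg$seed, "expression"))
  focal <- "scler_C01"
  m <- fam$members[fam$members$dataset_id == focal, ]
  m <- m[!duplicated(m$og_id), ]  # one gene per family in the focal dataset
  grp <- fam$truth$darkness[match(m$og_id, fam$truth$og_id)]
  genes <- data.frame(gene_id = m$protein_id, og_id = m$og_id,
                      group = grp, length = m$length,
                      stringsAsFactors = FALSE)
  en <- cfg$enrichment
  ng <- nrow(genes)

  # bulk DE: one row per gene x comparison
  de <- do.call(rbind, lapply(en$deComparisons, function(cmp) {
    p <- ifelse(genes$group == "dark", en$pDeDark, en$pDeLight)
    sig <- runif(ng) < p
    lfc <- ifelse(sig, sample(c(-1, 1), ng, TRUE) * runif(ng, 0.6, 3),
                  runif(ng, -0.5, 0.5))
    padj <- ifelse(sig, runif(ng, 1e-8, 0.049), runif(ng, 0.05, 1))
    data.frame(gene_id = genes$gene_id, comparison = cmp,
               log2_fc = lfc, p_adj = padj, stringsAsFactors = FALSE)
  }))

  # single-cell FC under old ids
  oldIds <- paste0("old_", genes$gene_id)
  sc <- do.call(rbind, lapply(en$granularities, function(gr) {
    do.call(rbind, lapply(en$cellTypes, function(ct) {
      p <- ifelse(genes$group == "dark",
                  .enrichP(en$pDark, ct), .enrichP(en$pLight, ct))
      sig <- runif(ng) < p
      fc <- ifelse(sig, runif(ng, 2.05, 8), runif(ng, 0, 2))
      data.frame(gene_id = oldIds, granularity = gr, cell_type = ct,
                 fc = fc, stringsAsFactors = FALSE)
    }))
  }))

  # reciprocal best hits old <-> new, with sub-best decoys
  mkHits <- function(q, s, qlen, slen) {
    best <- data.frame(query = q, subject = s,
                       bitscore = round(runif(ng, 200, 400), 1),
                       qstart = 1L, qend = qlen, qlen = qlen,
                       sstart = 1L, send = slen, slen = slen,
                       stringsAsFactors = FALSE)
    dec <- runif(ng) < 0.2
    decoy <- best[dec, ]
    if (nrow(decoy)) {
      decoy$subject <- s[sample.int(ng, nrow(decoy))]
      decoy$bitscore <- decoy$bitscore - runif(nrow(decoy), 50, 150)
      decoy$send <- pmax(1L, round(decoy$slen * 0.4))
    }
    rbind(best, decoy)
  }
  rbhAB <- mkHits(oldIds, genes$gene_id, genes$length, genes$length)
  rbhBA <- mkHits(genes$gene_id, oldIds, genes$length, genes$length)

  # proteomic intensities
  pr <- cfg$proteome
  np <- min(pr$nProteins, ng)
  prot <- genes$gene_id[seq_len(np)]
  pgrp <- genes$group[seq_len(np)]
  tps <- c("TP1", "TP2")
  design <- expand.grid(rep = seq_len(pr$nReps),
                        arm = c("control", "treatment"), time_point = tps,
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_%d", design$time_point, design$arm,
                           design$rep)
  base <- rlnorm(np, meanlog = 10, sdlog = 0.5)
  shiftP <- ifelse(pgrp == "dark", pr$shiftProbDark, pr$shiftProbLight)
  intensities <- sapply(seq_len(nrow(design)), function(j) {
    base * rlnorm(np, 0, 0.08)
  })
  colnames(intensities) <- design$sample
  rownames(intensities) <- prot
  for (tp in tps) {
    shifted <- runif(np) < shiftP
    fcs <- ifelse(shifted,
                  2^(sample(c(-1, 1), np, TRUE) * runif(np, 0.8, 2)), 1)
    cols <- design$sample[design$arm == "treatment" &
                            design$time_point == tp]
    intensities[, cols] <- intensities[, cols] * fcs
  }
  list(genes = genes, de = de, sc = sc, rbhAB = rbhAB, rbhBA = rbhBA,
       idMapTruth = data.frame(old = oldIds, new = genes$gene_id,
                               stringsAsFactors = FALSE),
       intensities = intensities,
       design = design[c("sample", "arm", "time_point")])
}

#' Simulate a hub-and-burst remote-homology hit table
#'
#' Plants `nHubs` hub OGs (light, broad origin) each connected to
#' `satellitesPerHub` satellite OGs (dark, single-dataset origin) by hits
#' passing the network filter, plus redundant reciprocal hits, self-hits,
#' and decoy rows straddling the probability and coverage thresholds from
#' below. After filtering and deduplication the planted structure is exactly
#' `nHubs` components of `satellitesPerHub + 1` nodes.
#'
#' @param cfg a [simConfig()].
#' @param fam output of [simulateFamilies()].
#' @return list: `hits` (hhblits-style data.frame), `truth`
#'   (data.frame hub/satellite).
#' @export
simulateRemoteHomology <- function(cfg, fam) {
  set.seed(.substreamSeed(cfg$seed, "network"))
  nt <- cfg$network
  tr <- fam$truth
  hubPool <- tr$og_id[tr$darkness == "light" &
                        tr$origin %in% c("Cnidaria", "root")]
  satPool <- tr$og_id[tr$darkness == "dark" & tr$origin == "dataset"]
  nSat <- nt$nHubs * nt$satellitesPerHub
  if (length(hubPool) < nt$nHubs || length(satPool) < nSat)
    stop("not enough families to plant the network")
  hubs <- sample(hubPool, nt$nHubs)
  sats <- sample(satPool, nSat)
  hubOf <- rep(hubs, each = nt$satellitesPerHub)

  row <- function(q, t, prob, qfrac, tfrac, score) {
    qlen <- 200L; tlen <- 200L
    qend <- as.integer(round(qfrac * qlen)); tend <- as.integer(round(tfrac * tlen))
    data.frame(query = q, target = t, probability = prob,
               evalue = 1e-10, score = score,
               qstart = 1L, qend = qend, tstart = 1L, tend = tend,
               alnlen = pmax(qend, tend), qlen = qlen, tlen = tlen,
               stringsAsFactors = FALSE)
  }
  planted <- row(hubOf, sats,
                 prob = round(runif(nSat, 60, 99.9), 1),
                 qfrac = runif(nSat, 0.7, 1), tfrac = runif(nSat, 0.7, 1),
                 score = round(runif(nSat, 100, 300), 1))
  # one planted edge sits exactly on the inclusive thresholds
  planted$probability[1] <- 50.0
  planted$qend[1] <- 120L; planted$tend[1] <- 120L
  planted$alnlen[1] <- 120L
  # redundant reciprocal hits at lower normalized score
  rec <- runif(nSat) < 0.4
  recip <- planted[rec, ]
  if (nrow(recip)) {
    tmp <- recip$query; recip$query <- recip$target; recip$target <- tmp
    recip$score <- recip$score * 0.8
  }
  selfh <- row(hubs, hubs, prob = 99, qfrac = 1, tfrac = 1, score = 500)
  others <- setdiff(tr$og_id, c(hubs, sats))
  d1 <- sample(others, nt$nDecoys); d2 <- sample(others, nt$nDecoys)
  lowProb <- row(d1, d2, prob = round(runif(nt$nDecoys, 5, 49.9), 1),
                 qfrac = runif(nt$nDecoys, 0.7, 1),
                 tfrac = runif(nt$nDecoys, 0.7, 1),
                 score = round(runif(nt$nDecoys, 100, 300), 1))
  lowCov <- row(sample(others, nt$nDecoys), sample(others, nt$nDecoys),
                prob = round(runif(nt$nDecoys, 60, 99), 1),
                qfrac = runif(nt$nDecoys, 0.2, 0.55),
                tfrac = runif(nt$nDecoys, 0.2, 0.55),
                score = round(runif(nt$nDecoys, 100, 300), 1))
  hits <- rbind(planted, recip, selfh, lowProb, lowCov)
  hits <- hits[sample.int(nrow(hits)), ]
  rownames(hits) <- NULL
  list(hits = hits,
       truth = data.frame(hub = hubOf, satellite = sats,
                          stringsAsFactors = FALSE))
}

#' Write a complete synthetic input set to disk
#'
#' Runs every generator and serializes each pipeline input in its external
#' format (long-format orthogroup TSV, lineage CSV, newick tree, annotation
#' hit TSV, bitscore observation TSV, representative table, database
#' lengths, DE table, single-cell FC table, RBH hit tables, intensity
#' matrix, design CSV, hhblits-style hit TSV) plus truth tables.
#' Byte-identical for identical config and seed.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (class `SimPaths`), with the config in
#'   attribute `config`.
#' @export
simulateAll <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tax <- simulateTaxonomyAndTree(cfg)
  fam <- simulateFamilies(cfg, tax)
  expr <- simulateExpression(cfg, fam)
  net <- simulateRemoteHomology(cfg, fam)
  p <- function(f) file.path(dir, f)
  wt <- function(x, f, sep = "\t") {
    write.table(x, p(f), sep = sep, quote = FALSE, row.names = FALSE)
    p(f)
  }
  ogs <- OrthogroupSet(fam$members)
  paths <- list(
    orthogroups = writeOrthogroups(ogs, p("orthogroups.tsv")),
    lineages = wt(tax$lineages, "lineages.csv", sep = ","),
    tree = {
      writeLines(tax$newick, p("species_tree.nwk")); p("species_tree.nwk")
    },
    annotation_hits = wt(fam$annotationHits, "annotation_hits.tsv"),
    bitscore_obs = wt(fam$bitscoreObs, "bitscore_obs.tsv"),
    representatives = wt(fam$reps, "representatives.tsv"),
    db_lengths = wt(fam$dbLengths, "db_lengths.tsv"),
    de = wt(expr$de, "de_results.tsv"),
    sc = wt(expr$sc, "sc_fc.tsv"),
    rbh_ab = wt(expr$rbhAB, "rbh_ab.tsv"),
    rbh_ba = wt(expr$rbhBA, "rbh_ba.tsv"),
    intensities = wt(data.frame(protein_id = rownames(expr$intensities),
                                expr$intensities, check.names = FALSE),
                     "intensities.tsv"),
    design = wt(expr$design, "design.csv", sep = ","),
    hh_hits = wt(net$hits, "hh_hits.tsv"),
    truth_families = wt(fam$truth, "truth_families.tsv"),
    truth_genes = wt(expr$genes, "truth_genes.tsv"),
    truth_idmap = wt(expr$idMapTruth, "truth_idmap.tsv"),
    truth_network = wt(net$truth, "truth_network.tsv"))
  structure(paths, config = cfg, class = c("SimPaths", "list"))
}
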