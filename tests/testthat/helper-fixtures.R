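# small in-code fixtures shared across test files

tinyLineages <- function() {
  ld <- defaultRankLadder()
  mk <- function(dataset_id, tax_id, ...) {
    row <- setNames(as.list(rep(NA_character_, length(ld))), ld)
    row$tax_id <- tax_id
    vals <- list(...)
    row[names(vals)] <- vals
    cbind(data.frame(dataset_id = dataset_id, stringsAsFactors = FALSE),
          as.data.frame(row, check.names = FALSE, optional = TRUE))
  }
  out <- rbind(
    mk("coralA", "1", species = "sp_A", genus = "gA", family = "fA",
       suborder = "Robust", order = "Scleractinia", class = "Hexacorallia",
       phylum = "Cnidaria", kingdom = "Metazoa",
       superkingdom = "Eukaryota"),
    mk("coralB", "2", species = "sp_B", genus = "gB", family = "fB",
       suborder = "Complex", order = "Scleractinia", class = "Hexacorallia",
       phylum = "Cnidaria", kingdom = "Metazoa",
       superkingdom = "Eukaryota"),
    mk("anemone", "3", species = "sp_C", genus = "gC", family = "fC",
       order = "Actiniaria", class = "Hexacorallia", phylum = "Cnidaria",
       kingdom = "Metazoa", superkingdom = "Eukaryota"),
    mk("sponge", "4", species = "sp_D", genus = "gD", family = "fD",
       order = "ord_D", class = "cls_D", phylum = "Porifera",
       kingdom = "Metazoa", superkingdom = "Eukaryota"))
  names(out) <- c("dataset_id", ld)
  out[["no rank"]] <- "cellular organisms"
  out
}

# random taxonomy with missing values for LCA oracle property tests
randomTaxonomy <- function(nDatasets, ladder = defaultRankLadder()) {
  # build a random rooted hierarchy: each rank coarsens the previous one
  n <- nDatasets
  out <- data.frame(dataset_id = sprintf("ds%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  labels <- seq_len(n)  # tax_id level: all distinct
  for (r in ladder) {
    if (r == ladder[[1]]) {
      out[[r]] <- sprintf("%s_%d", r, labels)
      next
    }
    # merge random label pairs to coarsen
    k <- length(unique(labels))
    groups <- sample.int(max(1L, ceiling(k * runif(1, 0.3, 0.9))),
                         n, replace = TRUE)
    labels <- as.integer(interaction(groups, drop = TRUE))
    vals <- sprintf("%s_%d", r, labels)
    vals[runif(n) < 0.15] <- NA  # missing ranks
    out[[r]] <- vals
  }
  # last rank never missing so an LCA always exists below the sentinel
  out[[ladder[length(ladder)]]] <- "cellular organisms"
  out
}

sortBy <- function(m) {
  m <- m[order(m$og_id, m$dataset_id, m$protein_id),
         c("og_id", "dataset_id", "protein_id")]
  rownames(m) <- NULL
  m
}

writeTsv <- function(x, path = tempfile(fileext = ".tsv"), sep = "\t") {
  write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

smallSimConfig <- function(seed = 42, nFamilies = 400L, ...) {
  simConfig(seed = seed, nFamilies = nFamilies,
            nScleractinia = 8L, nHexaOther = 4L, nCnidariaOther = 4L,
            nOutgroup = 2L,
            network = list(nHubs = 2L, satellitesPerHub = 5L,
                           nDecoys = 10L), ...)
}

# BLAST-style hit row for RBH tests
mkHit <- function(q, s, bits, qfrac = 1, sfrac = 1, qlen = 100,
                  slen = 100) {
  data.frame(query = q, subject = s, bitscore = bits,
             qstart = 1L, qend = as.integer(round(qfrac * qlen)),
             qlen = qlen, sstart = 1L,
             send = as.integer(round(sfrac * slen)), slen = slen)
}

randomHomologyHits <- function(n, nOgs = 12) {
  og <- sprintf("OG%03d", seq_len(nOgs))
  qlen <- sample(100:400, n, replace = TRUE)
  tlen <- sample(100:400, n, replace = TRUE)
  qend <- pmax(2L, as.integer(round(qlen * runif(n, 0.3, 1))))
  tend <- pmax(2L, as.integer(round(tlen * runif(n, 0.3, 1))))
  data.frame(
    query = sample(og, n, replace = TRUE),
    target = sample(og, n, replace = TRUE),
    probability = round(runif(n, 0, 100), 1),
    evalue = 10^runif(n, -30, 0),
    score = round(runif(n, 10, 500), 1),
    qstart = 1L, qend = qend, tstart = 1L, tend = tend,
    alnlen = pmax(qend, tend), qlen = qlen, tlen = tlen,
    stringsAsFactors = FALSE)
}
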