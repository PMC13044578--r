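#' Default taxonomic rank ladder
#'
#' Ranks ordered most specific to least specific, as used for LCA assignment.
#' The custom `suborder` rank (carrying the "Complex" / "Robust" clade
#' classification of stony corals) sits between `family` and `order`: it is a
#' clade within the order Scleractinia, so it must be scanned before `order`
#' or it could never be an LCA.
#'
#' @return character vector of rank names.
#' @export
defaultRankLadder <- function() {
  c("tax_id", "isolate", "species", "genus", "family", "suborder", "order",
    "class", "subphylum", "phylum", "clade1", "kingdom", "clade",
    "superkingdom", "no rank")
}

#' Assign the lowest common ancestor of a set of datasets
#'
#' Scans the rank ladder from most to least specific and returns the first
#' rank at which every dataset carries the same non-missing taxon. A dataset
#' missing a value at a rank cannot certify agreement there, so that rank is
#' skipped. If no rank agrees, a flagged root sentinel is returned.
#'
#' @param datasetIds character vector of member dataset ids.
#' @param lineages lineage data.frame from [readLineages()].
#' @param ladder rank ladder, most to least specific.
#' @return list: `rank`, `taxon`, `flagged` (TRUE for the root sentinel).
#' @export
assignLCA <- function(datasetIds, lineages, ladder = defaultRankLadder()) {
  i <- match(unique(datasetIds), lineages$dataset_id)
  if (anyNA(i))
    stop("dataset without lineage record: ",
         unique(datasetIds)[is.na(i)][1])
  for (r in ladder) {
    vals <- lineages[[r]][i]
    if (!anyNA(vals) && length(unique(vals)) == 1L)
      return(list(rank = r, taxon = vals[1], flagged = FALSE))
  }
  list(rank = "root", taxon = "cellular organisms", flagged = TRUE)
}

#' Assign LCAs for every orthogroup in a corpus
#'
#' @param ogs an [OrthogroupSet-class].
#' @param lineages lineage data.frame from [readLineages()].
#' @param ladder rank ladder.
#' @return `ogs` with `lca_rank` and `lca_taxon` set.
#' @export
assignLCAAll <- function(ogs, lineages, ladder = defaultRankLadder()) {
  byog <- split(ogs@members$dataset_id, ogs@members$og_id)
  byog <- byog[ogs@og$og_id]
  res <- lapply(byog, assignLCA, lineages = lineages, ladder = ladder)
  ogs@og$lca_rank <- vapply(res, `[[`, "", "rank")
  ogs@og$lca_taxon <- vapply(res, `[[`, "", "taxon")
  ogs
}

#' Nested lineage-group specification
#'
#' The three groups used for conserved-family selection must nest:
#' Scleractinia within Hexacorallia within Cnidaria.
#'
#' @param scleractinia,hexacorallia,cnidaria character vectors of dataset ids.
#' @return list of class `LineageGroups` with elements in narrowest-to-widest
#'   order, each a character vector of dataset ids.
#' @export
lineageGroups <- function(scleractinia, hexacorallia, cnidaria) {
  if (!length(cnidaria)) stop("empty group spec")
  if (!all(scleractinia %in% hexacorallia) ||
      !all(hexacorallia %in% cnidaria))
    stop("groups must nest: Scleractinia within Hexacorallia within Cnidaria")
  structure(list(Scleractinia = unique(scleractinia),
                 Hexacorallia = unique(hexacorallia),
                 Cnidaria = unique(cnidaria)),
            class = "LineageGroups")
}

#' Derive lineage groups from a lineage table
#'
#' Scleractinia = datasets with order "Scleractinia"; Hexacorallia = class
#' "Hexacorallia"; Cnidaria = phylum "Cnidaria".
#'
#' @param lineages lineage data.frame from [readLineages()].
#' @return a [lineageGroups()] object.
#' @export
groupsFromLineages <- function(lineages) {
  pick <- function(rank, taxon) {
    v <- lineages[[rank]]
    lineages$dataset_id[!is.na(v) & v == taxon]
  }
  lineageGroups(pick("order", "Scleractinia"),
                pick("class", "Hexacorallia"),
                pick("phylum", "Cnidaria"))
}

#' Select conserved dark orthogroups
#'
#' A dark OG qualifies iff (a) it is dark; (b) all member datasets lie inside
#' one of the nested groups (any member outside Cnidaria disqualifies it);
#' (c) its category is the narrowest group containing all members; and
#' (d) its distinct member datasets cover at least `minCoverage` of that
#' group's size (inclusive: exactly 50% qualifies at the default).
#'
#' @param ogs a classified [OrthogroupSet-class] (darkness and LCA set).
#' @param groups a [lineageGroups()] object.
#' @param minCoverage inclusive coverage threshold, default 0.5.
#' @return data.frame: `og_id`, `category`, `n_datasets`, `coverage`,
#'   `lca_rank`, `lca_taxon`, one row per selected OG.
#' @export
selectConservedDark <- function(ogs, groups, minCoverage = 0.5) {
  if (!inherits(groups, "LineageGroups")) stop("groups must be lineageGroups()")
  o <- ogs@og
  dark <- o$og_id[o$darkness == "dark"]
  byog <- split(ogs@members$dataset_id, ogs@members$og_id)
  sizes <- lengths(groups)
  rows <- lapply(dark, function(id) {
    dsets <- unique(byog[[id]])
    cat <- NA_character_
    for (g in names(groups)) {        # narrowest first
      if (all(dsets %in% groups[[g]])) { cat <- g; break }
    }
    if (is.na(cat)) return(NULL)
    cov <- length(dsets) / sizes[[cat]]
    if (cov < minCoverage) return(NULL)
    data.frame(og_id = id, category = cat,
               n_datasets = length(dsets), coverage = cov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(og_id = character(), category = character(),
                      n_datasets = integer(), coverage = numeric())
  i <- match(out$og_id, o$og_id)
  out$lca_rank <- o$lca_rank[i]
  out$lca_taxon <- o$lca_taxon[i]
  rownames(out) <- NULL
  out
}

#' Mark selected conserved OGs in the corpus object
#'
#' @param ogs an [OrthogroupSet-class].
#' @param conserved data.frame from [selectConservedDark()].
#' @return `ogs` with `conserved_group` filled for selected OGs.
#' @export
markConserved <- function(ogs, conserved) {
  i <- match(ogs@og$og_id, conserved$og_id)
  ogs@og$conserved_group <- conserved$category[i]
  ogs
}

.greedyCentroidClusters <- function(scores, threshold) {
  ids <- rownames(scores)
  diag(scores) <- NA
  strength <- rowSums(scores, na.rm = TRUE)
  remaining <- ids[order(-strength, ids)]  # ties lexicographic
  centroids <- character()
  while (length(remaining)) {
    c0 <- remaining[1]
    centroids <- c(centroids, c0)
    inClust <- remaining[remaining == c0 |
                           (!is.na(scores[c0, remaining]) &
                              scores[c0, remaining] >= threshold)]
    remaining <- setdiff(remaining, inClust)
  }
  centroids
}

#' Pick an orthogroup's representative sequence
#'
#' Either from precomputed per-sequence vote counts (the number of times each
#' sequence was a cluster representative across re-clustering runs), or from
#' a symmetric pairwise score matrix via an internal greedy centroid
#' clustering run at several thresholds (each run's centroids receive one
#' vote). The member with the maximal vote count wins; ties are broken
#' lexicographically by id and recorded.
#'
#' @param members character vector of member ids (non-empty).
#' @param votes optional named numeric vote counts.
#' @param scores optional symmetric numeric matrix with member dimnames.
#' @param thresholds clustering thresholds; default, the 25/50/75% quantiles
#'   of the off-diagonal scores.
#' @return list: `representative`, `votes` (named), `ties` (character vector
#'   of co-maximal ids, empty when unique).
#' @export
pickRepresentative <- function(members, votes = NULL, scores = NULL,
                               thresholds = NULL) {
  if (!length(members)) stop("empty OG")
  if (length(members) == 1L)
    return(list(representative = members,
                votes = setNames(1, members), ties = character()))
  if (is.null(votes)) {
    if (is.null(scores)) stop("supply votes or a pairwise score matrix")
    scores <- scores[members, members, drop = FALSE]
    if (is.null(thresholds)) {
      off <- scores[upper.tri(scores)]
      thresholds <- unique(quantile(off, c(0.25, 0.5, 0.75), names = FALSE))
    }
    votes <- setNames(numeric(length(members)), members)
    for (th in thresholds) {
      cents <- .greedyCentroidClusters(scores, th)
      votes[cents] <- votes[cents] + 1
    }
  }
  votes <- votes[order(names(votes))]
  top <- names(votes)[votes == max(votes)]
  list(representative = top[1], votes = votes,
       ties = if (length(top) > 1L) top else character())
}
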