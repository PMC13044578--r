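#' @include darkog-package.R
NULL

#' OrthogroupSet: a corpus of gene families
#'
#' Container for orthogroup (OG) membership plus per-OG annotations
#' accumulated by the pipeline (darkness call, LCA rank/taxon, representative
#' sequence, conserved-group category).
#'
#' @slot members data.frame with columns `og_id`, `dataset_id`, `protein_id`
#'   and optionally `length` (residues); one row per member protein.
#' @slot og data.frame with one row per OG: `og_id`, `darkness`
#'   (`"dark"`, `"light"` or `"unset"`), `lca_rank`, `lca_taxon`,
#'   `representative`, `conserved_group` (all `NA_character_` until set),
#'   `n_members`.
#'
#' @seealso [readOrthogroups()], [classifyOrthogroups()], [assignLCAAll()]
#' @exportClass OrthogroupSet
setClass("OrthogroupSet",
  slots = c(members = "data.frame", og = "data.frame"))

setValidity("OrthogroupSet", function(object) {
  m <- object@members; o <- object@og
  need_m <- c("og_id", "dataset_id", "protein_id")
  if (!all(need_m %in% names(m)))
    return(paste("members must have columns:", paste(need_m, collapse = ", ")))
  need_o <- c("og_id", "darkness", "lca_rank", "lca_taxon",
              "representative", "conserved_group", "n_members")
  if (!all(need_o %in% names(o)))
    return(paste("og must have columns:", paste(need_o, collapse = ", ")))
  if (anyDuplicated(o$og_id)) return("duplicate og_id in og table")
  if (nrow(m) == 0L) return("members table is empty")
  if (!all(o$og_id %in% m$og_id)) return("og table lists OGs with no members")
  if (!all(m$og_id %in% o$og_id)) return("members reference unknown og_id")
  bad <- !o$darkness %in% c("dark", "light", "unset")
  if (any(bad)) return("darkness must be dark/light/unset")
  rep_set <- !is.na(o$representative)
  if (any(rep_set)) {
    tok <- paste(m$og_id, m$protein_id, sep = "\r")
    rtok <- paste(o$og_id[rep_set], o$representative[rep_set], sep = "\r")
    if (!all(rtok %in% tok))
      return("a representative is not a member of its OG")
  }
  TRUE
})

#' Construct an OrthogroupSet from a membership table
#'
#' @param members data.frame with columns `og_id`, `dataset_id`,
#'   `protein_id` and optionally `length`.
#' @return An [OrthogroupSet-class] with all per-OG annotations unset.
#' @examples
#' m <- data.frame(og_id = "OG1", dataset_id = c("d1", "d2"),
#'                 protein_id = c("p1", "p2"))
#' OrthogroupSet(m)
#' @export
OrthogroupSet <- function(members) {
  members <- as.data.frame(members)
  dup <- duplicated(members[c("og_id", "dataset_id", "protein_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate member token(s) removed")
    members <- members[!dup, , drop = FALSE]
  }
  ids <- unique(members$og_id)
  og <- data.frame(
    og_id = ids,
    darkness = "unset",
    lca_rank = NA_character_,
    lca_taxon = NA_character_,
    representative = NA_character_,
    conserved_group = NA_character_,
    n_members = as.integer(table(factor(members$og_id, levels = ids))),
    stringsAsFactors = FALSE)
  new("OrthogroupSet", members = members, og = og)
}

#' @describeIn OrthogroupSet number of orthogroups
#' @param x,object an `OrthogroupSet`
#' @export
nOgs <- function(x) nrow(x@og)

#' @describeIn OrthogroupSet orthogroup identifiers
#' @export
ogIds <- function(x) x@og$og_id

#' @describeIn OrthogroupSet per-OG annotation table
#' @export
ogTable <- function(x) x@og

#' @describeIn OrthogroupSet membership table, optionally for one OG
#' @param og_id optional single OG id to subset members
#' @export
ogMembers <- function(x, og_id = NULL) {
  if (is.null(og_id)) return(x@members)
  x@members[x@members$og_id == og_id, , drop = FALSE]
}

setMethod("show", "OrthogroupSet", function(object) {
  o <- object@og
  cat("OrthogroupSet with", nrow(o), "OGs /", nrow(object@members),
      "member proteins\n")
  cat("  darkness:", sum(o$darkness == "dark"), "dark,",
      sum(o$darkness == "light"), "light,",
      sum(o$darkness == "unset"), "unset\n")
  cat("  LCA assigned:", sum(!is.na(o$lca_rank)),
      "| representatives:", sum(!is.na(o$representative)),
      "| conserved:", sum(!is.na(o$conserved_group)), "\n")
})

#' DecayFit: fitted exponential bitscore-decay model
#'
#' Model of the best homology-search bitscore of a gene family as a function
#' of evolutionary distance, `B(d) = a * exp(-b * d)`, fitted by nonlinear
#' least squares. Used to compute the probability that a true homolog at a
#' given distance would fall below the detection bitscore floor (homology
#' detection failure).
#'
#' @slot a bitscore at distance zero (`> 0`).
#' @slot b decay rate per unit distance (`>= 0`).
#' @slot residualSd residual standard deviation of the fit (bits).
#' @slot paramCov 2x2 covariance matrix of `(a, b)`.
#' @slot nPoints number of observations fitted.
#' @seealso [fitDecay()], [predictUndetected()]
#' @exportClass DecayFit
setClass("DecayFit",
  slots = c(a = "numeric", b = "numeric", residualSd = "numeric",
            paramCov = "matrix", nPoints = "integer"))

setValidity("DecayFit", function(object) {
  if (length(object@a) != 1L || object@a <= 0) return("a must be > 0")
  if (length(object@b) != 1L || object@b < 0) return("b must be >= 0")
  if (object@residualSd < 0) return("residualSd must be >= 0")
  if (!all(dim(object@paramCov) == c(2L, 2L)))
    return("paramCov must be 2x2")
  TRUE
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit: B(d) = %.4g * exp(-%.4g * d)  [residual sd %.3g, n = %d]\n",
    object@a, object@b, object@residualSd, object@nPoints))
})

#' HdfAssessment: per-OG homology detection failure evidence
#'
#' Per-dataset detection-failure probabilities for datasets absent from an
#' OG, with the counts of non-LCA datasets supporting (`p > 0.95`), against
#' (`p < 0.05`) and ambiguous for HDF, and the resulting OG-level call.
#'
#' @slot ogId the OG assessed.
#' @slot perDataset data.frame: `dataset_id`, `distance`, `p_undetected`,
#'   `class` (`support`/`against`/`ambiguous`), `in_lca` (logical).
#' @slot support,against,ambiguous counts over non-LCA datasets.
#' @slot call `"hdf_supported"`, `"hdf_rejected"` or `"ambiguous"`.
#' @slot scorable FALSE when no non-LCA dataset could be scored.
#' @seealso [assessOG()]
#' @exportClass HdfAssessment
setClass("HdfAssessment",
  slots = c(ogId = "character", perDataset = "data.frame",
            support = "integer", against = "integer", ambiguous = "integer",
            call = "character", scorable = "logical"))

setValidity("HdfAssessment", function(object) {
  n_nonlca <- sum(!object@perDataset$in_lca)
  if (object@support + object@against + object@ambiguous != n_nonlca)
    return("support + against + ambiguous must equal scored non-LCA datasets")
  if (!object@call %in% c("hdf_supported", "hdf_rejected", "ambiguous"))
    return("invalid call")
  TRUE
})

setMethod("show", "HdfAssessment", function(object) {
  cat(sprintf("HdfAssessment %s: %s (support %d / against %d / ambiguous %d)%s\n",
              object@ogId, object@call, object@support, object@against,
              object@ambiguous,
              if (object@scorable) "" else " [not scorable]"))
})

#' HomologyGraph: remote-homology network over orthogroups
#'
#' Undirected graph with OGs as nodes and filtered, deduplicated HMM-HMM
#' hits as edges (weight = length-normalized alignment score).
#'
#' @slot graph an `igraph` object.
#' @slot nodeAttrs data.frame of node attributes keyed by `og_id`
#'   (may have zero rows when no attributes were supplied).
#' @seealso [buildHomologyGraph()], [componentStats()]
#' @exportClass HomologyGraph
setClass("HomologyGraph",
  slots = c(graph = "ANY", nodeAttrs = "data.frame"))

setMethod("show", "HomologyGraph", function(object) {
  s <- componentStats(object)
  cat(sprintf(
    "HomologyGraph: %d nodes, %d edges, %d components (largest %d)\n",
    s$n_nodes, s$n_edges, s$n_components, s$largest_component_size))
})
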