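#' Configuration for dark/light protein classification
#'
#' A protein is "light" (putatively functional) if at least one of its
#' homology hits at or below the e-value cutoff carries a description that
#' contains none of the functionally ambiguous phrases; otherwise (including
#' the zero-hit case) it is "dark". Phrase matching is case-insensitive
#' substring containment; blank descriptions count as ambiguous.
#'
#' @param eValueCutoff hits above this e-value are ignored (default 1e-5).
#' @param ambiguousPhrases character vector of ambiguous description phrases.
#' @return list of class `DarknessConfig`.
#' @export
darknessConfig <- function(
    eValueCutoff = 1e-5,
    ambiguousPhrases = c("uncharacterized protein", "hypothetical protein",
                         "predicted protein", "expressed protein",
                         "unnamed protein product")) {
  if (!length(ambiguousPhrases)) stop("ambiguousPhrases must be non-empty")
  if (eValueCutoff <= 0) stop("eValueCutoff must be > 0")
  structure(list(eValueCutoff = eValueCutoff,
                 ambiguousPhrases = tolower(ambiguousPhrases)),
            class = "DarknessConfig")
}

.isAmbiguous <- function(descriptions, cfg) {
  d <- tolower(trimws(descriptions))
  amb <- !nzchar(d)  # blank = no usable function
  for (ph in cfg$ambiguousPhrases)
    amb <- amb | grepl(ph, d, fixed = TRUE)
  amb
}

#' Classify one protein from its homology hits
#'
#' @param hits data.frame of hits for a single query protein, with columns
#'   `e_value` and `description`. Zero rows is a valid dark call.
#' @param cfg a [darknessConfig()].
#' @return `"dark"` or `"light"`.
#' @examples
#' h <- data.frame(e_value = 1e-20, description = "hypothetical protein X1")
#' classifyProtein(h, darknessConfig())
#' @export
classifyProtein <- function(hits, cfg = darknessConfig()) {
  if (nrow(hits) == 0L) return("dark")
  informative <- hits$e_value <= cfg$eValueCutoff &
    !.isAmbiguous(hits$description, cfg)
  if (any(informative)) "light" else "dark"
}

#' Classify every member protein of a corpus
#'
#' Proteins of `ogs` with no rows in `hits` get a dark call (no hits).
#'
#' @param ogs an [OrthogroupSet-class].
#' @param hits data.frame with columns `dataset_id`, `protein_id`,
#'   `e_value`, `description` (all hits, all queries).
#' @param cfg a [darknessConfig()].
#' @return data.frame `dataset_id`, `protein_id`, `call`.
#' @export
classifyProteins <- function(ogs, hits, cfg = darknessConfig()) {
  m <- ogs@members
  key <- paste(m$dataset_id, m$protein_id, sep = "\r")
  calls <- rep("dark", length(key))
  if (nrow(hits)) {
    informative <- hits$e_value <= cfg$eValueCutoff &
      !.isAmbiguous(hits$description, cfg)
    lit <- unique(paste(hits$dataset_id, hits$protein_id,
                        sep = "\r")[informative])
    calls[key %in% lit] <- "light"
  }
  out <- data.frame(dataset_id = m$dataset_id, protein_id = m$protein_id,
                    call = calls, stringsAsFactors = FALSE)
  unique(out)
}

#' Classify orthogroups from member protein calls
#'
#' An OG is dark iff all member proteins are dark; light if any member is
#' light. Every member must have a call.
#'
#' @param ogs an [OrthogroupSet-class].
#' @param proteinCalls data.frame from [classifyProteins()].
#' @return `ogs` with the `darkness` column set (plus `n_light_members`).
#' @export
classifyOrthogroups <- function(ogs, proteinCalls) {
  m <- ogs@members
  key <- paste(m$dataset_id, m$protein_id, sep = "\r")
  ckey <- paste(proteinCalls$dataset_id, proteinCalls$protein_id, sep = "\r")
  i <- match(key, ckey)
  if (anyNA(i)) {
    j <- which(is.na(i))[1]
    stop("no darkness call for member ", m$dataset_id[j], "|",
         m$protein_id[j])
  }
  light <- proteinCalls$call[i] == "light"
  n_light <- as.integer(
    tapply(light, factor(m$og_id, levels = ogs@og$og_id), sum))
  ogs@og$darkness <- ifelse(n_light > 0L, "light", "dark")
  ogs@og$n_light_members <- n_light
  validObject(ogs)
  ogs
}

#' Corpus darkness summary
#'
#' @param ogs a classified [OrthogroupSet-class].
#' @param proteinCalls data.frame from [classifyProteins()].
#' @return one-row data.frame: `n_proteins`, `n_dark`, `fraction_dark`,
#'   `n_ogs`, `n_dark_ogs`.
#' @export
darknessSummary <- function(ogs, proteinCalls) {
  if (nrow(proteinCalls) == 0L) stop("empty corpus")
  if (any(ogs@og$darkness == "unset"))
    stop("classify orthogroups before summarizing")
  data.frame(
    n_proteins = nrow(proteinCalls),
    n_dark = sum(proteinCalls$call == "dark"),
    fraction_dark = mean(proteinCalls$call == "dark"),
    n_ogs = nOgs(ogs),
    n_dark_ogs = sum(ogs@og$darkness == "dark"))
}

#' Derive putative functional regions of a protein
#'
#' Merges the functional annotation intervals, subtracts the merged
#' transmembrane intervals, and keeps only regions strictly longer than
#' `min_len`. A protein whose merged transmembrane set is non-empty is
#' flagged putatively membrane associated.
#'
#' @param functional,transmembrane interval data.frames on one protein
#'   (see [intervalTable()]).
#' @param min_len strict length filter, default 30.
#' @return list: `regions` (interval data.frame),
#'   `membraneAssociated` (logical).
#' @export
deriveFunctionalRegions <- function(functional, transmembrane,
                                    min_len = 30L) {
  fun <- mergeIntervals(functional)
  tm <- mergeIntervals(transmembrane)
  regions <- filterMinLength(subtractIntervals(fun, tm), min_len)
  list(regions = regions, membraneAssociated = nrow(tm) > 0L)
}
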