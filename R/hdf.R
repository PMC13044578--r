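#' Patristic distance matrix from a species tree
#'
#' Sum of branch lengths between every pair of tips.
#'
#' @param tree an `ape::phylo` object or path to a newick file.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristicDistances <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stats::cophenetic(tree)
}

#' Best bitscore between an OG's representative and each member dataset
#'
#' For each dataset with members in the OG, the observation is the maximum
#' bitscore between the representative sequence and any sequence of that
#' dataset (paralogs collapse to their best score). The representative's own
#' dataset yields the distance-zero anchor.
#'
#' @param members data.frame with columns `dataset_id`, `protein_id`.
#' @param scores symmetric numeric matrix of within-OG bitscores with
#'   protein ids as dimnames.
#' @param representative protein id of the OG representative (must be set).
#' @param distances named numeric vector: patristic distance from the
#'   representative's dataset to each dataset.
#' @return data.frame: `dataset_id`, `distance`, `bitscore`.
#' @export
bestBitscorePerDataset <- function(members, scores, representative,
                                   distances) {
  if (is.null(representative) || is.na(representative))
    stop("representative unset")
  if (!representative %in% rownames(scores))
    stop("representative not in score matrix")
  row <- scores[representative, ]
  best <- tapply(row[members$protein_id],
                 factor(members$dataset_id), max)
  data.frame(dataset_id = names(best),
             distance = unname(distances[names(best)]),
             bitscore = unname(best),
             stringsAsFactors = FALSE)
}

#' Fit the exponential bitscore-decay model
#'
#' Nonlinear least squares fit of `B(d) = a * exp(-b * d)` with `a > 0`,
#' `b >= 0`, via Levenberg-Marquardt. Starting values come from a log-linear
#' regression of `log(B)` on `d`.
#'
#' @param d non-negative distances (substitutions/site).
#' @param B observed best bitscores (bits), same length as `d`.
#' @return a [DecayFit-class].
#' @examples
#' d <- c(0, 0.5, 1, 2, 4)
#' fitDecay(d, 200 * exp(-0.5 * d))
#' @export
fitDecay <- function(d, B) {
  if (length(d) != length(B)) stop("d and B must have equal length")
  keep <- !is.na(d) & !is.na(B)
  d <- d[keep]; B <- B[keep]
  if (length(d) < 3L) stop("need at least 3 observations")
  if (length(unique(d)) < 2L)
    stop("underdetermined: all distances equal")
  if (any(d < 0)) stop("distances must be >= 0")
  lf <- stats::lm(log(pmax(B, 1e-6)) ~ d)
  start <- list(a = max(exp(coef(lf)[1]), 1e-3),
                b = max(-coef(lf)[2], 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(B ~ a * exp(-b * d), start = start,
                      lower = c(a = 1e-9, b = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) stop("decay fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  dof <- max(length(d) - 2L, 1L)
  rsd <- sqrt(sum(stats::residuals(fit)^2) / dof)
  cv <- tryCatch(vcov(fit), error = function(e) matrix(0, 2, 2))
  if (any(!is.finite(cv))) cv <- matrix(0, 2, 2)
  dimnames(cv) <- list(c("a", "b"), c("a", "b"))
  new("DecayFit", a = unname(cf["a"]), b = unname(cf["b"]),
      residualSd = rsd, paramCov = cv, nPoints = length(d))
}

#' Predicted mean bitscore at a distance
#'
#' @param fit a [DecayFit-class].
#' @param d distance(s).
#' @return numeric vector `a * exp(-b * d)`.
#' @export
predictBitscore <- function(fit, d) fit@a * exp(-fit@b * d)

#' Probability that a homolog would go undetected
#'
#' The detection floor is the Karlin-Altschul-style bitscore at which a hit
#' reaches the e-value threshold in a search space of `repLength * dbLength`:
#' `B_thr = log2(repLength * dbLength / eThreshold)`. The true bitscore at
#' distance `dStar` is modeled as Gaussian with mean `a * exp(-b * dStar)`
#' and variance equal to the residual variance plus first-order (delta
#' method) propagation of the parameter covariance. The returned value is
#' `P(bitscore < B_thr)`.
#'
#' @param fit a [DecayFit-class].
#' @param dStar distance(s) at which to predict (>= 0).
#' @param repLength representative sequence length (residues).
#' @param dbLength target database length (residues).
#' @param eThreshold e-value threshold of the search (> 0 required: a zero
#'   threshold would put the detection floor at infinity).
#' @return probability in [0, 1], vectorized over `dStar`.
#' @export
predictUndetected <- function(fit, dStar, repLength, dbLength,
                              eThreshold = 1e-3) {
  if (eThreshold <= 0) stop("eThreshold must be > 0")
  if (any(dStar < 0)) stop("dStar must be >= 0")
  bthr <- log2(repLength * dbLength / eThreshold)
  m <- fit@a * exp(-fit@b * dStar)
  g1 <- exp(-fit@b * dStar)
  g2 <- -fit@a * dStar * exp(-fit@b * dStar)
  varp <- g1^2 * fit@paramCov[1, 1] + g2^2 * fit@paramCov[2, 2] +
    2 * g1 * g2 * fit@paramCov[1, 2]
  v <- fit@residualSd^2 + pmax(varp, 0)
  p <- pnorm(bthr, mean = m, sd = sqrt(pmax(v, 1e-12)))
  pmin(pmax(p, 0), 1)
}

#' Classify detection-failure probabilities
#'
#' `p > 0.95` supports HDF, `p < 0.05` is evidence against, probabilities in
#' `[0.05, 0.95]` are ambiguous.
#'
#' @param p numeric probabilities in [0, 1].
#' @return character vector `support` / `against` / `ambiguous`.
#' @export
classifyHdfProbability <- function(p) {
  ifelse(p > 0.95, "support", ifelse(p < 0.05, "against", "ambiguous"))
}

#' OG-level homology detection failure call
#'
#' Counts support / against / ambiguous over the scored datasets *outside*
#' the OG's LCA clade (absence of inside-LCA datasets is more plausibly
#' dataset incompleteness and is reported but not counted). The OG is called
#' `hdf_supported` when at least half of the scored non-LCA datasets support
#' HDF, `hdf_rejected` when at least half are against (support takes
#' precedence on an exact tie), else `ambiguous`. With zero scorable non-LCA
#' datasets the call is `ambiguous` and flagged not scorable.
#'
#' @param ogId OG identifier.
#' @param predictions data.frame: `dataset_id`, `p_undetected`, `in_lca`
#'   (logical; TRUE for datasets inside the OG's LCA clade), optionally
#'   `distance`.
#' @return an [HdfAssessment-class].
#' @export
assessOG <- function(ogId, predictions) {
  pd <- as.data.frame(predictions)
  if (!"distance" %in% names(pd)) pd$distance <- NA_real_
  pd$class <- classifyHdfProbability(pd$p_undetected)
  non <- pd[!pd$in_lca, , drop = FALSE]
  support <- sum(non$class == "support")
  against <- sum(non$class == "against")
  ambiguous <- sum(non$class == "ambiguous")
  scored <- nrow(non)
  if (scored == 0L) {
    call <- "ambiguous"; scorable <- FALSE
  } else {
    scorable <- TRUE
    call <- if (support >= scored / 2) "hdf_supported"
      else if (against >= scored / 2) "hdf_rejected"
      else "ambiguous"
  }
  new("HdfAssessment", ogId = ogId,
      perDataset = pd[c("dataset_id", "distance", "p_undetected",
                        "class", "in_lca")],
      support = as.integer(support), against = as.integer(against),
      ambiguous = as.integer(ambiguous), call = call, scorable = scorable)
}

#' Full HDF assessment of one OG from bitscore observations
#'
#' Fits the decay model on datasets where the family is present, predicts
#' the undetected probability for every absent dataset (inside- and
#' outside-LCA alike), and makes the OG-level call from the outside-LCA
#' predictions.
#'
#' @param ogId OG identifier.
#' @param obs data.frame of present-dataset observations: `dataset_id`,
#'   `distance`, `bitscore`.
#' @param absent data.frame of absent datasets: `dataset_id`, `distance`,
#'   `in_lca` (logical).
#' @param repLength representative sequence length.
#' @param dbLengths named numeric vector of per-dataset database lengths.
#' @param eThreshold e-value threshold (> 0).
#' @return an [HdfAssessment-class], or NULL when the decay model cannot be
#'   fitted (fewer than 3 observations or fewer than 2 distinct distances).
#' @export
hdfAssessOg <- function(ogId, obs, absent, repLength, dbLengths,
                        eThreshold = 1e-3) {
  if (nrow(obs) < 3L || length(unique(obs$distance)) < 2L) return(NULL)
  fit <- tryCatch(fitDecay(obs$distance, obs$bitscore),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  if (nrow(absent) == 0L)
    return(assessOG(ogId, data.frame(dataset_id = character(),
                                     p_undetected = numeric(),
                                     in_lca = logical(),
                                     distance = numeric())))
  p <- predictUndetected(fit, absent$distance, repLength,
                         dbLengths[absent$dataset_id], eThreshold)
  assessOG(ogId, data.frame(dataset_id = absent$dataset_id,
                            distance = absent$distance,
                            p_undetected = p, in_lca = absent$in_lca,
                            stringsAsFactors = FALSE))
}

#' Summarize a list of HDF assessments
#'
#' @param assessments list of [HdfAssessment-class] objects.
#' @return one-row data.frame with assessed/supported/rejected/ambiguous
#'   counts and the supported and rejected percentages (1 decimal place).
#' @export
hdfCallSummary <- function(assessments) {
  calls <- vapply(assessments, function(a) a@call, "")
  n <- length(calls)
  sup <- sum(calls == "hdf_supported")
  rej <- sum(calls == "hdf_rejected")
  data.frame(n_assessed = n, n_supported = sup, n_rejected = rej,
             n_ambiguous = n - sup - rej,
             pct_supported = if (n) round(100 * sup / n, 1) else NA_real_,
             pct_rejected = if (n) round(100 * rej / n, 1) else NA_real_)
}
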