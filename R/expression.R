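#' Filter genes with low expression (pOverA-style)
#'
#' Keeps a gene iff the fraction of samples with count strictly greater than
#' `minCount` is strictly greater than `minFrac` (read count > 10 in > 10%
#' of samples at the defaults).
#'
#' @param counts numeric gene x sample matrix with rownames.
#' @param minCount strict per-sample count threshold, default 10.
#' @param minFrac strict fraction-of-samples threshold, default 0.1.
#' @return character vector of retained gene ids.
#' @export
filterLowExpression <- function(counts, minCount = 10, minFrac = 0.1) {
  if (is.null(dim(counts)) || ncol(counts) == 0L) stop("zero samples")
  frac <- rowMeans(counts > minCount)
  rownames(counts)[frac > minFrac]
}

#' Call differentially expressed genes from a DE result table
#'
#' Significant iff `|log2_fc| > lfcCutoff` and `p_adj < pCutoff`
#' (both strict). Rows with missing `p_adj` are skipped with a warning.
#'
#' @param results data.frame: `gene_id`, `comparison`, `log2_fc`, `p_adj`.
#' @param lfcCutoff default 0.5.
#' @param pCutoff default 0.05.
#' @return `results` (minus skipped rows) with a logical `significant`
#'   column.
#' @export
callDegs <- function(results, lfcCutoff = 0.5, pCutoff = 0.05) {
  miss <- is.na(results$p_adj)
  if (any(miss)) {
    warning(sum(miss), " record(s) without adjusted p-value skipped")
    results <- results[!miss, , drop = FALSE]
  }
  results$significant <- abs(results$log2_fc) > lfcCutoff &
    results$p_adj < pCutoff
  results
}

.welch <- function(treat, control) {
  if (stats::sd(treat) == 0 && stats::sd(control) == 0) {
    # degenerate: no variance in either arm
    return(if (isTRUE(all.equal(mean(treat), mean(control)))) 1 else 0)
  }
  t.test(treat, control, var.equal = FALSE)$p.value
}

#' Call differentially accumulated proteins (Welch t test)
#'
#' Per protein and time point, compares treatment against control with a
#' Welch two-sample t test on normalized intensities; the fold change is the
#' log2 ratio of arm means. Significant iff `|FC| > fcCutoff` and
#' `p < pCutoff` (both strict). Zero variance in both arms with equal means
#' gives p = 1 by convention.
#'
#' @param intensities numeric protein x sample matrix with dimnames.
#' @param design data.frame: `sample`, `arm` (`"control"`/`"treatment"`),
#'   `time_point`. At least 2 replicates per arm are required.
#' @param fcCutoff default 0.5 (log2 scale).
#' @param pCutoff default 0.05.
#' @return data.frame: `protein_id`, `time_point`, `fc`, `p_value`,
#'   `significant`.
#' @export
callDifferentialProteins <- function(intensities, design, fcCutoff = 0.5,
                                     pCutoff = 0.05) {
  stopifnot(all(design$sample %in% colnames(intensities)))
  out <- lapply(unique(design$time_point), function(tp) {
    dtp <- design[design$time_point == tp, ]
    cs <- dtp$sample[dtp$arm == "control"]
    ts <- dtp$sample[dtp$arm == "treatment"]
    if (length(cs) < 2L || length(ts) < 2L)
      stop("need >= 2 replicates per arm at time point ", tp)
    ctrl <- intensities[, cs, drop = FALSE]
    trt <- intensities[, ts, drop = FALSE]
    fc <- log2(rowMeans(trt) / rowMeans(ctrl))
    p <- vapply(seq_len(nrow(intensities)),
                function(i) .welch(trt[i, ], ctrl[i, ]), numeric(1))
    data.frame(protein_id = rownames(intensities), time_point = tp,
               fc = fc, p_value = p,
               significant = abs(fc) > fcCutoff & p < pCutoff,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call significant cell-type-specific expression
#'
#' Significant iff the reported fold change is strictly greater than
#' `fcCutoff` (FC > 2.0 at the default). Negative fold changes are an error:
#' these are ratio-scale values.
#'
#' @param fcs data.frame: `gene_id`, `granularity` (`broadcell`/`cell`/
#'   `metacell`), `cell_type`, `fc`.
#' @param fcCutoff default 2.0.
#' @return `fcs` with a logical `significant` column.
#' @export
callCellTypeExpression <- function(fcs, fcCutoff = 2.0) {
  if (any(fcs$fc < 0)) stop("negative fold change: fc must be >= 0")
  bad <- setdiff(unique(fcs$granularity),
                 c("broadcell", "cell", "metacell"))
  if (length(bad)) stop("unknown granularity: ", paste(bad, collapse = ", "))
  fcs$significant <- fcs$fc > fcCutoff
  fcs
}

.bestHits <- function(tab) {
  # per query: unique best-bitscore subject; ties drop the query
  sp <- split(seq_len(nrow(tab)), tab$query)
  keep <- vapply(sp, function(i) {
    b <- tab$bitscore[i]
    if (sum(b == max(b)) > 1L) NA_integer_ else i[which.max(b)]
  }, integer(1))
  if (anyNA(keep))
    warning(sum(is.na(keep)), " quer(ies) with tied best hits dropped")
  tab[keep[!is.na(keep)], , drop = FALSE]
}

.hitCoverageOk <- function(hit, minCov, mode) {
  qcov <- (hit$qend - hit$qstart + 1) / hit$qlen
  scov <- (hit$send - hit$sstart + 1) / hit$slen
  if (mode == "either") qcov > minCov | scov > minCov
  else qcov > minCov & scov > minCov
}

#' Map gene ids across dataset versions by reciprocal best hit
#'
#' A pair `(a, b)` is mapped iff `b` is `a`'s unique best hit in the A-to-B
#' table, `a` is `b`'s unique best hit in the B-to-A table, and at least one
#' of the two reciprocal hits passes the coverage condition. Coverage is
#' strict (`> minCov`) and, in the default `"either"` mode, query *or*
#' subject coverage suffices. Ties for best hit drop the pair with a
#' warning. The result is an injective partial map; swapping the two tables
#' yields the inverse map.
#'
#' @param hitsAB,hitsBA data.frames with columns `query`, `subject`,
#'   `bitscore`, `qstart`, `qend`, `qlen`, `sstart`, `send`, `slen`.
#' @param minCov strict coverage threshold, default 0.6.
#' @param coverageMode `"either"` (default) or `"both"`.
#' @return data.frame: `id_a`, `id_b`.
#' @export
mapIdsRBH <- function(hitsAB, hitsBA, minCov = 0.6,
                      coverageMode = c("either", "both")) {
  coverageMode <- match.arg(coverageMode)
  bestAB <- .bestHits(hitsAB)
  bestBA <- .bestHits(hitsBA)
  ab <- setNames(bestAB$subject, bestAB$query)
  ba <- setNames(bestBA$subject, bestBA$query)
  cand <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  if (!length(cand))
    return(data.frame(id_a = character(), id_b = character()))
  ok <- vapply(cand, function(a) {
    b <- ab[[a]]
    h1 <- bestAB[bestAB$query == a, ][1, ]
    h2 <- bestBA[bestBA$query == b, ][1, ]
    .hitCoverageOk(h1, minCov, coverageMode) ||
      .hitCoverageOk(h2, minCov, coverageMode)
  }, logical(1))
  data.frame(id_a = cand[ok], id_b = unname(ab[cand[ok]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dark-versus-light proportion bias across units
#'
#' For each group (dark/light), the denominator is the number of distinct
#' group genes significant in at least one unit (comparison or cell type);
#' per unit, the proportion is the distinct significant group genes in that
#' unit over the denominator. A gene significant in k units contributes to k
#' numerators but once to the denominator, so proportions need not sum to 1
#' across units. The per-unit bias is `delta = prop_dark - prop_light`. The
#' statistic is descriptive; `test = TRUE` adds an optional two-proportion
#' test per unit as an extension.
#'
#' @param sig data.frame of significant gene x unit records: `gene_id`,
#'   `unit`.
#' @param groupOf named character vector mapping gene_id to `"dark"` or
#'   `"light"`; every significant gene must be covered.
#' @param test add `p_value` from `prop.test` per unit (default FALSE).
#' @return list: `rows` (group, unit, n_sig_in_unit, denominator,
#'   proportion), `delta` (unit, delta; NA when a denominator is 0).
#' @export
proportionBias <- function(sig, groupOf, test = FALSE) {
  sig <- unique(sig[c("gene_id", "unit")])
  grp <- groupOf[sig$gene_id]
  if (anyNA(grp))
    stop("significant gene without group: ",
         sig$gene_id[is.na(grp)][1])
  sig$group <- unname(grp)
  units <- sort(unique(sig$unit))
  denom <- c(dark = length(unique(sig$gene_id[sig$group == "dark"])),
             light = length(unique(sig$gene_id[sig$group == "light"])))
  rows <- do.call(rbind, lapply(c("dark", "light"), function(g) {
    n <- vapply(units, function(u)
      length(unique(sig$gene_id[sig$group == g & sig$unit == u])),
      integer(1))
    data.frame(group = g, unit = units, n_sig_in_unit = n,
               denominator = denom[[g]],
               proportion = if (denom[[g]] > 0) n / denom[[g]] else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  pd <- rows$proportion[rows$group == "dark"]
  pl <- rows$proportion[rows$group == "light"]
  delta <- data.frame(unit = units, delta = pd - pl)
  if (test) {
    nd <- rows$n_sig_in_unit[rows$group == "dark"]
    nl <- rows$n_sig_in_unit[rows$group == "light"]
    delta$p_value <- vapply(seq_along(units), function(i) {
      if (denom[["dark"]] == 0 || denom[["light"]] == 0) return(NA_real_)
      suppressWarnings(stats::prop.test(
        c(nd[i], nl[i]), c(denom[["dark"]], denom[["light"]]))$p.value)
    }, numeric(1))
  }
  list(rows = rows, delta = delta)
}
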