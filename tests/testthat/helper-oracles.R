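# Independent brute-force oracles, deliberately written with different
# algorithms than the implementation they check.

# set of covered integer positions per sequence (half-open intervals)
positionsOf <- function(df) {
  if (nrow(df) == 0L) return(list())
  sp <- split(df, df$seq_id)
  lapply(sp, function(x)
    sort(unique(unlist(Map(function(s, e) seq(s, e - 1L), x$start, x$end)))))
}

# integer position set -> maximal runs as an interval table
runsToIntervals <- function(pos, seq_id) {
  if (!length(pos)) return(NULL)
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    p <- pos[(brk[i] + 1L):brk[i + 1L]]
    data.frame(seq_id = seq_id, start = p[1], end = p[length(p)] + 1L)
  }))
}

oracleMerge <- function(df) {
  pos <- positionsOf(df)
  out <- do.call(rbind, Map(runsToIntervals, pos, names(pos)))
  if (is.null(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer()))
  out <- out[order(out$seq_id, out$start), ]
  rownames(out) <- NULL
  out
}

oracleSubtract <- function(a, b) {
  pa <- positionsOf(a); pb <- positionsOf(b)
  out <- do.call(rbind, lapply(names(pa), function(id) {
    runsToIntervals(setdiff(pa[[id]], pb[[id]]), id)
  }))
  if (is.null(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer()))
  out <- out[order(out$seq_id, out$start), ]
  rownames(out) <- NULL
  out
}

# connected components by explicit breadth-first search
bfsComponents <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (n in nodes) {
    if (!is.na(comp[[n]])) next
    k <- k + 1L
    queue <- n
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- k
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# LCA by rank-wise taxon sets
oracleLCA <- function(datasetIds, lineages, ladder) {
  rows <- lineages[lineages$dataset_id %in% datasetIds, , drop = FALSE]
  for (r in ladder) {
    taxa <- rows[[r]]
    if (sum(!is.na(taxa)) == nrow(rows) &&
        length(unique(taxa[!is.na(taxa)])) == 1L)
      return(c(rank = r, taxon = unique(taxa)))
  }
  c(rank = "root", taxon = "cellular organisms")
}

# exhaustive per-unordered-pair max of normalized score
oracleDedup <- function(hits) {
  key <- paste(pmin(hits$query, hits$target),
               pmax(hits$query, hits$target), sep = "|")
  do.call(rbind, lapply(unique(sort(key)), function(k) {
    cand <- hits[key == k, , drop = FALSE]
    cand <- cand[cand$norm_score == max(cand$norm_score), , drop = FALSE]
    cand <- cand[cand$probability == max(cand$probability), , drop = FALSE]
    cand[order(cand$query), ][1, , drop = FALSE]
  }))
}

# all-pairs reciprocal-best scan
oracleRBH <- function(hitsAB, hitsBA, minCov = 0.6) {
  cov_ok <- function(h) {
    qc <- (h$qend - h$qstart + 1) / h$qlen
    sc <- (h$send - h$sstart + 1) / h$slen
    qc > minCov || sc > minCov
  }
  best <- function(tab, q) {
    rows <- tab[tab$query == q, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    mx <- rows[rows$bitscore == max(rows$bitscore), , drop = FALSE]
    if (nrow(mx) > 1L) return(NA_character_)
    mx$subject
  }
  out <- NULL
  for (a in unique(hitsAB$query)) {
    b <- best(hitsAB, a)
    if (is.na(b)) next
    if (is.na(best(hitsBA, b)) || best(hitsBA, b) != a) next
    h1 <- hitsAB[hitsAB$query == a & hitsAB$subject == b, ][1, ]
    h2 <- hitsBA[hitsBA$query == b & hitsBA$subject == a, ][1, ]
    if (cov_ok(h1) || cov_ok(h2))
      out <- rbind(out, data.frame(id_a = a, id_b = b))
  }
  if (is.null(out)) data.frame(id_a = character(), id_b = character())
  else out
}

# random interval table on a few sequences
randomIntervals <- function(n, nseq = 2, span = 60) {
  s <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(15, n, replace = TRUE)
  data.frame(seq_id = paste0("s", sample.int(nseq, n, replace = TRUE)),
             start = s, end = s + len, stringsAsFactors = FALSE)
}

sortedIv <- function(df) {
  df <- df[order(df$seq_id, df$start), c("seq_id", "start", "end")]
  rownames(df) <- NULL
  df
}
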