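#' Interval tables
#'
#' Protein-coordinate intervals are held as plain data.frames with columns
#' `seq_id`, `start`, `end` in zero-based half-open convention, the native
#' convention of BED. Arithmetic is delegated to IRanges behind this surface.
#'
#' @param seq_id character vector of sequence identifiers.
#' @param start,end integer vectors; `start < end` is required
#'   (zero-based half-open, so a single position `i` is `[i, i+1)`).
#' @return A validated interval data.frame.
#' @examples
#' intervalTable("p1", c(0, 15), c(20, 30))
#' @export
intervalTable <- function(seq_id, start, end) {
  x <- data.frame(seq_id = as.character(seq_id),
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  .checkIntervals(x)
  x
}

.checkIntervals <- function(x) {
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(x)))
    stop("interval table needs columns seq_id, start, end")
  if (nrow(x) && any(x$start >= x$end))
    stop("invalid interval: start >= end")
  invisible(x)
}

.emptyIntervals <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

# zero-based half-open -> IRanges (1-based closed) and back
.toIRanges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

.fromIRanges <- function(ir, seq_id) {
  if (length(ir) == 0L) return(.emptyIntervals())
  data.frame(seq_id = seq_id,
             start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

.perSeq <- function(x, y = NULL, f) {
  ids <- sort(unique(c(x$seq_id, if (!is.null(y)) y$seq_id)))
  out <- lapply(ids, function(id) {
    xi <- x[x$seq_id == id, , drop = FALSE]
    if (is.null(y)) f(xi, id)
    else f(xi, y[y$seq_id == id, , drop = FALSE], id)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) return(.emptyIntervals())
  rownames(res) <- NULL
  res
}

#' Merge overlapping or adjacent intervals
#'
#' Collapses each sequence's intervals to a disjoint, sorted set
#' (union of covered positions). Idempotent.
#'
#' @param xs interval data.frame (see [intervalTable()]).
#' @return Disjoint sorted interval data.frame.
#' @examples
#' mergeIntervals(intervalTable("p", c(10, 15), c(20, 30)))
#' @export
mergeIntervals <- function(xs) {
  .checkIntervals(xs)
  if (nrow(xs) == 0L) return(.emptyIntervals())
  .perSeq(xs, f = function(xi, id)
    .fromIRanges(IRanges::reduce(.toIRanges(xi)), id))
}

#' Subtract one interval set from another
#'
#' Removes from `a` every position covered by `b`, per sequence.
#'
#' @param a,b interval data.frames on a shared `seq_id` namespace.
#' @return Interval data.frame covering `positions(a) - positions(b)`.
#' @examples
#' subtractIntervals(intervalTable("p", 0, 100), intervalTable("p", 40, 60))
#' @export
subtractIntervals <- function(a, b) {
  .checkIntervals(a); .checkIntervals(b)
  if (nrow(a) == 0L) return(.emptyIntervals())
  .perSeq(a, b, f = function(ai, bi, id) {
    if (nrow(ai) == 0L) return(NULL)
    ir <- IRanges::setdiff(.toIRanges(ai), .toIRanges(bi))
    .fromIRanges(ir, id)
  })
}

#' Keep intervals strictly longer than a minimum
#'
#' Length is `end - start`; the filter is strict (`length > min_len`), so a
#' region of exactly `min_len` positions is removed.
#'
#' @param xs interval data.frame.
#' @param min_len integer; default 30.
#' @return Filtered interval data.frame.
#' @examples
#' filterMinLength(intervalTable("p", c(0, 60), c(30, 100)), 30)
#' @export
filterMinLength <- function(xs, min_len = 30L) {
  .checkIntervals(xs)
  xs[(xs$end - xs$start) > min_len, , drop = FALSE]
}

#' Read / write 3-column BED interval files
#'
#' BED is zero-based half-open, matching the internal convention directly.
#'
#' @param path file path.
#' @return `readBedIntervals`: interval data.frame.
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(x) < 3L) stop("BED file needs at least 3 columns: ", path)
  intervalTable(x[[1]], x[[2]], x[[3]])
}

#' @rdname readBedIntervals
#' @param xs interval data.frame to write.
#' @export
writeBedIntervals <- function(xs, path) {
  .checkIntervals(xs)
  write.table(xs[c("seq_id", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
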