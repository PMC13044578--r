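#' Read orthogroup membership tables
#'
#' Two dialects are supported: `"wide"` (OrthoFinder `Orthogroups.tsv` style:
#' one column per dataset, cells holding comma-separated protein ids) and
#' `"long"` (two columns, `og_id` and a member token `dataset<delim>protein`).
#' With `format = "auto"` the dialect is guessed from the header.
#'
#' @param path TSV file path.
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @param delim delimiter inside long-format member tokens (default `"|"`).
#' @return An [OrthogroupSet-class]. Duplicate member tokens are removed with
#'   a warning; an OG row with no members is an error naming the line.
#' @export
readOrthogroups <- function(path, format = c("auto", "wide", "long"),
                            delim = "|") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  if (format == "auto") {
    format <- if (ncol(x) == 2L && any(grepl(delim, x[[2]], fixed = TRUE)))
      "long" else "wide"
  }
  if (format == "long") {
    if (ncol(x) < 2L) stop("long format needs 2 columns in ", path)
    tok <- strsplit(x[[2]], delim, fixed = TRUE)
    bad <- which(lengths(tok) != 2L | !nzchar(x[[2]]))
    if (length(bad))
      stop("malformed member token at line ", bad[1] + 1L, " of ", path)
    members <- data.frame(
      og_id = x[[1]],
      dataset_id = vapply(tok, `[`, "", 1L),
      protein_id = vapply(tok, `[`, "", 2L),
      stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(x[[1]]))
      stop("duplicate og_id in ", path, ": ", x[[1]][duplicated(x[[1]])][1])
    datasets <- names(x)[-1]
    parts <- lapply(datasets, function(ds) {
      cells <- x[[ds]]
      keep <- !is.na(cells) & nzchar(trimws(cells))
      if (!any(keep)) return(NULL)
      prot <- strsplit(cells[keep], ",[ ]*")
      data.frame(og_id = rep(x[[1]][keep], lengths(prot)),
                 dataset_id = ds,
                 protein_id = trimws(unlist(prot)),
                 stringsAsFactors = FALSE)
    })
    members <- do.call(rbind, parts)
    empty <- setdiff(x[[1]], members$og_id)
    if (length(empty))
      stop("OG with zero members in ", path, ": ", empty[1])
  }
  OrthogroupSet(members)
}

#' Write an OrthogroupSet as a long-format membership TSV
#'
#' Round-trips exactly through [readOrthogroups()].
#'
#' @param x an [OrthogroupSet-class].
#' @param path output path.
#' @param delim member-token delimiter.
#' @export
writeOrthogroups <- function(x, path, delim = "|") {
  m <- x@members
  out <- data.frame(og_id = m$og_id,
                    member = paste(m$dataset_id, m$protein_id, sep = delim))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy lineage table
#'
#' Consumes an ncbitax2lin-style CSV: one row per dataset with a `tax_id`
#' column and one column per taxonomic rank. Only ranks present in the rank
#' ladder are kept (others are dropped with a message). A `dataset_id` column
#' is used if present, otherwise `tax_id` doubles as the dataset id. Manual
#' per-dataset overrides (e.g. a custom suborder carrying the "Complex" or
#' "Robust" classification for stony corals) are applied after parsing.
#'
#' @param path CSV file path.
#' @param rank_ladder character vector of ranks, most to least specific;
#'   see [defaultRankLadder()].
#' @param overrides named list: `dataset_id -> c(rank, taxon)`. A dataset in
#'   `overrides` missing from the table is an error.
#' @return data.frame with columns `dataset_id`, `source_kind` (if present)
#'   and one column per ladder rank (NA where the rank is missing).
#' @export
readLineages <- function(path, rank_ladder = defaultRankLadder(),
                         overrides = list()) {
  if (!length(rank_ladder)) stop("rank_ladder must be non-empty")
  if (!file.exists(path)) stop("no such file: ", path)
  x <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                         colClasses = "character")
  if (!"tax_id" %in% names(x)) stop("lineage table needs a tax_id column")
  if (!"dataset_id" %in% names(x)) x$dataset_id <- x$tax_id
  if (anyDuplicated(x$dataset_id)) stop("duplicate dataset_id in ", path)
  keep <- c("dataset_id", intersect(c("source_kind"), names(x)))
  dropped <- setdiff(names(x), c(keep, rank_ladder))
  if (length(dropped))
    message("dropping non-ladder columns: ", paste(dropped, collapse = ", "))
  for (r in setdiff(rank_ladder, names(x))) x[[r]] <- NA_character_
  out <- x[c(keep, rank_ladder)]
  for (r in rank_ladder)
    out[[r]][!is.na(out[[r]]) & !nzchar(trimws(out[[r]]))] <- NA_character_
  for (ds in names(overrides)) {
    i <- match(ds, out$dataset_id)
    if (is.na(i)) stop("override for unknown dataset: ", ds)
    ov <- overrides[[ds]]
    if (!ov[1] %in% rank_ladder)
      stop("override rank not in ladder: ", ov[1])
    out[[ov[1]]][i] <- ov[2]
  }
  rownames(out) <- NULL
  out
}

.HH_COLS <- c("query", "target", "probability", "evalue", "score",
              "qstart", "qend", "tstart", "tend", "alnlen", "qlen", "tlen")

.validateHomologyChunk <- function(x, offset) {
  num <- setdiff(.HH_COLS, c("query", "target"))
  for (cc in num) x[[cc]] <- as.numeric(x[[cc]])
  ok <- x$probability >= 0 & x$probability <= 100 &
    x$qstart >= 1 & x$qstart <= x$qend & x$qend <= x$qlen &
    x$tstart >= 1 & x$tstart <= x$tend & x$tend <= x$tlen &
    x$alnlen >= 1
  ok[is.na(ok)] <- FALSE
  if (any(!ok))
    warning(sum(!ok), " invalid homology hit row(s) rejected near line ",
            offset + which(!ok)[1], call. = FALSE)
  x[ok, , drop = FALSE]
}

#' Read an HMM-HMM homology hit table
#'
#' hhblits-style TSV with columns `query, target, probability, evalue,
#' score, qstart, qend, tstart, tend, alnlen, qlen, tlen` (probability on
#' the 0-100 percent scale; coordinates 1-based inclusive). Rows with
#' out-of-range probability or coordinates are rejected with a warning.
#'
#' For large files supply `callback`: the file is then streamed in chunks of
#' `chunkSize` rows, `callback(chunk)` is invoked per validated chunk, and
#' only per-chunk memory is used; the function returns the number of rows
#' accepted instead of the full table.
#'
#' @param path TSV file path (header required).
#' @param chunkSize rows per chunk when streaming (default 50000).
#' @param callback optional function of one data.frame argument.
#' @return data.frame of validated hits, or (with `callback`) the integer
#'   count of accepted rows.
#' @export
readHomologyHits <- function(path, chunkSize = 50000L, callback = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(.HH_COLS, header)
  if (length(miss))
    stop("homology hit table missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(header, .HH_COLS)
  if (length(extra))
    message("ignoring extra columns: ", paste(extra, collapse = ", "))
  if (is.null(callback)) {
    x <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE)
    return(.validateHomologyChunk(x[.HH_COLS], offset = 1L))
  }
  con <- file(path, open = "r")
  on.exit(close(con))
  readLines(con, n = 1L)  # consume header
  total <- 0L; offset <- 1L
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (!length(lines)) break
    x <- read.table(text = lines, sep = "\t", header = FALSE,
                    col.names = header, stringsAsFactors = FALSE)
    x <- .validateHomologyChunk(x[.HH_COLS], offset = offset)
    offset <- offset + length(lines)
    total <- total + nrow(x)
    callback(x)
  }
  total
}
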