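#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open, the BED convention used internally
#' everywhere in the package.
#'
#' @param contig character vector of contig names.
#' @param start,end integer vectors; `end` is exclusive and must exceed
#'   `start`.
#' @param label optional label (recycled).
#' @return data frame with columns `contig`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(contig, start, end, label = NA_character_) {
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    label = rep_len(as.character(label), length(contig)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
}

validate_intervals <- function(df) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(df)
  if (any(is.na(df$contig) | df$contig == ""))
    stop("interval with empty contig name")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("interval with end <= start at record ", bad[1],
         " (", df$contig[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")")
  df
}

#' Read a BED track
#'
#' @param path BED3+ file; columns beyond the fourth are ignored.
#' @param label label attached to every interval; when `NULL` the fourth BED
#'   column is used if present.
#' @return interval data frame as from [genomic_intervals()]. Overlapping
#'   input intervals are preserved as-is.
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t| +")
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 3))
    stop("BED record with fewer than 3 columns at line ", which(ncols < 3)[1])
  contig <- vapply(fields, `[[`, character(1), 1)
  start <- as.integer(vapply(fields, `[[`, character(1), 2))
  end <- as.integer(vapply(fields, `[[`, character(1), 3))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  lab <- if (!is.null(label)) label
         else ifelse(ncols >= 4, vapply(fields, function(f)
           if (length(f) >= 4) f[[4]] else NA_character_, character(1)),
           NA_character_)
  genomic_intervals(contig, start, end, lab)
}

#' Write intervals to BED
#'
#' @param intervals interval data frame.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  lab <- intervals$label %||% NA_character_
  has_lab <- !all(is.na(lab))
  lines <- if (has_lab)
    paste(intervals$contig, intervals$start, intervals$end,
          ifelse(is.na(lab), ".", lab), sep = "\t")
  else
    paste(intervals$contig, intervals$start, intervals$end, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# 0-based half-open data frame -> GRanges (1-based closed internally).
as_granges <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# Logical: does each query interval intersect any subject interval?
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject)) > 0
}

#' Harmonize contig naming
#'
#' Reference builds differ in whether contigs carry a `chr` prefix; this
#' switch converts between the two styles at the ingestion boundary.
#'
#' @param x character vector of contig names.
#' @param style `"none"` (leave as-is), `"strip_chr"` or `"add_chr"`.
#' @return character vector.
#' @export
harmonize_contigs <- function(x, style = c("none", "strip_chr", "add_chr")) {
  style <- match.arg(style)
  switch(style,
    none = x,
    strip_chr = sub("^chr", "", x),
    add_chr = ifelse(grepl("^chr", x), x, paste0("chr", x))
  )
}
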