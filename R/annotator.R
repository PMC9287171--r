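#' Construct a homopolymer track
#'
#' Two interval sets mirroring the GIAB stratifications used for nanopore
#' indel error context: long homopolymers (>6 bp perfect or >10 bp
#' imperfect, with slop) and short 4-6 bp homopolymers. The two lists may
#' overlap each other.
#'
#' @param long_intervals,short_intervals interval data frames
#'   (0-based half-open).
#' @return object of class `homopolymer_track`.
#' @export
homopolymer_track <- function(long_intervals = NULL, short_intervals = NULL) {
  empty <- genomic_intervals(character(), integer(), integer())
  out <- list(long = validate_intervals(long_intervals %||% empty),
              short = validate_intervals(short_intervals %||% empty))
  class(out) <- "homopolymer_track"
  out
}

# Extend intervals 1 bp to the left (floor at 0). VCF anchors insertions at
# the previous base, so a track interval starting at x must also capture an
# insertion anchored at x - 1.
extend_left <- function(intervals, bp = 1L) {
  if (nrow(intervals) == 0) return(intervals)
  intervals$start <- pmax(0L, intervals$start - as.integer(bp))
  intervals
}

#' Flag variants in homopolymer context
#'
#' Each variant whose affected span (the single anchor base for insertions,
#' the full reference span otherwise) intersects a long-track interval
#' extended 1 bp to the left gains the `"Homopolymer"` flag; intersection
#' with an extended short-track interval gains `"ShortHomopolymer"`. Both
#' flags may co-occur. Partial overlap counts as overlap. No variant is
#' dropped, reordered, or otherwise modified; the operation is idempotent.
#'
#' @param variants `small_variants` data frame.
#' @param track `homopolymer_track`; `NULL` is the identity.
#' @return the annotated `small_variants` data frame.
#' @export
annotate_homopolymer <- function(variants, track = NULL) {
  if (is.null(track) || nrow(variants) == 0) return(variants)
  span <- affected_span(variants)
  hit_long <- overlaps_any(span, extend_left(track$long))
  hit_short <- overlaps_any(span, extend_left(track$short))
  variants$annotations <- lapply(seq_len(nrow(variants)), function(i) {
    fl <- variants$annotations[[i]]
    if (hit_long[i]) fl <- union(fl, "Homopolymer")
    if (hit_short[i]) fl <- union(fl, "ShortHomopolymer")
    fl
  })
  variants
}

#' Read a position-keyed annotation table
#'
#' TSV with columns `contig`, `pos`, `ref`, `alt` and one value column
#' (e.g. `clinvar`, `hgmd`, `maf`). Alleles are normalized before keying.
#' Duplicate keys carrying conflicting values are an error at load time.
#'
#' @param path TSV file.
#' @param value_col name of the value column.
#' @return data frame with a `key` column and the value column.
#' @export
read_annotation_table <- function(path, value_col) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "ref", "alt", value_col) %in% names(tab)))
  annotation_table(tab, value_col)
}

#' Build an annotation table from a data frame
#'
#' @param tab data frame with `contig`, `pos`, `ref`, `alt` and `value_col`.
#' @param value_col name of the value column.
#' @return keyed annotation table.
#' @export
annotation_table <- function(tab, value_col) {
  if (nrow(tab) > 0) {
    norm <- normalize_alleles(as.integer(tab$pos), toupper(tab$ref),
                              toupper(tab$alt))
    tab$key <- variant_key(tab$contig, norm$pos, norm$ref, norm$alt)
    dup <- tab$key[duplicated(tab$key)]
    for (k in unique(dup)) {
      vals <- unique(tab[[value_col]][tab$key == k])
      if (length(vals) > 1)
        stop("conflicting values for key ", k, " in annotation table")
    }
    tab <- tab[!duplicated(tab$key), , drop = FALSE]
  } else {
    tab$key <- character(0)
  }
  attr(tab, "value_col") <- value_col
  tab
}

lookup_key <- function(keys, tab) {
  if (is.null(tab) || nrow(tab) == 0)
    return(rep(NA_character_, length(keys)))
  vc <- attr(tab, "value_col")
  idx <- match(keys, tab$key)
  vals <- tab[[vc]][idx]
  as.character(vals)
}

#' Attach database annotations to variants
#'
#' Populates `clinvar`, `hgmd`, `maf`, `gene` and (when a `consequence`
#' table column exists in any supplied table) `consequence` by exact
#' normalized-key lookup; gene symbols come from transcript-span overlap
#' with the gene model. Lookup is allele-aware: a different alternate
#' allele at the same site does not annotate. Variants outside any
#' transcript keep `gene = NA`. Idempotent; never drops or reorders.
#'
#' @param variants `small_variants` data frame.
#' @param clinvar_table,hgmd_table,af_table annotation tables from
#'   [annotation_table()] (value columns `clinvar`, `hgmd`, `maf`), or
#'   `NULL`.
#' @param gene_model `gene_model` or `NULL`.
#' @return annotated `small_variants` data frame.
#' @export
annotate_databases <- function(variants, clinvar_table = NULL,
                               hgmd_table = NULL, af_table = NULL,
                               gene_model = NULL) {
  if (nrow(variants) == 0) return(variants)
  keys <- variant_key(variants$contig, variants$pos, variants$ref,
                      variants$alt)
  if (!is.null(clinvar_table)) {
    hit <- lookup_key(keys, clinvar_table)
    variants$clinvar <- ifelse(is.na(hit), variants$clinvar, hit)
  }
  if (!is.null(hgmd_table)) {
    hit <- lookup_key(keys, hgmd_table)
    hit <- sub("^DMq$", "DM?", hit)
    variants$hgmd <- ifelse(is.na(hit), variants$hgmd, hit)
  }
  if (!is.null(af_table)) {
    hit <- suppressWarnings(as.numeric(lookup_key(keys, af_table)))
    variants$maf <- ifelse(is.na(hit), variants$maf, hit)
  }
  if (!is.null(gene_model)) {
    g <- gene_at(variants$contig, variants$pos - 1L, gene_model)
    variants$gene <- ifelse(is.na(g), variants$gene, g)
  }
  validate_small_variants(variants)
}
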