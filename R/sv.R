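SVTYPES <- c("DEL", "DUP", "INV", "INS", "BND")

#' Build a structural-variant table
#'
#' Breakpoint coordinates are 0-based half-open; insertions occupy the
#' single anchor base (`end = start + 1`). `size` is the absolute event
#' length in bp (for insertions, the inserted length).
#'
#' @param contig,start,end breakpoint span (0-based half-open).
#' @param svtype one of `DEL`, `DUP`, `INV`, `INS`, `BND`.
#' @param size event length in bp; `NA` allowed for BND only.
#' @param id record identifier.
#' @param catalog_af optional population allele frequency.
#' @param genes list column of overlapping gene symbols.
#' @param tier optional integer in 1..3.
#' @param min_size SV definition floor (default 50 bp); smaller non-BND
#'   records are rejected.
#' @return data frame of class `sv_records`.
#' @export
sv_records <- function(contig, start, end, svtype, size,
                       id = NULL, catalog_af = NA_real_, genes = NULL,
                       tier = NA_integer_, min_size = 50L) {
  n <- length(start)
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    svtype = as.character(svtype),
    size = as.integer(size),
    id = if (is.null(id)) sprintf("sv%05d", seq_len(n)) else as.character(id),
    catalog_af = rep_len(as.numeric(catalog_af), n),
    tier = rep_len(as.integer(tier), n),
    stringsAsFactors = FALSE
  )
  df$genes <- if (is.null(genes)) rep(list(character()), n) else genes
  class(df) <- c("sv_records", "data.frame")
  validate_sv_records(df, min_size = min_size)
}

validate_sv_records <- function(df, min_size = 50L) {
  if (nrow(df) == 0) return(df)
  if (any(!df$svtype %in% SVTYPES)) stop("invalid svtype")
  non_bnd <- df$svtype != "BND"
  if (any(non_bnd & is.na(df$size))) stop("non-BND record without size")
  if (any(non_bnd & df$size < min_size))
    stop("SV smaller than the ", min_size, " bp size floor")
  span_types <- df$svtype %in% c("DEL", "DUP", "INV")
  bad <- span_types & (df$end - df$start != df$size)
  if (any(bad))
    stop("DEL/DUP/INV record where size != end - start (record ",
         which(bad)[1], ")")
  ins_bad <- df$svtype == "INS" & (df$end != df$start + 1L)
  if (any(ins_bad)) stop("INS record where end != start + 1")
  af <- df$catalog_af
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("catalog_af outside [0,1]")
  df
}

#' Read structural variants from a VCF
#'
#' Consumes long-read SV-caller conventions: `SVTYPE`, `SVLEN` (sign
#' ignored) and/or `END` INFO keys. Coordinates are converted to 0-based
#' half-open: a deletion at POS 101 with `END=200` becomes the span
#' `[100, 200)`. Non-BND records lacking both `SVLEN` and `END` are
#' rejected with a warning. An `AF` INFO key populates `catalog_af`.
#'
#' @param path VCF file.
#' @param contig_style see [harmonize_contigs()].
#' @param min_size SV size floor (default 50 bp).
#' @return `sv_records` data frame.
#' @export
read_sv_vcf <- function(path, contig_style = "none", min_size = 50L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  empty <- sv_records(character(), integer(), integer(), character(), integer(),
                      min_size = min_size)
  if (is.null(fix) || nrow(fix) == 0) return(empty)
  rows <- vector("list", 0)
  for (i in seq_len(nrow(fix))) {
    info <- parse_info_field(fix[i, "INFO"])
    svtype <- info$SVTYPE
    if (is.null(svtype)) {
      warning("record at line ", i, " lacks SVTYPE; skipped")
      next
    }
    pos <- as.integer(fix[i, "POS"])
    start <- pos - 1L
    svlen <- if (!is.null(info$SVLEN)) abs(as.integer(info$SVLEN)) else NA_integer_
    endpos <- if (!is.null(info$END)) as.integer(info$END) else NA_integer_
    if (svtype == "BND") {
      rows[[length(rows) + 1L]] <- list(contig = fix[i, "CHROM"], start = start,
        end = start + 1L, svtype = "BND", size = NA_integer_,
        id = fix[i, "ID"] %||% NA_character_,
        af = if (is.null(info$AF)) NA_real_ else as.numeric(info$AF))
      next
    }
    if (is.na(svlen) && is.na(endpos)) {
      warning("record at ", fix[i, "CHROM"], ":", pos,
              " lacks both SVLEN and END; rejected")
      next
    }
    if (svtype == "INS") {
      size <- svlen
      if (is.na(size)) {
        warning("INS at ", fix[i, "CHROM"], ":", pos, " lacks SVLEN; rejected")
        next
      }
      end <- start + 1L
    } else {
      end <- if (!is.na(endpos)) endpos else start + svlen
      size <- end - start
    }
    rows[[length(rows) + 1L]] <- list(contig = fix[i, "CHROM"], start = start,
      end = end, svtype = svtype, size = size,
      id = if (is.na(fix[i, "ID"])) sprintf("sv%05d", i) else fix[i, "ID"],
      af = if (is.null(info$AF)) NA_real_ else as.numeric(info$AF))
  }
  if (length(rows) == 0) return(empty)
  sv_records(
    contig = harmonize_contigs(
      vapply(rows, function(r) r$contig, character(1)), contig_style),
    start = vapply(rows, function(r) r$start, integer(1)),
    end = vapply(rows, function(r) r$end, integer(1)),
    svtype = vapply(rows, function(r) r$svtype, character(1)),
    size = vapply(rows, function(r) as.integer(r$size), integer(1)),
    id = vapply(rows, function(r) as.character(r$id), character(1)),
    catalog_af = vapply(rows, function(r) r$af, numeric(1)),
    min_size = min_size
  )
}

#' Write structural variants to a VCF
#'
#' Emits `SVTYPE`, `SVLEN` (negative for deletions, caller convention) and
#' `END`; insertions are anchored at `start + 1` with no `END`.
#'
#' @param svs `sv_records` data frame.
#' @param path output file.
#' @export
write_sv_vcf <- function(svs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Catalog allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  body <- vapply(seq_len(nrow(svs)), function(i) {
    s <- svs[i, ]
    info <- paste0("SVTYPE=", s$svtype)
    if (s$svtype == "INS") {
      info <- paste0(info, ";SVLEN=", s$size)
    } else if (s$svtype != "BND") {
      svlen <- if (s$svtype == "DEL") -s$size else s$size
      info <- paste0(info, ";SVLEN=", svlen, ";END=", s$end)
    }
    if (!is.na(s$catalog_af))
      info <- paste0(info, ";AF=", format(s$catalog_af, digits = 17))
    alt <- paste0("<", s$svtype, ">")
    paste(s$contig, s$start + 1L, s$id, "N", alt, ".", "PASS", info,
          "GT", "0/1", sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
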