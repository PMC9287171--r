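VTYPES <- c("SNP", "INS", "DEL", "MNP")
GENOTYPES <- c("het", "hom_alt")
CONSEQUENCES <- c("LOF", "missense", "synonymous", "splice_region", "noncoding")
CLINVAR_CLASSES <- c("P", "LP", "VUS", "LB", "B")
HGMD_CLASSES <- c("DM", "DM?")

#' Build a small-variant table
#'
#' One row per normalized alternate allele. `pos` is the 1-based VCF anchor
#' position; `annotations` is a list column of character flag sets (e.g.
#' `"Homopolymer"`, `"ShortHomopolymer"`).
#'
#' @param contig,pos,ref,alt core allele description (`pos` 1-based).
#' @param genotype `"het"` or `"hom_alt"`.
#' @param qual call quality (may be `NA`).
#' @param gene,consequence,maf,clinvar,hgmd,insilico_deleterious optional
#'   annotation fields (`NA` when absent). `hgmd` is `"DM"` or `"DM?"`.
#' @param annotations list of character vectors of flags.
#' @param normalize trim shared prefix/suffix bases before storing
#'   (default `TRUE`); positional database keys require normalized alleles.
#' @return data frame of class `small_variants`.
#' @export
small_variants <- function(contig, pos, ref, alt,
                           genotype = "het", qual = NA_real_,
                           gene = NA_character_, consequence = NA_character_,
                           maf = NA_real_, clinvar = NA_character_,
                           hgmd = NA_character_,
                           insilico_deleterious = NA,
                           annotations = NULL, normalize = TRUE) {
  n <- length(pos)
  contig <- rep_len(as.character(contig), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  pos <- as.integer(pos)
  if (normalize && n > 0) {
    norm <- normalize_alleles(pos, ref, alt)
    pos <- norm$pos; ref <- norm$ref; alt <- norm$alt
  }
  df <- data.frame(
    contig = contig,
    pos = pos,
    ref = ref,
    alt = alt,
    vtype = classify_vtype(ref, alt),
    genotype = rep_len(as.character(genotype), n),
    qual = rep_len(as.numeric(qual), n),
    gene = rep_len(as.character(gene), n),
    consequence = rep_len(as.character(consequence), n),
    maf = rep_len(as.numeric(maf), n),
    clinvar = rep_len(as.character(clinvar), n),
    hgmd = rep_len(as.character(hgmd), n),
    insilico_deleterious = rep_len(as.logical(insilico_deleterious), n),
    stringsAsFactors = FALSE
  )
  df$annotations <- if (is.null(annotations)) rep(list(character()), n)
                    else annotations
  class(df) <- c("small_variants", "data.frame")
  validate_small_variants(df)
}

validate_small_variants <- function(df) {
  if (nrow(df) == 0) return(df)
  if (any(df$pos < 1)) stop("variant with pos < 1")
  if (any(!df$vtype %in% VTYPES)) stop("invalid vtype")
  if (any(!df$genotype %in% GENOTYPES)) stop("invalid genotype")
  bad_maf <- !is.na(df$maf) & (df$maf < 0 | df$maf > 1)
  if (any(bad_maf)) stop("maf outside [0,1]")
  cq <- df$consequence
  if (any(!is.na(cq) & !cq %in% CONSEQUENCES)) stop("invalid consequence")
  if (any(!is.na(df$clinvar) & !df$clinvar %in% CLINVAR_CLASSES))
    stop("invalid clinvar class")
  if (any(!is.na(df$hgmd) & !df$hgmd %in% HGMD_CLASSES))
    stop("invalid hgmd class")
  df
}

#' Classify variant type from allele lengths
#'
#' @param ref,alt allele strings (single alt per element).
#' @return `"SNP"`, `"MNP"`, `"INS"` or `"DEL"`.
#' @export
classify_vtype <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1L, "SNP", "MNP"),
         ifelse(la > lr, "INS", "DEL"))
}

#' Normalize alleles by prefix/suffix trimming
#'
#' Trims shared trailing bases, then shared leading bases (advancing `pos`),
#' always retaining at least one base of each allele. This yields the
#' canonical representation used for positional database keys.
#'
#' @param pos 1-based positions.
#' @param ref,alt allele strings.
#' @return list with components `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1L)
      a <- substr(a, 1, nchar(a) - 1L)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- as.integer(p)
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Affected reference span of small variants
#'
#' The 0-based half-open span a variant is considered to touch for interval
#' annotation: the full reference span for SNP/MNP/DEL, and the single
#' anchor base for insertions (the VCF previous-base convention).
#'
#' @param variants `small_variants` data frame.
#' @return interval data frame (one row per variant, same order).
#' @export
affected_span <- function(variants) {
  start <- variants$pos - 1L
  end <- ifelse(variants$vtype == "INS", start + 1L,
                start + nchar(variants$ref))
  data.frame(contig = variants$contig, start = as.integer(start),
             end = as.integer(end), label = NA_character_,
             stringsAsFactors = FALSE)
}

# -- VCF ingestion ----------------------------------------------------------

parse_info_field <- function(info) {
  out <- list()
  if (is.na(info) || info == "." || info == "") return(out)
  for (part in strsplit(info, ";", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1) kv[2] else TRUE
  }
  out
}

#' Read small variants from a single-sample VCF
#'
#' Multiallelic records are split into one row per alternate allele; alleles
#' are normalized by prefix/suffix trimming. Annotation INFO keys
#' (`GENE`, `CONSEQUENCE`, `MAF`, `CLINVAR`, `HGMD`, `DELETERIOUS`,
#' `HOMOPOLYMER`, `SHORT_HOMOPOLYMER`) are read when present. Records
#' without a genotype are skipped with a warning. Input order is preserved.
#'
#' @param path VCF 4.x file with a GT field for one sample.
#' @param contig_style contig-name harmonization, see [harmonize_contigs()].
#' @return `small_variants` data frame.
#' @export
read_small_variants <- function(path, contig_style = "none") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0)
    return(small_variants(character(), integer(), character(), character()))
  pos_num <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos_num))
    stop("malformed VCF: non-numeric POS at data line ", which(is.na(pos_num))[1])
  gt <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "GT") else
    stop("VCF has no sample genotype column")
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    g <- gt[i, 1]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      warning("record at ", fix[i, "CHROM"], ":", fix[i, "POS"],
              " has no genotype; skipped")
      next
    }
    alleles <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info_field(fix[i, "INFO"])
    flags <- c(if (isTRUE(info$HOMOPOLYMER)) "Homopolymer",
               if (isTRUE(info$SHORT_HOMOPOLYMER)) "ShortHomopolymer")
    for (ai in seq_along(alts)) {
      geno <- if (all(!is.na(alleles)) && all(alleles == ai)) "hom_alt" else "het"
      rows[[length(rows) + 1L]] <- list(
        contig = fix[i, "CHROM"], pos = pos_num[i],
        ref = fix[i, "REF"], alt = alts[ai], genotype = geno,
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        gene = info$GENE %||% NA_character_,
        consequence = info$CONSEQUENCE %||% NA_character_,
        maf = if (is.null(info$MAF)) NA_real_ else as.numeric(info$MAF),
        clinvar = info$CLINVAR %||% NA_character_,
        hgmd = if (is.null(info$HGMD)) NA_character_
               else sub("^DMq$", "DM?", info$HGMD),
        insilico_deleterious = if (isTRUE(info$DELETERIOUS)) TRUE else NA,
        flags = list(flags %||% character())
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(small_variants(character(), integer(), character(), character()))
  get_chr <- function(f) vapply(rows, function(r) as.character(r[[f]]), character(1))
  get_num <- function(f) vapply(rows, function(r) as.numeric(r[[f]]), numeric(1))
  small_variants(
    contig = harmonize_contigs(get_chr("contig"), contig_style),
    pos = get_num("pos"), ref = get_chr("ref"), alt = get_chr("alt"),
    genotype = get_chr("genotype"), qual = get_num("qual"),
    gene = get_chr("gene"), consequence = get_chr("consequence"),
    maf = get_num("maf"), clinvar = get_chr("clinvar"),
    hgmd = get_chr("hgmd"),
    insilico_deleterious = vapply(rows, function(r)
      as.logical(r$insilico_deleterious), logical(1)),
    annotations = lapply(rows, function(r) r$flags[[1]])
  )
}

format_info <- function(v) {
  parts <- character()
  if (!is.na(v$gene)) parts <- c(parts, paste0("GENE=", v$gene))
  if (!is.na(v$consequence)) parts <- c(parts, paste0("CONSEQUENCE=", v$consequence))
  if (!is.na(v$maf)) parts <- c(parts, paste0("MAF=", format(v$maf, digits = 17)))
  if (!is.na(v$clinvar)) parts <- c(parts, paste0("CLINVAR=", v$clinvar))
  if (!is.na(v$hgmd)) parts <- c(parts, paste0("HGMD=", sub("DM\\?", "DMq", v$hgmd)))
  if (isTRUE(v$insilico_deleterious)) parts <- c(parts, "DELETERIOUS")
  fl <- v$annotations[[1]]
  if ("Homopolymer" %in% fl) parts <- c(parts, "HOMOPOLYMER")
  if ("ShortHomopolymer" %in% fl) parts <- c(parts, "SHORT_HOMOPOLYMER")
  if (length(parts) == 0) "." else paste(parts, collapse = ";")
}

#' Write small variants to a single-sample VCF
#'
#' Inverse of [read_small_variants()]: annotation fields and flags are
#' emitted as INFO keys, the genotype as a GT sample column.
#'
#' @param variants `small_variants` data frame.
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @export
write_small_variants <- function(variants, path, sample = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description=\"Coding consequence\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##INFO=<ID=CLINVAR,Number=1,Type=String,Description=\"ClinVar-style classification\">",
    "##INFO=<ID=HGMD,Number=1,Type=String,Description=\"HGMD-style annotation (DM or DMq)\">",
    "##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description=\"Predicted deleterious in silico\">",
    "##INFO=<ID=HOMOPOLYMER,Number=0,Type=Flag,Description=\"Overlaps long homopolymer track\">",
    "##INFO=<ID=SHORT_HOMOPOLYMER,Number=0,Type=Flag,Description=\"Overlaps 4-6 bp homopolymer track\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    paste(v$contig, v$pos, ".", v$ref, v$alt,
          if (is.na(v$qual)) "." else format(v$qual, digits = 17),
          "PASS", format_info(v), "GT",
          if (v$genotype == "hom_alt") "1/1" else "0/1",
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
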