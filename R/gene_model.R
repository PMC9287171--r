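#' Build a gene model
#'
#' An interval hierarchy per protein-coding gene: transcript span, CDS
#' blocks, derived UTRs (transcript span outside the CDS extent), derived
#' introns (gaps between CDS blocks) and a derived strand-aware promoter
#' upstream of the transcription start site. All coordinates 0-based
#' half-open. Without full exon structure, non-coding exons are not
#' distinguished from introns; UTRs are approximated as the transcript
#' termini flanking the CDS extent.
#'
#' @param genes data frame with columns `gene`, `contig`, `strand` (`+`/`-`),
#'   `tx_start`, `tx_end`, `omim_inheritance` (`AR`, `AD`, `XL`, `other` or
#'   `NA`).
#' @param cds data frame with columns `gene`, `contig`, `start`, `end`
#'   (one row per CDS block).
#' @param promoter_size promoter length upstream of the TSS in bp
#'   (default 2000).
#' @return object of class `gene_model`: list with elements `genes`, `cds`,
#'   `utr`, `intron`, `promoter` (interval data frames carrying a `gene`
#'   column).
#' @export
gene_model <- function(genes, cds, promoter_size = 2000L) {
  stopifnot(all(c("gene", "contig", "strand", "tx_start", "tx_end") %in% names(genes)))
  if (!"omim_inheritance" %in% names(genes))
    genes$omim_inheritance <- NA_character_
  utr <- list(); intron <- list(); promoter <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    blocks <- cds[cds$gene == g$gene, , drop = FALSE]
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (nrow(blocks) > 0) {
      if (min(blocks$start) < g$tx_start || max(blocks$end) > g$tx_end)
        stop("CDS outside transcript span for gene ", g$gene)
      if (g$tx_start < min(blocks$start))
        utr[[length(utr) + 1L]] <- data.frame(gene = g$gene, contig = g$contig,
          start = g$tx_start, end = min(blocks$start))
      if (max(blocks$end) < g$tx_end)
        utr[[length(utr) + 1L]] <- data.frame(gene = g$gene, contig = g$contig,
          start = max(blocks$end), end = g$tx_end)
      if (nrow(blocks) > 1) {
        for (j in seq_len(nrow(blocks) - 1L)) {
          if (blocks$end[j] < blocks$start[j + 1L])
            intron[[length(intron) + 1L]] <- data.frame(gene = g$gene,
              contig = g$contig, start = blocks$end[j],
              end = blocks$start[j + 1L])
        }
      }
    }
    pstart <- if (g$strand == "+") max(0L, g$tx_start - promoter_size)
              else g$tx_end
    pend <- if (g$strand == "+") g$tx_start else g$tx_end + promoter_size
    if (pend > pstart)
      promoter[[length(promoter) + 1L]] <- data.frame(gene = g$gene,
        contig = g$contig, start = as.integer(pstart), end = as.integer(pend))
  }
  bind_or_empty <- function(lst) {
    if (length(lst) == 0)
      return(data.frame(gene = character(), contig = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    do.call(rbind, lst)
  }
  out <- list(genes = genes,
              cds = cds[, c("gene", "contig", "start", "end")],
              utr = bind_or_empty(utr),
              intron = bind_or_empty(intron),
              promoter = bind_or_empty(promoter),
              promoter_size = promoter_size)
  class(out) <- "gene_model"
  out
}

#' Read a gene model from TSV
#'
#' Expected columns: `gene`, `contig`, `strand`, `tx_start`, `tx_end`,
#' `cds_starts`, `cds_ends` (comma-separated 0-based block coordinates) and
#' `omim_inheritance`.
#'
#' @param path TSV file.
#' @param promoter_size see [gene_model()].
#' @return `gene_model` object.
#' @export
read_gene_model <- function(path, promoter_size = 2000L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = list(cds_starts = "character",
                                             cds_ends = "character"))
  cds <- list()
  for (i in seq_len(nrow(tab))) {
    starts <- as.integer(strsplit(tab$cds_starts[i], ",")[[1]])
    ends <- as.integer(strsplit(tab$cds_ends[i], ",")[[1]])
    if (length(starts) != length(ends))
      stop("gene ", tab$gene[i], ": mismatched CDS block lists")
    cds[[i]] <- data.frame(gene = tab$gene[i], contig = tab$contig[i],
                           start = starts, end = ends,
                           stringsAsFactors = FALSE)
  }
  gene_model(tab[, c("gene", "contig", "strand", "tx_start", "tx_end",
                     "omim_inheritance")],
             do.call(rbind, cds), promoter_size = promoter_size)
}

#' Write a gene model to TSV
#'
#' @param model `gene_model` object.
#' @param path output file.
#' @export
write_gene_model <- function(model, path) {
  tab <- model$genes
  tab$cds_starts <- vapply(tab$gene, function(g) {
    b <- model$cds[model$cds$gene == g, , drop = FALSE]
    paste(b$start[order(b$start)], collapse = ",")
  }, character(1))
  tab$cds_ends <- vapply(tab$gene, function(g) {
    b <- model$cds[model$cds$gene == g, , drop = FALSE]
    paste(b$end[order(b$start)], collapse = ",")
  }, character(1))
  utils::write.table(
    tab[, c("gene", "contig", "strand", "tx_start", "tx_end",
            "cds_starts", "cds_ends", "omim_inheritance")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes with a given OMIM inheritance label
#'
#' @param model `gene_model` object.
#' @param inheritance label to select (default `"AR"`).
#' @return character vector of gene symbols.
#' @export
omim_genes <- function(model, inheritance = "AR") {
  g <- model$genes
  g$gene[!is.na(g$omim_inheritance) & g$omim_inheritance == inheritance]
}

# Assign each position the symbol of the transcript span containing it
# (first gene in tx_start order when several overlap), NA outside genes.
gene_at <- function(contig, pos0, model) {
  g <- model$genes[order(model$genes$contig, model$genes$tx_start), ,
                   drop = FALSE]
  out <- rep(NA_character_, length(pos0))
  if (nrow(g) == 0 || length(pos0) == 0) return(out)
  q <- GenomicRanges::GRanges(contig,
                              IRanges::IRanges(pos0 + 1L, pos0 + 1L))
  s <- GenomicRanges::GRanges(g$contig,
                              IRanges::IRanges(g$tx_start + 1L, g$tx_end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  sel <- !is.na(hits)
  out[sel] <- g$gene[hits[sel]]
  out
}
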