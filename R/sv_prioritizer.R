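#' Match two structural variants
#'
#' Two SVs of the same type on the same contig match when, for deletions,
#' duplications and inversions, the reciprocal overlap exceeds `min_recip`
#' (strict, both ratios), or, for insertions, the smaller size is at least
#' `min_size_sim` of the larger (inclusive) and the anchor starts lie
#' within `max_ins_dist` bp of each other (strict). BND records never
#' match. The relation is symmetric.
#'
#' @param a,b single SV records (one-row `sv_records` data frames or
#'   lists with fields `contig`, `start`, `end`, `svtype`, `size`).
#' @param max_ins_dist maximum insertion anchor distance in bp
#'   (default 100, strict `<`).
#' @param min_recip reciprocal-overlap threshold (default 0.5, strict `>`).
#' @param min_size_sim insertion size-similarity threshold (default 0.5,
#'   inclusive `>=`).
#' @return logical.
#' @export
sv_match <- function(a, b, max_ins_dist = 100, min_recip = 0.5,
                     min_size_sim = 0.5) {
  if (a$svtype != b$svtype || a$contig != b$contig) return(FALSE)
  if (a$svtype == "BND") return(FALSE)
  if (a$svtype == "INS") {
    sim <- min(a$size, b$size) / max(a$size, b$size)
    return(sim >= min_size_sim && abs(a$start - b$start) < max_ins_dist)
  }
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(FALSE)
  ov / (a$end - a$start) > min_recip && ov / (b$end - b$start) > min_recip
}

# All matching (call index, catalog/truth index) pairs with a match score:
# min reciprocal-overlap ratio for interval types, size similarity for INS.
sv_match_pairs <- function(calls, others, max_ins_dist = 100,
                           min_recip = 0.5, min_size_sim = 0.5) {
  out <- data.frame(call = integer(), other = integer(), score = numeric())
  if (nrow(calls) == 0 || nrow(others) == 0) return(out)
  for (i in seq_len(nrow(calls))) {
    a <- calls[i, ]
    if (a$svtype == "BND") next
    for (j in seq_len(nrow(others))) {
      b <- others[j, ]
      if (!sv_match(a, b, max_ins_dist, min_recip, min_size_sim)) next
      score <- if (a$svtype == "INS") {
        min(a$size, b$size) / max(a$size, b$size)
      } else {
        ov <- min(a$end, b$end) - max(a$start, b$start)
        min(ov / (a$end - a$start), ov / (b$end - b$start))
      }
      out <- rbind(out, data.frame(call = i, other = j, score = score))
    }
  }
  out
}

#' Remove SVs matching common catalog records
#'
#' A call is removed iff it matches (by [sv_match()]) any catalog record
#' whose allele frequency exceeds `af_threshold`; records at exactly the
#' threshold are retained. Input order is preserved.
#'
#' @param calls `sv_records` data frame.
#' @param catalogs list of `sv_records` data frames with `catalog_af`
#'   populated (an empty list is the identity).
#' @param af_threshold frequency cut-off (default 0.01, strict `>`).
#' @param ... matching parameters passed to [sv_match()].
#' @return the retained subset of `calls`.
#' @export
select_rare <- function(calls, catalogs, af_threshold = 0.01, ...) {
  if (length(catalogs) == 0 || nrow(calls) == 0) return(calls)
  remove <- rep(FALSE, nrow(calls))
  for (cat in catalogs) {
    common <- cat[!is.na(cat$catalog_af) & cat$catalog_af > af_threshold, ,
                  drop = FALSE]
    if (nrow(common) == 0) next
    pairs <- sv_match_pairs(calls, common, ...)
    remove[unique(pairs$call)] <- TRUE
  }
  calls[!remove, , drop = FALSE]
}

#' Assign prioritization tiers to rare SVs
#'
#' Tier 1: the SV span intersects any CDS block (coding SV). Tier 2: it
#' intersects a UTR, promoter or intron of a protein-coding gene. Tier 3:
#' it intersects a conserved element or regulatory element. The tests are
#' evaluated in that order and are exclusive, so every SV receives at most
#' one tier; SVs matching none receive `NA` and are dropped from the
#' report. Within each tier, SVs touching a target-list gene are listed
#' first, then genomic order.
#'
#' @param calls rare `sv_records`.
#' @param gene_model `gene_model`.
#' @param conserved,regulatory interval data frames (0-based half-open).
#' @param target_genes character vector of prioritized gene symbols.
#' @return list with `calls` (tier column set, input order) and `report`
#'   (tiered SVs, ordered tier, target-first, genomic).
#' @export
assign_tiers <- function(calls, gene_model,
                         conserved = NULL, regulatory = NULL,
                         target_genes = character()) {
  empty <- genomic_intervals(character(), integer(), integer())
  conserved <- conserved %||% empty
  regulatory <- regulatory %||% empty
  span <- data.frame(contig = calls$contig, start = calls$start,
                     end = calls$end, stringsAsFactors = FALSE)
  hit_cds <- overlaps_any(span, gene_model$cds)
  noncoding_features <- rbind(
    gene_model$utr[, c("contig", "start", "end")],
    gene_model$promoter[, c("contig", "start", "end")],
    gene_model$intron[, c("contig", "start", "end")])
  hit_t2 <- overlaps_any(span, noncoding_features)
  hit_t3 <- overlaps_any(span, conserved) | overlaps_any(span, regulatory)
  tier <- ifelse(hit_cds, 1L, ifelse(hit_t2, 2L, ifelse(hit_t3, 3L,
                                                        NA_integer_)))
  calls$tier <- tier
  # overlapping genes: transcript span or promoter
  gene_feats <- rbind(
    cbind(gene = gene_model$genes$gene,
          gene_model$genes[, c("contig"),  drop = FALSE],
          start = gene_model$genes$tx_start, end = gene_model$genes$tx_end),
    gene_model$promoter[, c("gene", "contig", "start", "end")])
  if (nrow(calls) > 0 && nrow(gene_feats) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(span),
                                        as_granges(gene_feats))
    calls$genes <- lapply(seq_len(nrow(calls)), function(i) {
      sort(unique(gene_feats$gene[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]))
    })
  }
  report <- calls[!is.na(calls$tier), , drop = FALSE]
  if (nrow(report) > 0) {
    on_target <- vapply(report$genes, function(g)
      any(g %in% target_genes), logical(1))
    report$on_target <- on_target
    report <- report[order(report$tier, !report$on_target, report$contig,
                           report$start), , drop = FALSE]
  }
  list(calls = calls, report = report)
}

#' Evaluate SV calls against a truthset
#'
#' Calls and truth records are first restricted to the confident regions
#' (records not intersecting any confident interval are ignored for both
#' true-positive and false counts); BND records are excluded. Matching is
#' greedy one-to-one per SV type using [sv_match()]: candidate pairs are
#' ranked by best reciprocal overlap (size similarity for insertions),
#' ties broken leftmost, and each call and truth record is consumed at
#' most once. `exact_matches` counts matched pairs with identical start
#' and identical size, the metric used to quantify breakpoint refinement
#' by local assembly.
#'
#' @param calls,truth `sv_records` data frames.
#' @param confident interval data frame of high-confidence regions
#'   (`NULL` keeps everything).
#' @param ... matching parameters passed to [sv_match()].
#' @return object of class `sv_eval`: list with `overall` and `per_type`
#'   data frames of `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `exact_matches`, plus the matched pair table.
#' @export
evaluate_sv <- function(calls, truth, confident = NULL, ...) {
  restrict <- function(x) {
    x <- x[x$svtype != "BND", , drop = FALSE]
    if (is.null(confident) || nrow(x) == 0) return(x)
    keep <- overlaps_any(
      data.frame(contig = x$contig, start = x$start, end = x$end), confident)
    x[keep, , drop = FALSE]
  }
  calls <- restrict(calls)
  truth <- restrict(truth)
  if (nrow(truth) == 0)
    warning("empty truthset within confident regions; recall reported as 0")
  pairs <- sv_match_pairs(calls, truth, ...)
  matched <- data.frame(call = integer(), truth = integer(),
                        exact = logical())
  if (nrow(pairs) > 0) {
    ord <- order(-pairs$score, truth$start[pairs$other],
                 calls$start[pairs$call])
    pairs <- pairs[ord, , drop = FALSE]
    used_call <- rep(FALSE, nrow(calls))
    used_truth <- rep(FALSE, nrow(truth))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$call[k]; j <- pairs$other[k]
      if (used_call[i] || used_truth[j]) next
      used_call[i] <- TRUE; used_truth[j] <- TRUE
      matched <- rbind(matched, data.frame(
        call = i, truth = j,
        exact = calls$start[i] == truth$start[j] &&
          calls$size[i] == truth$size[j]))
    }
  }
  metrics_for <- function(keep_call, keep_truth) {
    m <- matched[matched$call %in% which(keep_call), , drop = FALSE]
    tp <- nrow(m)
    fp <- sum(keep_call) - tp
    fn <- sum(keep_truth) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
               recall = recall, f1 = f1, exact_matches = sum(m$exact))
  }
  types <- sort(unique(c(calls$svtype, truth$svtype)))
  per_type <- do.call(rbind, lapply(types, function(tt) {
    cbind(svtype = tt,
          metrics_for(calls$svtype == tt, truth$svtype == tt))
  }))
  overall <- metrics_for(rep(TRUE, nrow(calls)), rep(TRUE, nrow(truth)))
  out <- list(overall = overall, per_type = per_type, matched = matched,
              n_calls = nrow(calls), n_truth = nrow(truth))
  class(out) <- "sv_eval"
  out
}

#' @export
print.sv_eval <- function(x, ...) {
  cat("SV evaluation:", x$n_calls, "calls vs", x$n_truth, "truth records\n")
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  (tp %d fp %d fn %d, %d exact)\n",
              x$overall$precision, x$overall$recall, x$overall$f1,
              x$overall$tp, x$overall$fp, x$overall$fn,
              x$overall$exact_matches))
  invisible(x)
}

#' Windowed read-depth track with aneuploidy flags
#'
#' Computes mean per-base depth in fixed non-overlapping windows (default
#' 10 kb; the last window of each contig is truncated) from unit-depth
#' alignment spans, the per-contig mean depth, and flags contigs whose
#' mean deviates from the autosome-wide mean by more than a configured
#' fraction, as orthogonal evidence for large CNVs or aneuploidy. Spans
#' extending beyond the contig end are clipped with a warning.
#'
#' @param spans interval data frame of aligned read spans (depth 1 each).
#' @param contig_lengths named integer vector of contig lengths.
#' @param window window size in bp (default 10000).
#' @param aneuploidy_threshold flag when `|contig mean / autosomal mean - 1|`
#'   exceeds this fraction (default 0.25).
#' @param sex_contigs contigs excluded from the autosomal baseline.
#' @return list with `windows` (contig, start, end, depth), `contigs`
#'   (contig, mean_depth, ratio, flagged) and `autosomal_mean`.
#' @export
coverage_windows <- function(spans, contig_lengths, window = 10000L,
                             aneuploidy_threshold = 0.25,
                             sex_contigs = c("chrX", "chrY", "chrM",
                                             "X", "Y", "MT")) {
  stopifnot(!is.null(names(contig_lengths)))
  spans <- spans[spans$contig %in% names(contig_lengths), , drop = FALSE]
  lens <- contig_lengths[spans$contig]
  if (any(spans$end > lens)) {
    warning(sum(spans$end > lens), " span(s) extend beyond the contig end; clipped")
    spans$end <- pmin(spans$end, as.integer(lens))
    spans <- spans[spans$end > spans$start, , drop = FALSE]
  }
  win_rows <- list()
  for (ctg in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ctg]])
    starts <- seq.int(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    s <- spans[spans$contig == ctg, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(s$start + 1L, s$end),
                             width = len)
    v <- IRanges::Views(cov, start = starts + 1L, end = ends)
    win_rows[[ctg]] <- data.frame(contig = ctg, start = starts, end = ends,
                                  depth = IRanges::viewMeans(v),
                                  stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, win_rows)
  rownames(windows) <- NULL
  contigs <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    w <- windows[windows$contig == ctg, , drop = FALSE]
    len <- sum(w$end - w$start)
    data.frame(contig = ctg,
               mean_depth = sum(w$depth * (w$end - w$start)) / len,
               length = len, stringsAsFactors = FALSE)
  }))
  auto <- contigs[!contigs$contig %in% sex_contigs, , drop = FALSE]
  autosomal_mean <- sum(auto$mean_depth * auto$length) / sum(auto$length)
  contigs$ratio <- contigs$mean_depth / autosomal_mean
  contigs$flagged <- abs(contigs$ratio - 1) > aneuploidy_threshold
  list(windows = windows,
       contigs = contigs[, c("contig", "mean_depth", "ratio", "flagged")],
       autosomal_mean = autosomal_mean)
}
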