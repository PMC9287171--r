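#' Build a read-metadata table
#'
#' @param read_id,qscore,barcode per-read metadata; `barcode` is the
#'   demultiplexed barcode call or `"unclassified"`.
#' @param source_sample optional ground-truth sample of origin (used by
#'   contamination simulations).
#' @return data frame of class `read_records`.
#' @export
read_records <- function(read_id, qscore, barcode,
                         source_sample = NA_character_) {
  df <- data.frame(read_id = as.character(read_id),
                   qscore = as.numeric(qscore),
                   barcode = as.character(barcode),
                   source_sample = rep_len(as.character(source_sample),
                                           length(read_id)),
                   stringsAsFactors = FALSE)
  if (any(df$qscore < 0)) stop("negative q score")
  class(df) <- c("read_records", "data.frame")
  df
}

#' Read a read-metadata TSV
#'
#' Columns: `read_id`, `qscore`, `barcode`, optional `source_sample`.
#'
#' @param path TSV file.
#' @return `read_records` data frame.
#' @export
read_reads_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  read_records(tab$read_id, tab$qscore, tab$barcode,
               tab$source_sample %||% NA_character_)
}

#' Write a read-metadata TSV
#'
#' @param reads `read_records` data frame.
#' @param path output file.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Estimate the barcode carryover rate
#'
#' Filters out failed reads (q score strictly below `q_min`; reads at
#' exactly the threshold are retained), then unclassified reads, and
#' reports the fraction of remaining reads whose barcode does not match
#' the expected barcode — the carryover estimate for a re-used flow cell
#' after a nuclease wash. A per-barcode breakdown of the mismatches is
#' included.
#'
#' @param reads `read_records` data frame.
#' @param expected_barcode the barcode of the library loaded on this run.
#' @param q_min q-score pass threshold (default 7; filter is strict `<`).
#' @return object of class `carryover_report`: `total_reads`,
#'   `failed_reads`, `unclassified_reads`, `evaluated_reads`,
#'   `mismatched_reads`, `carryover_rate`, `per_barcode`.
#' @export
carryover_rate <- function(reads, expected_barcode, q_min = 7.0) {
  total <- nrow(reads)
  passed <- reads[reads$qscore >= q_min, , drop = FALSE]
  failed <- total - nrow(passed)
  classified <- passed[passed$barcode != "unclassified", , drop = FALSE]
  unclassified <- nrow(passed) - nrow(classified)
  evaluated <- nrow(classified)
  if (evaluated == 0)
    stop("no evaluated reads after q-score and barcode filtering; ",
         "carryover rate undefined")
  mismatched <- classified[classified$barcode != expected_barcode, ,
                           drop = FALSE]
  per_barcode <- if (nrow(mismatched) > 0) {
    tb <- table(mismatched$barcode)
    data.frame(barcode = names(tb), reads = as.integer(tb),
               rate = as.integer(tb) / evaluated,
               stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = character(), reads = integer(), rate = numeric())
  }
  out <- list(total_reads = total, failed_reads = failed,
              unclassified_reads = unclassified,
              evaluated_reads = evaluated,
              mismatched_reads = nrow(mismatched),
              carryover_rate = nrow(mismatched) / evaluated,
              expected_barcode = expected_barcode,
              per_barcode = per_barcode)
  class(out) <- "carryover_report"
  out
}

#' @export
print.carryover_report <- function(x, ...) {
  cat(sprintf(
    "Carryover: %d/%d evaluated reads mismatched (%.4f%%); %d failed, %d unclassified of %d total\n",
    x$mismatched_reads, x$evaluated_reads, 100 * x$carryover_rate,
    x$failed_reads, x$unclassified_reads, x$total_reads))
  invisible(x)
}

#' Mix contaminant reads into a primary sample
#'
#' Simulates library carryover in silico by adding
#' `round(fraction * nrow(primary))` reads drawn without replacement from
#' the contaminant pool. The fraction is defined relative to the primary
#' sample's read count. `source_sample` is preserved as ground truth.
#' Deterministic for a given seed.
#'
#' @param primary,contaminant `read_records` data frames.
#' @param fraction contamination fraction (default 0.01).
#' @param seed integer RNG seed for the draw.
#' @return combined `read_records` data frame (primary reads first).
#' @export
mix_reads <- function(primary, contaminant, fraction = 0.01, seed = 1L) {
  n_add <- round(fraction * nrow(primary))
  if (n_add > nrow(contaminant))
    stop("contaminant pool too small: need ", n_add, " reads, have ",
         nrow(contaminant))
  if (n_add == 0) return(primary)
  idx <- with_seed(seed, sample.int(nrow(contaminant), n_add))
  out <- rbind(primary, contaminant[idx, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("read_records", "data.frame")
  out
}

#' Read per-contig runtime profiles
#'
#' TSV with columns `contig` and `runtime` (minutes).
#'
#' @param path TSV file.
#' @return data frame with `contig`, `runtime`.
#' @export
read_contig_profiles <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (any(tab$runtime <= 0)) stop("non-positive contig runtime")
  tab[, c("contig", "runtime")]
}

#' Schedule contigs across parallel workers
#'
#' Longest-processing-time (LPT) greedy assignment of per-contig
#' variant-calling runtimes to `n_workers` identical instances: contigs
#' are sorted by descending runtime (ties broken by contig name) and each
#' is assigned to the currently least-loaded worker (ties to the
#' lowest-numbered worker). LPT guarantees a makespan within
#' `4/3 - 1/(3k)` of the optimum for `k` workers.
#'
#' @param profiles data frame with `contig` and `runtime` columns.
#' @param n_workers number of parallel instances (>= 1).
#' @return object of class `contig_schedule`: list with `assignments`
#'   (one data frame per worker), `loads` and `makespan`.
#' @export
schedule_contigs <- function(profiles, n_workers) {
  if (n_workers < 1) stop("n_workers must be >= 1")
  if (any(profiles$runtime <= 0)) stop("non-positive contig runtime")
  ord <- order(-profiles$runtime, profiles$contig)
  profiles <- profiles[ord, , drop = FALSE]
  loads <- numeric(n_workers)
  worker_of <- integer(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    w <- which.min(loads)
    worker_of[i] <- w
    loads[w] <- loads[w] + profiles$runtime[i]
  }
  assignments <- lapply(seq_len(n_workers), function(w) {
    a <- profiles[worker_of == w, , drop = FALSE]
    rownames(a) <- NULL
    a
  })
  out <- list(assignments = assignments, loads = loads,
              makespan = max(loads))
  class(out) <- "contig_schedule"
  out
}

#' @export
print.contig_schedule <- function(x, ...) {
  cat("LPT schedule over", length(x$loads), "workers; makespan",
      format(x$makespan), "\n")
  for (w in seq_along(x$assignments)) {
    a <- x$assignments[[w]]
    cat(sprintf("  worker %d (load %s): %s\n", w, format(x$loads[w]),
                paste(a$contig, collapse = ", ")))
  }
  invisible(x)
}
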