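# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own interval/matching
# machinery.

# O(n*m) homopolymer flag assignment: manual 1-bp left extension and
# pairwise half-open interval intersection against each variant's affected
# span (anchor base for insertions, full ref span otherwise).
bf_homopolymer_flags <- function(variants, track) {
  flag_for <- function(ivs, contig, s, e) {
    for (j in seq_len(nrow(ivs))) {
      is_ <- max(0L, ivs$start[j] - 1L)  # 1 bp left extension
      ie <- ivs$end[j]
      if (ivs$contig[j] == contig && s < ie && is_ < e) return(TRUE)
    }
    FALSE
  }
  t(vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    s <- v$pos - 1L
    e <- if (v$vtype == "INS") s + 1L else s + nchar(v$ref)
    c(long = flag_for(track$long, v$contig, s, e),
      short = flag_for(track$short, v$contig, s, e))
  }, logical(2)))
}

# Maximum bipartite matching size (Kuhn's augmenting-path algorithm) over
# a logical adjacency matrix calls x truths.
bf_max_matching <- function(adj) {
  if (length(adj) == 0 || nrow(adj) == 0 || ncol(adj) == 0) return(0L)
  match_of <- rep(0L, ncol(adj))
  try_kuhn <- function(u, seen) {
    for (v in which(adj[u, ])) {
      if (seen[v]) next
      seen[v] <- TRUE
      if (match_of[v] == 0L || Recall(match_of[v], seen)) {
        match_of[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_len(nrow(adj)))
    if (try_kuhn(u, rep(FALSE, ncol(adj)))) size <- size + 1L
  size
}

# Optimal makespan by branch and bound (exact for the small instances the
# suite uses). Upper bound initialized from a greedy schedule.
bf_makespan <- function(runtimes, k) {
  runtimes <- sort(runtimes, decreasing = TRUE)
  loads <- numeric(k)
  for (r in runtimes) loads[which.min(loads)] <- loads[which.min(loads)] + r
  best <- max(loads)
  n <- length(runtimes)
  rec <- function(i, loads) {
    if (max(loads) >= best) return()
    if (i > n) {
      best <<- max(loads)
      return()
    }
    tried <- numeric(0)
    for (w in seq_len(k)) {
      if (loads[w] %in% tried) next  # symmetric branches
      tried <- c(tried, loads[w])
      loads[w] <- loads[w] + runtimes[i]
      rec(i + 1L, loads)
      loads[w] <- loads[w] - runtimes[i]
    }
  }
  rec(1L, numeric(k))
  best
}

# One-line variant builders for unit tests.
mkvar <- function(contig = "chr1", pos = 100L, ref = "A", alt = "G", ...) {
  small_variants(contig, pos, ref, alt, ...)
}

mksv <- function(contig = "chr1", start = 100L, end = 200L, svtype = "DEL",
                 size = end - start, ...) {
  sv_records(contig, start, end, svtype, size, ...)
}

tiny_gene_model <- function() {
  genes <- data.frame(
    gene = c("GA", "GB", "GC"),
    contig = "chr1",
    strand = c("+", "-", "+"),
    tx_start = c(10000L, 40000L, 70000L),
    tx_end = c(20000L, 50000L, 80000L),
    omim_inheritance = c("AR", "AD", NA),
    stringsAsFactors = FALSE)
  cds <- data.frame(
    gene = rep(c("GA", "GB", "GC"), each = 2),
    contig = "chr1",
    start = c(11000L, 15000L, 41000L, 45000L, 71000L, 75000L),
    end = c(12000L, 16000L, 42000L, 46000L, 72000L, 76000L),
    stringsAsFactors = FALSE)
  gene_model(genes, cds)
}
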