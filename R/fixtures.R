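#' Specification for synthetic fixtures
#'
#' A seeded, fully deterministic description of a synthetic study: cohort
#' size, gene count, the number of variants planted per prioritization
#' criterion class, structural-variant truthset size and perturbation
#' model, and contig layout. Identical specs produce byte-identical
#' outputs. Planted variants carry exactly one criterion each, and
#' background variants carry none and lie outside genes, so every
#' downstream result is predictable from the construction and recorded in
#' a ground-truth manifest.
#'
#' @param seed integer RNG seed.
#' @param n_variants total small variants in the cohort.
#' @param n_svs structural variants in the benchmark truthset.
#' @param n_genes genes in the synthetic gene model.
#' @param planted named list of planted variant counts per class:
#'   `clinvar_plp`, `hgmd_dm`, `target_gene`, `biallelic_ar`, `lof`,
#'   `homopolymer_indel`.
#' @param sv_truth_perturbation list with `shift_sd` (bp, breakpoint shift
#'   standard deviation, clamped within matching tolerance), `size_jitter`
#'   (fractional size jitter sd, clamped at 10%), `fp_rate` and `fn_rate`.
#' @param contigs named vector of contig lengths.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_variants = 400L, n_svs = 80L,
                         n_genes = 30L,
                         planted = list(clinvar_plp = 3L, hgmd_dm = 3L,
                                        target_gene = 4L, biallelic_ar = 2L,
                                        lof = 3L, homopolymer_indel = 5L),
                         sv_truth_perturbation = list(shift_sd = 5,
                                                      size_jitter = 0.03,
                                                      fp_rate = 0.1,
                                                      fn_rate = 0.1),
                         contigs = c(chr1 = 1000000L, chr2 = 1000000L)) {
  defaults <- list(clinvar_plp = 0L, hgmd_dm = 0L, target_gene = 0L,
                   biallelic_ar = 0L, lof = 0L, homopolymer_indel = 0L)
  for (k in names(planted)) {
    if (!k %in% names(defaults)) stop("unknown planted class: ", k)
    defaults[[k]] <- as.integer(planted[[k]])
  }
  pert <- list(shift_sd = 5, size_jitter = 0.03, fp_rate = 0.1,
               fn_rate = 0.1)
  for (k in names(sv_truth_perturbation))
    pert[[k]] <- sv_truth_perturbation[[k]]
  if (pert$fp_rate < 0 || pert$fn_rate < 0 ||
      pert$fp_rate + pert$fn_rate >= 1)
    stop("fp_rate and fn_rate must be non-negative with fp_rate + fn_rate < 1")
  if (sum(unlist(defaults)) > n_variants)
    stop("planted counts exceed n_variants")
  out <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              n_svs = as.integer(n_svs), n_genes = as.integer(n_genes),
              planted = defaults, sv_truth_perturbation = pert,
              contigs = contigs)
  class(out) <- "fixture_spec"
  out
}

# Gene layout: 10-kb genes on a 30-kb grid starting at offset 20 kb,
# round-robin across contigs, inheritance cycling AR / AD / none.
fixture_gene_model <- function(spec) {
  n_contigs <- length(spec$contigs)
  genes <- do.call(rbind, lapply(seq_len(spec$n_genes), function(i) {
    ctg_i <- ((i - 1L) %% n_contigs) + 1L
    slot <- (i - 1L) %/% n_contigs
    tx_start <- 20000L + slot * 30000L
    if (tx_start + 10000L > spec$contigs[[ctg_i]] - 1000L)
      stop("contigs too short for ", spec$n_genes, " genes")
    data.frame(gene = sprintf("GENE%03d", i),
               contig = names(spec$contigs)[ctg_i],
               strand = if (i %% 2 == 0) "-" else "+",
               tx_start = tx_start, tx_end = tx_start + 10000L,
               omim_inheritance = c("AR", "AD", NA_character_)[((i - 1L) %% 3L) + 1L],
               stringsAsFactors = FALSE)
  }))
  cds <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    data.frame(gene = g$gene, contig = g$contig,
               start = g$tx_start + c(1000L, 4000L, 8000L),
               end = g$tx_start + c(1400L, 4400L, 8400L),
               stringsAsFactors = FALSE)
  }))
  gene_model(genes, cds)
}

# End of the gene grid on the longest-occupied contig (0-based).
fixture_gene_region_end <- function(spec) {
  slots <- ceiling(spec$n_genes / length(spec$contigs))
  20000L + slots * 30000L
}

#' Generate a synthetic small-variant cohort
#'
#' Builds a cohort VCF, ClinVar-like / HGMD-like / allele-frequency
#' annotation tables, a gene model, homopolymer tracks, a target gene
#' list and a ground-truth manifest. Planted variants each carry exactly
#' one criterion (placed inside gene CDS, or inside long-homopolymer
#' intervals for the indel class); background variants are intergenic
#' SNPs, 80% common (MAF 1-50%) and 20% rare, exercising the rarity gate.
#' The manifest records, per class, the planted variant keys and the
#' expected behavior of both triage systems under the default schema.
#'
#' @param spec `fixture_spec`.
#' @param dir optional directory; when given, all files are written there
#'   (`cohort.vcf`, `clinvar.tsv`, `hgmd.tsv`, `af.tsv`, `genes.tsv`,
#'   `homopolymers_long.bed`, `homopolymers_short.bed`,
#'   `target_genes.txt`, `manifest.json`).
#' @return list with the in-memory objects: `variants` (bare cohort, as
#'   read from the VCF), `clinvar_table`, `hgmd_table`, `af_table`,
#'   `gene_model`, `track`, `target_genes`, `manifest` and `paths`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  with_seed(spec$seed, generate_cohort_impl(spec, dir))
}

generate_cohort_impl <- function(spec, dir) {
  model <- fixture_gene_model(spec)
  genes <- model$genes
  pool <- function(label) {
    if (is.na(label)) genes$gene[is.na(genes$omim_inheritance)]
    else genes$gene[!is.na(genes$omim_inheritance) &
                      genes$omim_inheritance == label]
  }
  take <- function(from, k, used) {
    avail <- setdiff(from, used)
    if (length(avail) < k) stop("not enough genes for planted classes")
    avail[seq_len(k)]
  }
  used <- character()
  pl <- spec$planted
  g_biallelic <- take(pool("AR"), pl$biallelic_ar, used)
  used <- c(used, g_biallelic)
  g_lof <- take(pool("AD"), pl$lof, used); used <- c(used, g_lof)
  g_target <- take(pool("AD"), pl$target_gene, used); used <- c(used, g_target)
  g_clinvar <- take(pool(NA), pl$clinvar_plp, used); used <- c(used, g_clinvar)
  g_hgmd <- take(pool(NA), pl$hgmd_dm, used); used <- c(used, g_hgmd)
  target_genes <- g_target

  plant_in_gene <- function(gene, ref, alt, consequence, genotype) {
    g <- genes[genes$gene == gene, ]
    # inside the first CDS block
    pos0 <- g$tx_start + 1050L + sample.int(300L, 1)
    list(contig = g$contig, pos = pos0 + 1L, ref = ref, alt = alt,
         consequence = consequence, genotype = genotype)
  }
  rows <- list(); manifest_planted <- list()
  add_plants <- function(class, gs, ref, alt, consequence, genotype) {
    keys <- character(length(gs))
    for (i in seq_along(gs)) {
      p <- plant_in_gene(gs[i], ref, alt, consequence, genotype)
      rows[[length(rows) + 1L]] <<- c(p, list(class = class))
      keys[i] <- variant_key(p$contig, p$pos, p$ref, p$alt)
    }
    manifest_planted[[class]] <<- keys
  }
  add_plants("clinvar_plp", g_clinvar, "A", "G", "missense", "het")
  add_plants("hgmd_dm", g_hgmd, "C", "A", "missense", "het")
  add_plants("target_gene", g_target, "C", "T", "synonymous", "het")
  add_plants("biallelic_ar", g_biallelic, "A", "T", "missense", "hom_alt")
  add_plants("lof", g_lof, "G", "T", "LOF", "het")

  # homopolymer tracks in a reserved intergenic region
  hp_base <- fixture_gene_region_end(spec) + 10000L
  n_long <- max(pl$homopolymer_indel, 6L)
  ctg1 <- names(spec$contigs)[1]
  long_iv <- genomic_intervals(ctg1, hp_base + (seq_len(n_long) - 1L) * 500L,
                               hp_base + (seq_len(n_long) - 1L) * 500L + 12L)
  short_iv <- genomic_intervals(ctg1,
                                hp_base + 30000L + (0:3) * 500L,
                                hp_base + 30000L + (0:3) * 500L + 5L)
  track <- homopolymer_track(long_iv, short_iv)
  hp_keys <- character(pl$homopolymer_indel)
  for (i in seq_len(pl$homopolymer_indel)) {
    pos <- long_iv$start[i] + 4L  # anchor base inside the interval
    rows[[length(rows) + 1L]] <- list(contig = ctg1, pos = pos, ref = "AA",
                                      alt = "A", consequence = NA_character_,
                                      genotype = "het",
                                      class = "homopolymer_indel")
    hp_keys[i] <- variant_key(ctg1, pos, "AA", "A")
  }
  manifest_planted[["homopolymer_indel"]] <- hp_keys

  # intergenic background SNPs: 80% common, 20% rare (half with MAF record)
  n_bg <- spec$n_variants - length(rows)
  bg_start <- hp_base + 60000L
  af_rows <- list()
  ctg_assign <- rep(seq_along(spec$contigs), length.out = n_bg)
  for (ctg_i in seq_along(spec$contigs)) {
    ctg <- names(spec$contigs)[ctg_i]
    n_here <- sum(ctg_assign == ctg_i)
    if (n_here == 0) next
    lo <- if (ctg == ctg1) bg_start else fixture_gene_region_end(spec) + 1000L
    positions <- sample(seq.int(lo, spec$contigs[[ctg_i]] - 1000L), n_here)
    for (pos in positions) {
      rows[[length(rows) + 1L]] <- list(contig = ctg, pos = pos, ref = "T",
                                        alt = "C",
                                        consequence = NA_character_,
                                        genotype = "het",
                                        class = "background")
      u <- runif(1)
      maf <- if (u < 0.8) runif(1, 0.01, 0.5)
             else if (u < 0.9) runif(1, 1e-6, 0.009)
             else NA_real_
      if (!is.na(maf))
        af_rows[[length(af_rows) + 1L]] <- data.frame(
          contig = ctg, pos = pos, ref = "T", alt = "C", maf = maf,
          stringsAsFactors = FALSE)
    }
  }

  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(contig = r$contig, pos = r$pos, ref = r$ref, alt = r$alt,
               consequence = r$consequence, genotype = r$genotype,
               class = r$class, stringsAsFactors = FALSE)))
  dup <- duplicated(variant_key(df$contig, df$pos, df$ref, df$alt))
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  variants <- small_variants(df$contig, df$pos, df$ref, df$alt,
                             genotype = df$genotype,
                             qual = round(runif(nrow(df), 20, 60), 1),
                             consequence = df$consequence)

  mk_table <- function(keys, col, values) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    tab <- data.frame(contig = vapply(parts, `[[`, "", 1),
                      pos = as.integer(vapply(parts, `[[`, "", 2)),
                      ref = vapply(parts, `[[`, "", 3),
                      alt = vapply(parts, `[[`, "", 4),
                      stringsAsFactors = FALSE)
    tab[[col]] <- values
    annotation_table(tab, col)
  }
  cv_keys <- manifest_planted$clinvar_plp
  clinvar_table <- mk_table(cv_keys, "clinvar",
                            rep(c("P", "LP"), length.out = length(cv_keys)))
  hgmd_table <- mk_table(manifest_planted$hgmd_dm, "hgmd",
                         rep("DM", length(manifest_planted$hgmd_dm)))
  af_df <- if (length(af_rows)) do.call(rbind, af_rows) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), maf = numeric())
  af_table <- annotation_table(af_df, "maf")

  config <- triage_config()
  pts <- config$points
  expected_totals <- c(
    setNames(rep(pts[["clinvar_plp"]], length(cv_keys)), cv_keys),
    setNames(rep(pts[["hgmd_dm"]], length(manifest_planted$hgmd_dm)),
             manifest_planted$hgmd_dm),
    setNames(rep(pts[["target_gene"]], length(manifest_planted$target_gene)),
             manifest_planted$target_gene),
    setNames(rep(pts[["biallelic_omim_ar"]],
                 length(manifest_planted$biallelic_ar)),
             manifest_planted$biallelic_ar),
    setNames(rep(pts[["lof"]], length(manifest_planted$lof)),
             manifest_planted$lof),
    setNames(rep(0L, length(hp_keys)), hp_keys))
  thr <- config$review_threshold
  manifest <- list(
    seed = spec$seed, n_variants = nrow(variants),
    planted = manifest_planted,
    expected = list(
      rapid_review = names(expected_totals)[expected_totals >= thr],
      rapid_scored_not_reviewed =
        names(expected_totals)[expected_totals >= 1 & expected_totals < thr],
      standard_reviewed = c(manifest_planted$clinvar_plp,
                            manifest_planted$hgmd_dm,
                            manifest_planted$biallelic_ar,
                            manifest_planted$lof),
      standard_unreviewed_target = manifest_planted$target_gene,
      totals = as.list(expected_totals)))

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      clinvar = file.path(dir, "clinvar.tsv"),
      hgmd = file.path(dir, "hgmd.tsv"),
      af = file.path(dir, "af.tsv"),
      genes = file.path(dir, "genes.tsv"),
      long_bed = file.path(dir, "homopolymers_long.bed"),
      short_bed = file.path(dir, "homopolymers_short.bed"),
      targets = file.path(dir, "target_genes.txt"),
      manifest = file.path(dir, "manifest.json"))
    write_small_variants(variants, paths$vcf)
    write_tab <- function(tab, col, path)
      utils::write.table(tab[, c("contig", "pos", "ref", "alt", col)],
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_tab(clinvar_table, "clinvar", paths$clinvar)
    write_tab(hgmd_table, "hgmd", paths$hgmd)
    write_tab(af_table, "maf", paths$af)
    write_gene_model(model, paths$genes)
    write_bed(track$long, paths$long_bed)
    write_bed(track$short, paths$short_bed)
    writeLines(target_genes, paths$targets)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(variants = variants, clinvar_table = clinvar_table,
       hgmd_table = hgmd_table, af_table = af_table, gene_model = model,
       track = track, target_genes = target_genes, manifest = manifest,
       paths = paths)
}

#' Generate a synthetic SV benchmark
#'
#' Builds a truthset of DEL/INS/DUP/INV records on a fixed grid, a
#' perturbed callset (per-record breakpoint shifts and size jitter kept
#' within matching tolerance, plus spurious calls and dropped truths at
#' the configured rates), two allele-frequency catalogs built from truth
#' records, confident-region intervals, and a manifest with the
#' analytically expected tp/fp/fn/exact-match counts.
#'
#' @param spec `fixture_spec`.
#' @param dir optional output directory (`truth.vcf`, `calls.vcf`,
#'   `catalog_public.vcf`, `catalog_inhouse.vcf`, `confident.bed`,
#'   `sv_manifest.json`).
#' @return list with `truth`, `calls`, `catalogs`, `confident`,
#'   `manifest`, `paths`.
#' @export
generate_sv_benchmark <- function(spec, dir = NULL) {
  with_seed(spec$seed + 1L, generate_sv_benchmark_impl(spec, dir))
}

generate_sv_benchmark_impl <- function(spec, dir) {
  pert <- spec$sv_truth_perturbation
  n <- spec$n_svs
  ctgs <- names(spec$contigs)
  types <- rep(c("DEL", "INS", "DUP", "DEL", "INS", "INV"), length.out = n)
  slot_of <- function(i) {
    ctg_i <- ((i - 1L) %% length(ctgs)) + 1L
    slot <- (i - 1L) %/% length(ctgs)
    start <- 1000L + slot * 8000L
    if (start + 3000L > spec$contigs[[ctg_i]])
      stop("contigs too short for ", n, " SVs")
    list(contig = ctgs[ctg_i], start = start)
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- slot_of(i)
    size <- if (types[i] == "INS") sample(60:400, 1) else sample(100:2000, 1)
    data.frame(contig = s$contig, start = s$start,
               end = if (types[i] == "INS") s$start + 1L else s$start + size,
               svtype = types[i], size = size, id = sprintf("truth_%03d", i),
               stringsAsFactors = FALSE)
  }))
  truth <- sv_records(truth$contig, truth$start, truth$end, truth$svtype,
                      truth$size, id = truth$id)

  dropped <- runif(n) < pert$fn_rate
  call_rows <- list(); exact_flags <- logical(0)
  for (i in which(!dropped)) {
    t <- truth[i, ]
    shift_cap <- min(50L, floor(0.1 * t$size))
    shift <- as.integer(max(-shift_cap, min(shift_cap,
                                            round(rnorm(1, 0, pert$shift_sd)))))
    jit <- max(-0.1, min(0.1, rnorm(1, 0, pert$size_jitter)))
    size2 <- max(50L, as.integer(round(t$size * (1 + jit))))
    start2 <- t$start + shift
    call_rows[[length(call_rows) + 1L]] <- data.frame(
      contig = t$contig, start = start2,
      end = if (t$svtype == "INS") start2 + 1L else start2 + size2,
      svtype = t$svtype, size = size2,
      id = sprintf("call_%03d", i), stringsAsFactors = FALSE)
    exact_flags <- c(exact_flags, shift == 0L && size2 == t$size)
  }
  n_fp <- round(pert$fp_rate * n)
  for (j in seq_len(n_fp)) {
    s <- slot_of(j)
    tt <- c("DEL", "INS")[((j - 1L) %% 2L) + 1L]
    size <- sample(60:300, 1)
    start <- s$start + 4500L
    call_rows[[length(call_rows) + 1L]] <- data.frame(
      contig = s$contig, start = start,
      end = if (tt == "INS") start + 1L else start + size,
      svtype = tt, size = size, id = sprintf("fp_%03d", j),
      stringsAsFactors = FALSE)
  }
  cd <- do.call(rbind, call_rows)
  calls <- sv_records(cd$contig, cd$start, cd$end, cd$svtype, cd$size,
                      id = cd$id)

  k <- min(20L, n)
  mk_catalog <- function(idx, afs) {
    t <- truth[idx, , drop = FALSE]
    sv_records(t$contig, t$start, t$end, t$svtype, t$size,
               id = sub("truth", "cat", t$id),
               catalog_af = rep(afs, length.out = length(idx)))
  }
  cat_pub <- mk_catalog(seq_len(k), c(0.05, 0.005))
  idx2 <- seq.int(k + 1L, min(n, 2L * k))
  cat_inh <- mk_catalog(idx2, c(0.005, 0.05))
  common_truth_idx <- c(seq_len(k)[rep(c(TRUE, FALSE), length.out = k)],
                        idx2[rep(c(FALSE, TRUE), length.out = length(idx2))])
  removed_ids <- sprintf("call_%03d", intersect(common_truth_idx,
                                                which(!dropped)))
  confident <- genomic_intervals(ctgs, rep(0L, length(ctgs)),
                                 as.integer(spec$contigs))

  per_type <- lapply(unique(types), function(tt) {
    kept <- !dropped & types == tt
    list(tp = sum(kept), fn = sum(dropped & types == tt),
         fp = sum(cd$svtype == tt & grepl("^fp_", cd$id)),
         exact = sum(exact_flags[types[!dropped] == tt]))
  })
  names(per_type) <- unique(types)
  manifest <- list(seed = spec$seed, n_truth = n,
                   tp = sum(!dropped), fn = sum(dropped), fp = n_fp,
                   exact_matches = sum(exact_flags),
                   per_type = per_type,
                   retained_after_select_rare =
                     setdiff(calls$id, removed_ids))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(truth = file.path(dir, "truth.vcf"),
                  calls = file.path(dir, "calls.vcf"),
                  catalog_public = file.path(dir, "catalog_public.vcf"),
                  catalog_inhouse = file.path(dir, "catalog_inhouse.vcf"),
                  confident = file.path(dir, "confident.bed"),
                  manifest = file.path(dir, "sv_manifest.json"))
    write_sv_vcf(truth, paths$truth)
    write_sv_vcf(calls, paths$calls)
    write_sv_vcf(cat_pub, paths$catalog_public)
    write_sv_vcf(cat_inh, paths$catalog_inhouse)
    write_bed(confident, paths$confident)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(truth = truth, calls = calls, catalogs = list(cat_pub, cat_inh),
       confident = confident, manifest = manifest, paths = paths)
}

#' Generate a synthetic read-metadata table
#'
#' Reads for one library: a configurable fraction fail the q-score
#' threshold (q < 7) and a fraction are unclassified; the rest carry the
#' library barcode.
#'
#' @param n number of reads.
#' @param barcode library barcode (e.g. `"BC01"`).
#' @param sample sample name recorded as `source_sample`.
#' @param fail_rate fraction of reads with q score below 7.
#' @param unclassified_rate fraction of reads without a barcode call.
#' @param seed RNG seed.
#' @return `read_records` data frame.
#' @export
generate_reads <- function(n, barcode, sample = barcode,
                           fail_rate = 0.05, unclassified_rate = 0.02,
                           seed = 1L) {
  with_seed(seed, {
    q <- runif(n, 7, 20)
    n_fail <- round(fail_rate * n)
    if (n_fail > 0) q[seq_len(n_fail)] <- runif(n_fail, 2, 6.9)
    bc <- rep(barcode, n)
    uncl <- runif(n) < unclassified_rate
    bc[uncl] <- "unclassified"
    ord <- sample.int(n)
    read_records(sprintf("%s_r%06d", sample, seq_len(n))[ord], q[ord],
                 bc[ord], sample)
  })
}

#' Generate synthetic per-contig runtime profiles
#'
#' Log-normal runtimes (minutes), emulating the skewed distribution of
#' per-contig variant-calling workloads across a genome.
#'
#' @param n_contigs number of contigs.
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters (default ~30 min median).
#' @return data frame with `contig`, `runtime`.
#' @export
generate_contig_profiles <- function(n_contigs = 25L, seed = 1L,
                                     meanlog = log(30), sdlog = 0.6) {
  with_seed(seed, data.frame(
    contig = sprintf("chr%d", seq_len(n_contigs)),
    runtime = round(stats::rlnorm(n_contigs, meanlog, sdlog), 1),
    stringsAsFactors = FALSE))
}
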