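test_that("rapid scoring awards criterion points independently and applies the threshold", {
  cfg <- triage_config()
  # ClinVar LP + target gene: 5 + 2 = 7 >= 4, reviewed
  v <- mkvar(clinvar = "LP", gene = "G1")
  r <- score_rapid(v, cfg, target_genes = "G1")
  expect_equal(r$total, 7L)
  expect_true(r$review)
  expect_equal(c(r$pts_clinvar, r$pts_target), c(5L, 2L))

  # no criteria met: total 0, no review
  r0 <- score_rapid(mkvar(), cfg)
  expect_equal(r0$total, 0L)
  expect_false(r0$review)

  # homopolymer insertion with DM?: 2 - 2 = 0, no review
  vh <- mkvar(ref = "A", alt = "AT", hgmd = "DM?",
              annotations = list("Homopolymer"))
  rh <- score_rapid(vh, cfg)
  expect_equal(rh$total, 0L)
  expect_false(rh$review)
  expect_equal(rh$pts_homopolymer, -2L)
})

test_that("the rarity gate zeroes common variants and treats missing MAF as rare", {
  cfg <- triage_config()
  common <- mkvar(clinvar = "P", maf = 0.05)
  expect_equal(score_rapid(common, cfg)$total, 0L)
  at_threshold <- mkvar(clinvar = "P", maf = 0.01)
  expect_equal(score_rapid(at_threshold, cfg)$total, 0L)  # gate is >= threshold
  just_below <- mkvar(clinvar = "P", maf = 0.0099)
  expect_equal(score_rapid(just_below, cfg)$total, 5L)
  expect_message(r <- score_rapid(mkvar(clinvar = "P"), cfg), "treated as rare")
  expect_equal(r$total, 5L)
})

test_that("penalty never drives a total below zero and totals never exceed the scale top", {
  cfg <- triage_config()
  bare_indel <- mkvar(ref = "AA", alt = "A", normalize = FALSE,
                      annotations = list("Homopolymer"))
  r <- score_rapid(bare_indel, cfg)
  expect_equal(r$total, 0L)
  expect_equal(r$pts_homopolymer, 0L)  # clamped, so total == sum of points

  m <- tiny_gene_model()
  # every compatible criterion at once, inside AR gene GA on the target list
  maxed <- small_variants("chr1", 11500L, "A", "G", genotype = "hom_alt",
                          gene = "GA", consequence = "LOF",
                          clinvar = "P", hgmd = "DM")
  rm_ <- score_rapid(maxed, cfg, target_genes = "GA", gene_model = m)
  expect_equal(rm_$total, cfg$max_total)
  expect_equal(cfg$max_total, 14L)
})

test_that("biallelic points require OMIM-AR in rapid mode and unphased pairs count", {
  cfg <- triage_config()
  m <- tiny_gene_model()
  # two rare hets in AR gene GA: both get biallelic points
  pair <- small_variants("chr1", c(11100L, 15500L), "A", "G", gene = "GA",
                         genotype = "het")
  rp <- score_rapid(pair, cfg, gene_model = m)
  expect_equal(rp$pts_biallelic, c(2L, 2L))
  expect_true(all(rp$unphased_biallelic))
  # a single rare het in GA: no biallelic points
  single <- score_rapid(pair[1, ], cfg, gene_model = m)
  expect_equal(single$pts_biallelic, 0L)
  # hom_alt in AD gene GB: no rapid points, but standard recessive trigger
  hom_ad <- small_variants("chr1", 41500L, "A", "G", gene = "GB",
                           genotype = "hom_alt")
  expect_equal(score_rapid(hom_ad, cfg, gene_model = m)$pts_biallelic, 0L)
  st <- score_standard(hom_ad, cfg, gene_model = m)
  expect_true(st$review)
  expect_equal(st$first_trigger, "recessive")
})

test_that("biallelic detection matches a brute-force group-by count of rare alleles", {
  cfg <- triage_config()
  genes <- data.frame(gene = sprintf("G%02d", 1:8), contig = "chr1",
                      strand = "+", tx_start = (0:7) * 10000L,
                      tx_end = (0:7) * 10000L + 5000L,
                      omim_inheritance = "AR", stringsAsFactors = FALSE)
  cds <- data.frame(gene = genes$gene, contig = "chr1",
                    start = genes$tx_start + 100L,
                    end = genes$tx_start + 4000L, stringsAsFactors = FALSE)
  m <- gene_model(genes, cds)
  set.seed(11)
  for (rep_i in 1:5) {
    n <- 60L
    v <- small_variants("chr1", sample.int(80000L, n), "A", "G",
                        gene = sample(c(genes$gene, NA), n, TRUE),
                        genotype = sample(c("het", "hom_alt"), n, TRUE,
                                          prob = c(0.8, 0.2)),
                        maf = ifelse(runif(n) < 0.5, NA,
                                     runif(n, 0, 0.3)))
    got <- score_rapid(v, cfg, gene_model = m)$pts_biallelic > 0
    rare <- is.na(v$maf) | v$maf < cfg$maf_threshold
    het_counts <- table(v$gene[rare & v$genotype == "het" & !is.na(v$gene)])
    want <- vapply(seq_len(n), function(i) {
      if (!rare[i] || is.na(v$gene[i])) return(FALSE)
      if (v$genotype[i] == "hom_alt") return(TRUE)
      cnt <- het_counts[v$gene[i]]
      !is.na(cnt) && cnt >= 2
    }, logical(1))
    expect_equal(got, want)
  }
})

test_that("standard mode pre-filters target hits to coding impact; rapid scores them anyway", {
  cfg <- triage_config()
  syn <- mkvar(gene = "G1", consequence = "synonymous")
  st <- score_standard(syn, cfg, target_genes = "G1")
  expect_false(st$review)  # fails the protein-coding pre-filter
  rp <- score_rapid(syn, cfg, target_genes = "G1")
  expect_equal(rp$pts_target, 2L)  # scored before any coding-impact restriction
  # splice-region counts as coding impact for the standard target trigger
  spl <- mkvar(gene = "G1", consequence = "splice_region")
  expect_true(score_standard(spl, cfg, target_genes = "G1")$review)
})

test_that("standard triggers are ordered and exclusive", {
  cfg <- triage_config()
  both <- mkvar(clinvar = "P", gene = "G1", consequence = "missense")
  st <- score_standard(both, cfg, target_genes = "G1")
  expect_equal(st$first_trigger, "clinvar")
  dm_only <- mkvar(hgmd = "DM?")
  expect_equal(score_standard(dm_only, cfg)$first_trigger, "hgmd")
  lof_only <- mkvar(consequence = "LOF")
  expect_equal(score_standard(lof_only, cfg)$first_trigger, "deleterious")
})

test_that("review set shrinks monotonically in the threshold and grows with added criteria", {
  fx <- generate_cohort(fixture_spec(seed = 5))
  v <- annotate_homopolymer(fx$variants, fx$track)
  v <- annotate_databases(v, fx$clinvar_table, fx$hgmd_table, fx$af_table,
                          fx$gene_model)
  prev <- NULL
  for (thr in 1:14) {
    cfg <- triage_config(review_threshold = thr)
    suppressMessages(r <- score_rapid(v, cfg, fx$target_genes, fx$gene_model))
    cur <- which(r$review)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    expect_true(all(r$total[cur] >= thr))
    scored_not_reviewed <- r$total >= 1 & !r$review
    expect_true(all(r$total[scored_not_reviewed] < thr))
    prev <- cur
  }
  # adding a positive criterion never removes a variant from review
  cfg <- triage_config()
  suppressMessages(base <- score_rapid(v, cfg, fx$target_genes, fx$gene_model))
  v2 <- v
  v2$clinvar[is.na(v2$clinvar)] <- "P"
  suppressMessages(more <- score_rapid(v2, cfg, fx$target_genes, fx$gene_model))
  expect_true(all(which(base$review) %in% which(more$review)))
})

test_that("triage report ranks reviews and tallies both systems per category", {
  fx <- generate_cohort(fixture_spec(seed = 9))
  v <- annotate_homopolymer(fx$variants, fx$track)
  v <- annotate_databases(v, fx$clinvar_table, fx$hgmd_table, fx$af_table,
                          fx$gene_model)
  suppressMessages(
    rep <- triage_report(v, triage_config(), fx$target_genes, fx$gene_model))
  expect_equal(nrow(rep$review), sum(rep$rapid$review))
  expect_true(all(diff(rep$review$total) <= 0))
  man <- fx$manifest$expected
  keys <- variant_key(rep$review$contig, rep$review$pos, rep$review$ref,
                      rep$review$alt)
  expect_setequal(keys, man$rapid_review)
  # planted target variants: scored by rapid, invisible to standard
  tgt <- rep$comparison[rep$comparison$category == "target", ]
  expect_equal(tgt$rapid_scored, length(fx$manifest$planted$target_gene))
  expect_equal(tgt$standard_candidates, 0L)
  # empty cohort is an empty report, not an error
  empty <- triage_report(v[0, ], triage_config())
  expect_equal(nrow(empty$review), 0L)
})

test_that("schema configuration validates and loads from YAML", {
  expect_error(triage_config(review_threshold = 0), "review_threshold")
  expect_error(triage_config(homopolymer_indel_penalty = 1), "negative")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("review_threshold: 6", "clinvar_plp: 7",
               "target_gene: 3"), path)
  cfg <- read_triage_config(path)
  expect_equal(cfg$review_threshold, 6L)
  expect_equal(unname(cfg$points["clinvar_plp"]), 7L)
  expect_equal(unname(cfg$points["target_gene"]), 3L)
})
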