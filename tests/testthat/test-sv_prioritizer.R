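test_that("sv_match applies strict reciprocal overlap and inclusive size similarity", {
  del <- function(s, e) list(contig = "chr1", start = s, end = e,
                             svtype = "DEL", size = e - s)
  ins <- function(s, size) list(contig = "chr1", start = s, end = s + 1L,
                                svtype = "INS", size = size)
  # identical records match (reciprocal overlap 1.0)
  expect_true(sv_match(del(100L, 200L), del(100L, 200L)))
  # exactly 50% reciprocal overlap: rule is strict >50%, no match
  expect_false(sv_match(del(100L, 200L), del(150L, 250L)))
  expect_true(sv_match(del(100L, 200L), del(149L, 249L)))
  # insertion size ratio exactly 0.5 at distance < 100: inclusive, match
  expect_true(sv_match(ins(100L, 100L), ins(150L, 50L)))
  expect_false(sv_match(ins(100L, 100L), ins(150L, 49L)))
  # anchor distance exactly 100: strict <100, no match
  expect_false(sv_match(ins(100L, 80L), ins(200L, 80L)))
  expect_true(sv_match(ins(100L, 80L), ins(199L, 80L)))
  # type and contig mismatches are FALSE, not errors; BND never matches
  dup <- del(100L, 200L); dup$svtype <- "DUP"
  expect_false(sv_match(del(100L, 200L), dup))
  other <- del(100L, 200L); other$contig <- "chr2"
  expect_false(sv_match(del(100L, 200L), other))
  bnd <- list(contig = "chr1", start = 100L, end = 101L, svtype = "BND",
              size = NA_integer_)
  expect_false(sv_match(bnd, bnd))
})

test_that("sv_match is symmetric over random type-compatible pairs", {
  set.seed(33)
  for (i in 1:200) {
    tt <- sample(c("DEL", "DUP", "INV", "INS"), 1)
    mk <- function() {
      s <- sample.int(5000L, 1)
      size <- sample(50:500, 1)
      list(contig = "chr1", start = s,
           end = if (tt == "INS") s + 1L else s + size,
           svtype = tt, size = size)
    }
    a <- mk(); b <- mk()
    expect_identical(sv_match(a, b), sv_match(b, a))
  }
})

test_that("rare-SV selection removes only calls matching common catalog records", {
  calls <- sv_records("chr1", c(100L, 1000L, 5000L),
                      c(300L, 1200L, 5001L),
                      c("DEL", "DEL", "INS"), c(200L, 200L, 120L),
                      id = c("a", "b", "c"))
  catalog <- sv_records("chr1", c(110L, 1010L), c(310L, 1210L), "DEL",
                        200L, catalog_af = c(0.05, 0.005))
  kept <- select_rare(calls, list(catalog))
  expect_equal(kept$id, c("b", "c"))  # af 0.005 match and no-match retained
  # catalog af exactly at the 1% threshold: retained (rule is strict >1%)
  at <- sv_records("chr1", 110L, 310L, "DEL", 200L, catalog_af = 0.01)
  expect_equal(select_rare(calls, list(at))$id, calls$id)
  expect_equal(select_rare(calls, list()), calls)
})

test_that("select_rare is anti-monotone in the frequency threshold", {
  set.seed(4)
  fx <- generate_sv_benchmark(fixture_spec(seed = 21, n_svs = 40))
  prev <- NULL
  for (thr in c(0.10, 0.01, 0.001, 0)) {
    kept <- select_rare(fx$calls, fx$catalogs, af_threshold = thr)$id
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("tier assignment is an ordered exclusive partition", {
  m <- tiny_gene_model()
  conserved <- genomic_intervals("chr1", 90000L, 90500L)
  regulatory <- genomic_intervals("chr1", 95000L, 95200L)
  svs <- sv_records("chr1",
                    start = c(11500L, 43000L, 8500L, 90100L, 60000L),
                    end = c(11700L, 43200L, 8700L, 90300L, 60200L),
                    svtype = "DEL", size = 200L,
                    id = c("cds", "intron", "promoter", "conserved", "none"))
  res <- assign_tiers(svs, m, conserved, regulatory,
                      target_genes = "GA")
  expect_equal(res$calls$tier[match(c("cds", "intron", "promoter",
                                      "conserved", "none"), res$calls$id)],
               c(1L, 2L, 2L, 3L, NA))
  # untered SV dropped from the report; each reported SV has exactly one tier
  expect_false("none" %in% res$report$id)
  expect_false(any(is.na(res$report$tier)))
  # target-gene SVs listed first within their tier
  t2 <- res$report[res$report$tier == 2L, ]
  expect_true(all(which(t2$on_target) < which(!t2$on_target)))
  # a coding SV also overlapping an intron stays tier 1 (ordered tests)
  span <- sv_records("chr1", 11500L, 15500L, "DEL", 4000L)
  expect_equal(assign_tiers(span, m)$calls$tier, 1L)
})

test_that("evaluation on an identical callset is perfect and shifts spoil exactness only", {
  truth <- sv_records("chr1", c(100L, 5000L, 9000L),
                      c(600L, 5001L, 9400L), c("DEL", "INS", "DEL"),
                      c(500L, 120L, 400L))
  ev <- evaluate_sv(truth, truth)
  expect_equal(c(ev$overall$precision, ev$overall$recall, ev$overall$f1),
               c(1, 1, 1))
  expect_equal(ev$overall$exact_matches, nrow(truth))
  # 1-bp shift, same size: still a tp but no longer exact
  shifted <- truth
  shifted$start <- shifted$start + 1L
  shifted$end <- shifted$end + 1L
  ev2 <- evaluate_sv(shifted, truth)
  expect_equal(ev2$overall$tp, 3L)
  expect_equal(ev2$overall$exact_matches, 0L)
})

test_that("counts follow the formula on a partially matched set", {
  truth <- sv_records("chr1", c(100L, 5000L, 9000L, 20000L),
                      c(600L, 5500L, 9400L, 20300L), "DEL",
                      c(500L, 500L, 400L, 300L))
  calls <- truth[1:3, ]
  extra <- sv_records("chr1", 50000L, 50200L, "DEL", 200L)
  calls <- rbind(calls, extra)
  class(calls) <- class(truth)
  ev <- evaluate_sv(calls, truth)
  expect_equal(c(ev$overall$tp, ev$overall$fp, ev$overall$fn), c(3L, 1L, 1L))
  expect_equal(c(ev$overall$precision, ev$overall$recall, ev$overall$f1),
               c(0.75, 0.75, 0.75))
})

test_that("confident regions gate both calls and truth; empty truth warns", {
  truth <- sv_records("chr1", c(100L, 50000L), c(600L, 50400L), "DEL",
                      c(500L, 400L))
  calls <- truth
  conf <- genomic_intervals("chr1", 0L, 10000L)
  ev <- evaluate_sv(calls, truth, conf)
  expect_equal(c(ev$overall$tp, ev$overall$fp, ev$overall$fn),
               c(1L, 0L, 0L))
  off <- genomic_intervals("chr1", 900000L, 990000L)
  expect_warning(ev0 <- evaluate_sv(calls, truth, off), "empty truthset")
  expect_equal(ev0$overall$recall, 0)
})

test_that("greedy matching attains the exhaustive maximum on small random instances and never overcounts", {
  set.seed(77)
  n_instances <- 120L
  equal_count <- 0L
  for (i in seq_len(n_instances)) {
    n_c <- sample(2:10, 1); n_t <- sample(2:10, 1)
    mk <- function(n) {
      starts <- sample.int(3000L, n)
      sizes <- sample(50:400, n, replace = TRUE)
      sv_records("chr1", starts, starts + sizes, "DEL", sizes)
    }
    calls <- mk(n_c); truth <- mk(n_t)
    ev <- evaluate_sv(calls, truth)
    adj <- matrix(FALSE, n_c, n_t)
    for (a in seq_len(n_c)) for (b in seq_len(n_t))
      adj[a, b] <- sv_match(calls[a, ], truth[b, ])
    opt <- bf_max_matching(adj)
    expect_lte(ev$overall$tp, opt)  # a matching can never exceed the maximum
    if (ev$overall$tp == opt) equal_count <- equal_count + 1L
  }
  expect_gte(equal_count / n_instances, 0.99)
})

test_that("manifest-predicted tp/fp/fn/exact are reproduced exactly", {
  fx <- generate_sv_benchmark(fixture_spec(seed = 13))
  ev <- evaluate_sv(fx$calls, fx$truth, fx$confident)
  m <- fx$manifest
  expect_equal(c(ev$overall$tp, ev$overall$fp, ev$overall$fn),
               c(m$tp, m$fp, m$fn))
  expect_equal(ev$overall$exact_matches, m$exact_matches)
  for (tt in names(m$per_type)) {
    row <- ev$per_type[ev$per_type$svtype == tt, ]
    expect_equal(c(row$tp, row$fp, row$fn),
                 c(m$per_type[[tt]]$tp, m$per_type[[tt]]$fp,
                   m$per_type[[tt]]$fn),
                 label = paste("per-type counts for", tt))
  }
})

test_that("window coverage conserves mass and clips out-of-bounds spans", {
  lens <- c(chrA = 50000L, chrB = 30000L)
  spans <- genomic_intervals(c("chrA", "chrA", "chrB"),
                             c(0L, 12000L, 1000L),
                             c(10000L, 17000L, 29000L))
  cw <- coverage_windows(spans, lens)
  expect_equal(sum(cw$windows$depth * (cw$windows$end - cw$windows$start)),
               sum(spans$end - spans$start))
  # one read covering a whole window -> mean 1; half a window -> 0.5
  w1 <- cw$windows[cw$windows$contig == "chrA" & cw$windows$start == 0L, ]
  expect_equal(w1$depth, 1)
  w2 <- cw$windows[cw$windows$contig == "chrA" & cw$windows$start == 10000L, ]
  expect_equal(w2$depth, 0.5)
  over <- genomic_intervals("chrB", 25000L, 35000L)
  expect_warning(cw2 <- coverage_windows(over, lens), "clipped")
  expect_equal(sum(cw2$windows$depth * (cw2$windows$end - cw2$windows$start)),
               5000)
})

test_that("a contig at 1.5x relative depth is flagged for aneuploidy review", {
  lens <- c(chr1 = 100000L, chr2 = 100000L, chr3 = 100000L)
  one_x <- function(ctg) genomic_intervals(ctg, 0L, 100000L)
  spans <- rbind(one_x("chr1"), one_x("chr2"),
                 one_x("chr3"),
                 genomic_intervals("chr3", 0L, 50000L))  # 1.5x on chr3
  cw <- coverage_windows(spans, lens)
  flagged <- cw$contigs$contig[cw$contigs$flagged]
  expect_equal(flagged, "chr3")
  ratio3 <- cw$contigs$ratio[cw$contigs$contig == "chr3"]
  expect_gt(ratio3, 1.25)
})
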