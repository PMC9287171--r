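#' Triage configuration
#'
#' The point schema and review threshold for the rapid score-based
#' prioritization tree. Each criterion is scored independently and a
#' variant is surfaced for manual review when its total meets the
#' threshold. The default schema is chosen so that a ClinVar P/LP
#' classification or a high-confidence HGMD DM annotation alone triggers
#' review, a low-confidence DM? alone does not, and the maximum achievable
#' total over mutually compatible criteria equals `max_total` (14, the
#' documented top of the scale). All values are configurable; the
#' target-gene weight is intended to be varied per case (1-3) with the
#' confidence of the patient-specific gene list.
#'
#' @param maf_threshold rarity gate: variants with minor allele frequency
#'   at or above this fraction score zero (default 0.01).
#' @param review_threshold total score at or above which a variant is
#'   reviewed (default 4).
#' @param points named integer vector of positive criterion weights:
#'   `clinvar_plp`, `hgmd_dm`, `hgmd_dmq`, `target_gene`,
#'   `biallelic_omim_ar`, `lof`, `deleterious_missense`.
#' @param homopolymer_indel_penalty negative points added to indels carrying
#'   the `"Homopolymer"` flag (default -2).
#' @param max_total documented top of the score scale; when `NULL`,
#'   computed as the maximum achievable total (HGMD DM/DM? and LOF/missense
#'   being mutually exclusive within a variant).
#' @return object of class `triage_config`.
#' @export
triage_config <- function(maf_threshold = 0.01, review_threshold = 4L,
                          points = c(clinvar_plp = 5L, hgmd_dm = 4L,
                                     hgmd_dmq = 2L, target_gene = 2L,
                                     biallelic_omim_ar = 2L, lof = 1L,
                                     deleterious_missense = 1L),
                          homopolymer_indel_penalty = -2L,
                          max_total = NULL) {
  needed <- c("clinvar_plp", "hgmd_dm", "hgmd_dmq", "target_gene",
              "biallelic_omim_ar", "lof", "deleterious_missense")
  if (!all(needed %in% names(points)))
    stop("points must name: ", paste(needed, collapse = ", "))
  points <- as.integer(points[needed])
  names(points) <- needed
  if (review_threshold < 1) stop("review_threshold must be >= 1")
  if (homopolymer_indel_penalty >= 0)
    stop("homopolymer_indel_penalty must be negative")
  achievable <- points[["clinvar_plp"]] +
    max(points[["hgmd_dm"]], points[["hgmd_dmq"]]) +
    points[["target_gene"]] + points[["biallelic_omim_ar"]] +
    max(points[["lof"]], points[["deleterious_missense"]])
  out <- list(maf_threshold = maf_threshold,
              review_threshold = as.integer(review_threshold),
              points = points,
              homopolymer_indel_penalty = as.integer(homopolymer_indel_penalty),
              max_total = as.integer(max_total %||% achievable))
  class(out) <- "triage_config"
  out
}

#' Read a point schema from YAML
#'
#' A flat `key: integer` document; recognized keys are the criterion names
#' of [triage_config()] plus `maf_threshold`, `review_threshold` and
#' `homopolymer_indel_penalty`.
#'
#' @param path YAML file.
#' @return `triage_config`.
#' @export
read_triage_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- triage_config()
  pts <- defaults$points
  for (k in names(pts)) if (!is.null(y[[k]])) pts[[k]] <- as.integer(y[[k]])
  triage_config(
    maf_threshold = y$maf_threshold %||% defaults$maf_threshold,
    review_threshold = y$review_threshold %||% defaults$review_threshold,
    points = pts,
    homopolymer_indel_penalty = y$homopolymer_indel_penalty %||%
      defaults$homopolymer_indel_penalty)
}

# Rarity: absent MAF is treated as rare (absence from population databases
# is evidence of rarity in clinical filtration practice).
is_rare <- function(variants, config) {
  is.na(variants$maf) | variants$maf < config$maf_threshold
}

# Per-variant biallelic candidacy among rare variants: homozygous-alternate,
# or a rare heterozygous variant in a gene carrying >= 2 rare heterozygous
# variants (unphased compound-het proxy).
biallelic_candidate <- function(variants, rare) {
  gene <- variants$gene
  het_rare <- rare & variants$genotype == "het" & !is.na(gene)
  het_counts <- table(gene[het_rare])
  in_comphet_gene <- het_rare &
    gene %in% names(het_counts)[het_counts >= 2]
  rare & !is.na(gene) &
    (variants$genotype == "hom_alt" | in_comphet_gene)
}

criterion_points <- function(variants, config, target_genes, gene_model) {
  n <- nrow(variants)
  rare <- is_rare(variants, config)
  pts <- config$points
  ar_genes <- if (is.null(gene_model)) character() else omim_genes(gene_model, "AR")
  clinvar <- ifelse(!is.na(variants$clinvar) &
                      variants$clinvar %in% c("P", "LP"),
                    pts[["clinvar_plp"]], 0L)
  hgmd <- ifelse(is.na(variants$hgmd), 0L,
                 ifelse(variants$hgmd == "DM", pts[["hgmd_dm"]],
                        pts[["hgmd_dmq"]]))
  target <- ifelse(!is.na(variants$gene) & variants$gene %in% target_genes,
                   pts[["target_gene"]], 0L)
  biallelic <- ifelse(biallelic_candidate(variants, rare) &
                        !is.na(variants$gene) & variants$gene %in% ar_genes,
                      pts[["biallelic_omim_ar"]], 0L)
  cq <- variants$consequence
  deleterious <- ifelse(!is.na(cq) & cq == "LOF", pts[["lof"]],
                 ifelse(!is.na(cq) & cq == "missense" &
                          !is.na(variants$insilico_deleterious) &
                          variants$insilico_deleterious,
                        pts[["deleterious_missense"]], 0L))
  has_hp <- vapply(variants$annotations, function(fl)
    "Homopolymer" %in% fl, logical(1))
  penalty_raw <- ifelse(variants$vtype %in% c("INS", "DEL") & has_hp,
                        config$homopolymer_indel_penalty, 0L)
  pos_sum <- clinvar + hgmd + target + biallelic + deleterious
  # clamp the penalty so totals never drop below zero (scores are 1..max)
  penalty <- pmax(penalty_raw, -pos_sum)
  data.frame(rare = rare,
             pts_clinvar = as.integer(clinvar),
             pts_hgmd = as.integer(hgmd),
             pts_target = as.integer(target),
             pts_biallelic = as.integer(biallelic),
             pts_deleterious = as.integer(deleterious),
             pts_homopolymer = as.integer(penalty))
}

#' Rapid score-based triage
#'
#' Applies the rarity gate (MAF below threshold, or absent), then scores
#' every criterion independently: ClinVar P/LP; HGMD DM or DM?; membership
#' of the variant's gene in the patient-specific target list (awarded
#' regardless of coding impact); biallelic status (homozygous-alternate or
#' unphased compound-het candidate) in OMIM autosomal-recessive genes;
#' predicted deleterious impact (LOF, or missense predicted deleterious in
#' silico); and a negative adjustment for homopolymer-context indels. The
#' penalty is clamped so totals never fall below zero. A variant is marked
#' for review when its total meets the review threshold.
#'
#' @param cohort annotated `small_variants` data frame for one sample (the
#'   full list is needed for compound-het detection).
#' @param config `triage_config`.
#' @param target_genes character vector of patient-specific target genes.
#' @param gene_model `gene_model` supplying OMIM inheritance labels
#'   (`NULL` disables the biallelic criterion).
#' @return data frame with one row per input variant: the variant key
#'   columns, per-criterion points, `total` and `review`.
#' @export
score_rapid <- function(cohort, config = triage_config(),
                        target_genes = character(), gene_model = NULL) {
  n <- nrow(cohort)
  base <- data.frame(contig = cohort$contig, pos = cohort$pos,
                     ref = cohort$ref, alt = cohort$alt,
                     gene = cohort$gene, stringsAsFactors = FALSE)
  if (n == 0) {
    base$total <- integer(0); base$review <- logical(0)
    return(base)
  }
  if (anyNA(cohort$maf))
    message("note: ", sum(is.na(cohort$maf)),
            " variant(s) lack MAF and are treated as rare")
  pts <- criterion_points(cohort, config, target_genes, gene_model)
  pcols <- c("pts_clinvar", "pts_hgmd", "pts_target", "pts_biallelic",
             "pts_deleterious", "pts_homopolymer")
  # rarity gate: common variants score nothing at all
  for (cn in pcols) pts[[cn]][!pts$rare] <- 0L
  out <- cbind(base, pts[pcols])
  out$total <- as.integer(rowSums(pts[pcols]))
  out$review <- out$total >= config$review_threshold
  out$unphased_biallelic <- pts$pts_biallelic > 0 &
    cohort$genotype == "het"
  out
}

STANDARD_CATEGORIES <- c("clinvar", "hgmd", "target", "recessive",
                         "deleterious")

#' Standard any-criterion trigger triage
#'
#' The conventional diagnostic tree: a rare variant is flagged for manual
#' review when it meets any one of the ordered criteria — ClinVar P/LP;
#' HGMD DM or DM?; target-gene membership (evaluated only for variants
#' with protein-coding impact: LOF, missense or splice-region); any rare
#' biallelic candidate regardless of OMIM inheritance; predicted
#' deleterious impact. `first_trigger` records the first satisfied
#' category (ordered, exclusive), the basis of the category comparison
#' with the rapid system.
#'
#' @inheritParams score_rapid
#' @return data frame with logical trigger columns, `review` and
#'   `first_trigger`.
#' @export
score_standard <- function(cohort, config = triage_config(),
                           target_genes = character(), gene_model = NULL) {
  base <- data.frame(contig = cohort$contig, pos = cohort$pos,
                     ref = cohort$ref, alt = cohort$alt,
                     gene = cohort$gene, stringsAsFactors = FALSE)
  if (nrow(cohort) == 0) {
    base$review <- logical(0)
    base$first_trigger <- character(0)
    return(base)
  }
  rare <- is_rare(cohort, config)
  cq <- cohort$consequence
  coding_impact <- !is.na(cq) & cq %in% c("LOF", "missense", "splice_region")
  trig <- data.frame(
    trig_clinvar = !is.na(cohort$clinvar) & cohort$clinvar %in% c("P", "LP"),
    trig_hgmd = !is.na(cohort$hgmd),
    trig_target = coding_impact & !is.na(cohort$gene) &
      cohort$gene %in% target_genes,
    trig_recessive = biallelic_candidate(cohort, rare),
    trig_deleterious = (!is.na(cq) & cq == "LOF") |
      (!is.na(cq) & cq == "missense" &
         !is.na(cohort$insilico_deleterious) & cohort$insilico_deleterious)
  )
  # rarity applies globally in both systems
  trig[!rare, ] <- FALSE
  out <- cbind(base, trig)
  out$review <- Reduce(`|`, trig)
  mat <- as.matrix(trig)
  first_idx <- apply(mat, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  out$first_trigger <- STANDARD_CATEGORIES[first_idx]
  out
}

#' Run both triage systems and compare them
#'
#' Scores every variant under the rapid and the standard system, ranks the
#' rapid review list by descending total then genomic order, and tabulates
#' per category how many variants each system scored (met the criterion)
#' versus marked for review.
#'
#' @inheritParams score_rapid
#' @return list with elements `rapid` (full rapid scores), `standard`
#'   (full standard triggers), `review` (rapid review list, ranked) and
#'   `comparison` (per-category counts for both systems).
#' @export
triage_report <- function(cohort, config = triage_config(),
                          target_genes = character(), gene_model = NULL) {
  rapid <- score_rapid(cohort, config, target_genes, gene_model)
  standard <- score_standard(cohort, config, target_genes, gene_model)
  review <- rapid[rapid$review, , drop = FALSE]
  if (nrow(review) > 0)
    review <- review[order(-review$total, review$contig, review$pos), ,
                     drop = FALSE]
  pcol <- c(clinvar = "pts_clinvar", hgmd = "pts_hgmd",
            target = "pts_target", recessive = "pts_biallelic",
            deleterious = "pts_deleterious")
  tcol <- c(clinvar = "trig_clinvar", hgmd = "trig_hgmd",
            target = "trig_target", recessive = "trig_recessive",
            deleterious = "trig_deleterious")
  comparison <- do.call(rbind, lapply(STANDARD_CATEGORIES, function(cat) {
    rp <- if (nrow(rapid) > 0) rapid[[pcol[[cat]]]] > 0 else logical(0)
    st <- if (nrow(standard) > 0) standard[[tcol[[cat]]]] else logical(0)
    data.frame(category = cat,
               rapid_scored = sum(rp),
               rapid_reviewed = sum(rp & rapid$review),
               standard_candidates = sum(st),
               standard_reviewed = sum(!is.na(standard$first_trigger) &
                                         standard$first_trigger == cat),
               stringsAsFactors = FALSE)
  }))
  list(rapid = rapid, standard = standard, review = review,
       comparison = comparison)
}

#' Read a one-gene-per-line target list
#'
#' @param path plain-text file.
#' @return character vector.
#' @export
read_target_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
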