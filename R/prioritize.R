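#' Default configuration for the three-round germline filter
#'
#' * `maf_threshold`: strict upper bound on population allele frequency
#'   (default 0.1%, i.e. `maf < 0.001` is required).
#' * `min_deleterious_votes`: missense variants must collect at least this
#'   many deleterious verdicts among the six predictors (default 3;
#'   truncating variants are exempt because predictors typically return
#'   no verdict for them).
#' * `retained_impacts`: impact classes kept at round 1.
#' * `inheritance`: `dominant`, `recessive` or `both`.
#' * `require_shared`: demand the variant in every affected, sequenced
#'   family member.
#' * `missing_genotype`: `"fail"` (conservative default: a missing genotype
#'   in an affected member fails the shared rule) or `"ignore"`.
#'
#' @return Named list of filter settings.
#' @export
default_filter_config <- function() {
  list(
    maf_threshold = 0.001,
    min_deleterious_votes = 3L,
    retained_impacts = c("missense", "truncating"),
    inheritance = "both",
    require_shared = TRUE,
    missing_genotype = "fail"
  )
}

#' Count deleterious predictor verdicts for each variant
#'
#' The predictor score is the number of the six tools calling the variant
#' deleterious; tools with no verdict (`U`, printed `N/A` downstream) count
#' zero, never deleterious.
#'
#' @param variants Variant table with `pred.<tool>` columns.
#' @return Integer vector of scores in 0..6.
#' @export
predictor_score <- function(variants) {
  tools <- predictor_tools()
  pred_cols <- grep("^pred\\.", names(variants), value = TRUE)
  extra <- setdiff(sub("^pred\\.", "", pred_cols), tools)
  if (length(extra) > 0L)
    stopf("predictor verdict(s) outside the configured six tools: %s",
          paste(extra, collapse = ", "))
  if (nrow(variants) == 0L) return(integer(0))
  score <- integer(nrow(variants))
  for (tl in tools) {
    col <- paste0("pred.", tl)
    if (col %in% names(variants))
      score <- score + as.integer(!is.na(variants[[col]]) &
                                    variants[[col]] == "D")
  }
  score
}

#' Round-1 hard filter: rarity, impact, pathogenicity predictors
#'
#' Retains a variant iff `maf < maf_threshold` (strict), its impact class is
#' retained (default missense or truncating), and - for non-truncating
#' variants - its predictor score reaches `min_deleterious_votes` (`>=`).
#' Truncating variants pass on impact alone. Input order is preserved.
#'
#' @param variants Variant table.
#' @param config Filter configuration ([default_filter_config()]).
#' @return The retained subset of `variants`, with a `predictor_score`
#'   column attached.
#' @export
filter_round1 <- function(variants, config = default_filter_config()) {
  assert_variant_table(variants)
  score <- predictor_score(variants)
  keep <- variants$maf < config$maf_threshold &
    variants$impact %in% config$retained_impacts &
    (variants$impact == "truncating" |
       score >= config$min_deleterious_votes)
  out <- variants[keep, , drop = FALSE]
  out$predictor_score <- score[keep]
  rownames(out) <- NULL
  out
}

#' Family co-segregation filter
#'
#' Keeps variants carried by every affected, sequenced member of the family.
#' Under the dominant model every such member must be a carrier (het or
#' hom_alt - carrier status is what is tested). Under the recessive model
#' either every affected member is hom_alt, or the gene carries at least two
#' distinct retained variants het-shared by all affected members (an
#' unphased compound-heterozygous surrogate). With `inheritance = "both"` a
#' variant is retained if it satisfies either model and is labelled
#' accordingly. Missing genotypes fail the rule under the conservative
#' default.
#'
#' @param variants Variant table (typically round-1 output).
#' @param genotypes Genotype table covering the family members.
#' @param pedigree Pedigree data.frame restricted (or restrictable) to one
#'   family.
#' @param config Filter configuration.
#' @return Retained subset with an `inheritance_model` column
#'   (`"dominant"` or `"recessive"`).
#' @export
segregation_filter <- function(variants, genotypes, pedigree,
                               config = default_filter_config()) {
  fam <- unique(pedigree$family_id)
  if (length(fam) != 1L)
    stopf("segregation_filter expects a single family, got %d", length(fam))
  members <- pedigree$sample_id[pedigree$affected &
                                  pedigree$sequenced_germline]
  if (length(members) == 0L) stopf("family %s has no affected, sequenced members", fam)
  if (nrow(variants) == 0L) {
    variants$inheritance_model <- character(0)
    return(variants)
  }
  g <- genotypes[genotypes$sample_id %in% members, , drop = FALSE]
  gt_of <- function(vid) {
    gg <- g[g$vid == vid, ]
    out <- setNames(rep("missing", length(members)), members)
    out[gg$sample_id] <- gg$gt
    out
  }
  gts <- lapply(variants$vid, gt_of)
  consider <- function(gt_vec) {
    if (config$missing_genotype == "ignore") gt_vec[gt_vec != "missing"]
    else gt_vec
  }
  dom <- vapply(gts, function(gv) {
    gv <- consider(gv)
    length(gv) > 0L && all(gv %in% c("het", "hom_alt"))
  }, logical(1))
  hom <- vapply(gts, function(gv) {
    gv <- consider(gv)
    length(gv) > 0L && all(gv == "hom_alt")
  }, logical(1))
  het_shared <- vapply(gts, function(gv) {
    gv <- consider(gv)
    length(gv) > 0L && all(gv == "het")
  }, logical(1))
  # unphased compound-het surrogate: gene with >= 2 distinct het-shared variants
  comp_genes <- names(which(table(variants$gene[het_shared]) >= 2L))
  rec <- hom | (het_shared & variants$gene %in% comp_genes)
  keep <- switch(config$inheritance,
                 dominant = dom,
                 recessive = rec,
                 both = dom | rec)
  if (!isTRUE(config$require_shared)) keep <- rep(TRUE, nrow(variants))
  out <- variants[keep, , drop = FALSE]
  out$inheritance_model <- switch(config$inheritance,
                                  dominant = rep("dominant", nrow(out)),
                                  recessive = rep("recessive", nrow(out)),
                                  ifelse(dom[keep], "dominant",
                                         "recessive"))
  rownames(out) <- NULL
  out
}

#' Cross-family exclusion of inconsistently segregating variants
#'
#' A variant retained in one family is removed everywhere when the identical
#' variant (chrom, pos, ref, alt) is observed in a member of another family
#' where it fails the shared-by-all-affected rule, or when it appears on an
#' external exclusion list (e.g. variants mis-segregating in an independent
#' CRC cohort).
#'
#' @param per_family_retained Named list (family_id -> retained variant
#'   table from [segregation_filter()]).
#' @param genotypes Genotype table across the whole cohort.
#' @param pedigree Cohort pedigree data.frame.
#' @param external_exclusion Character vector of `vid` keys to drop
#'   unconditionally.
#' @param config Filter configuration.
#' @return Named list parallel to `per_family_retained`.
#' @export
cross_family_exclusion <- function(per_family_retained, genotypes, pedigree,
                                   external_exclusion = character(0),
                                   config = default_filter_config()) {
  fams <- names(per_family_retained)
  carriers <- genotypes[genotypes$gt %in% c("het", "hom_alt"), ,
                        drop = FALSE]
  fam_of <- setNames(pedigree$family_id, pedigree$sample_id)
  carriers$family_id <- fam_of[carriers$sample_id]
  bad <- character(0)
  all_vids <- unique(unlist(lapply(per_family_retained, `[[`, "vid")))
  for (vid in all_vids) {
    seen_fams <- unique(carriers$family_id[carriers$vid == vid])
    for (f in seen_fams) {
      members <- pedigree$sample_id[pedigree$family_id == f &
                                      pedigree$affected &
                                      pedigree$sequenced_germline]
      gg <- genotypes[genotypes$vid == vid &
                        genotypes$sample_id %in% members, , drop = FALSE]
      status <- setNames(rep("hom_ref", length(members)), members)
      status[gg$sample_id] <- gg$gt
      if (config$missing_genotype == "ignore")
        status <- status[status != "missing"]
      if (!all(status %in% c("het", "hom_alt"))) {
        bad <- c(bad, vid)
        break
      }
    }
  }
  bad <- union(bad, external_exclusion)
  lapply(per_family_retained, function(tab) {
    out <- tab[!(tab$vid %in% bad), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Validate a gene-set configuration
#'
#' `prioritized` maps set names (`cancer`, `senescence`, `epigenetics`) to
#' gene lists; `excluded` maps exclusion reasons (`non_cancer_disease`,
#' `vague_function`) to gene lists. A gene may sit in several prioritized
#' sets but never in both a prioritized and an excluded set.
#'
#' @param gene_sets List with elements `prioritized` and `excluded`.
#' @return `gene_sets`, invisibly, after validation.
#' @export
validate_gene_sets <- function(gene_sets) {
  pri <- unique(unlist(gene_sets$prioritized))
  exc <- unique(unlist(gene_sets$excluded))
  both <- intersect(pri, exc)
  if (length(both) > 0L)
    stopf("gene(s) in both prioritized and excluded sets: %s",
          paste(both, collapse = ", "))
  invisible(gene_sets)
}

# human-readable selection criterion from the prioritized sets hit
selection_criterion_label <- function(sets_hit) {
  label <- c(cancer = "Involvement in cancer development",
             senescence = "Senescence candidate",
             epigenetics = "Epigenetics regulator candidate")
  sets_hit <- intersect(names(label), sets_hit)
  if (length(sets_hit) == 0L) return("")
  if (identical(sets_hit, "cancer")) return(label[["cancer"]])
  if (length(sets_hit) == 1L) return(label[[sets_hit]])
  # merged phrasing, e.g. "Senescence and epigenetics regulator candidate"
  if (setequal(sets_hit, c("senescence", "epigenetics")))
    return("Senescence and epigenetics regulator candidate")
  paste(label[sets_hit], collapse = "; ")
}

#' Gene-function prioritization (rounds 2 and 3)
#'
#' Round 2 removes variants whose gene sits in an excluded set (known
#' non-cancer disease gene, vague/incompatible function). Round 3 keeps only
#' genes present in at least one prioritized set (cancer development,
#' senescence, epigenetic regulation), attaching a `selection_criterion`
#' naming the set(s).
#'
#' @param variants Variant table.
#' @param gene_sets Validated gene-set configuration.
#' @param round 2 or 3.
#' @return Filtered variant table; round 3 adds `selection_criterion`.
#' @export
gene_function_prioritize <- function(variants, gene_sets, round) {
  validate_gene_sets(gene_sets)
  stopifnot(round %in% c(2L, 3L))
  if (round == 2L) {
    excluded <- unique(unlist(gene_sets$excluded))
    out <- variants[!(variants$gene %in% excluded), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  pri <- gene_sets$prioritized
  in_set <- vapply(variants$gene, function(g) {
    any(vapply(pri, function(gl) g %in% gl, logical(1)))
  }, logical(1))
  out <- variants[in_set, , drop = FALSE]
  out$selection_criterion <- vapply(out$gene, function(g) {
    hit <- names(pri)[vapply(pri, function(gl) g %in% gl, logical(1))]
    selection_criterion_label(hit)
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Run the full three-round prioritization over a cohort
#'
#' Per family: round-1 hard filters, co-segregation, then cohort-wide
#' cross-family exclusion, round-2 gene exclusion and round-3 function
#' prioritization. Also returns per-stage attrition counts, the primary
#' debugging surface for filter behaviour.
#'
#' @param cohort A cohort object: list with `pedigree` and `families`
#'   (named list of `list(variants, genotypes)` per family), as produced by
#'   [simulate_cohort()] or assembled from [read_annotated_vcf()] /
#'   [read_pedigree()].
#' @param gene_sets Gene-set configuration.
#' @param config Filter configuration.
#' @param external_exclusion Character vector of `vid` keys excluded
#'   a priori.
#' @return List with `round1`, `round2`, `round3` (named lists of per-family
#'   variant tables), and `attrition` (data.frame of per-family counts).
#' @export
prioritize_cohort <- function(cohort, gene_sets = default_gene_sets(),
                              config = default_filter_config(),
                              external_exclusion = character(0)) {
  validate_gene_sets(gene_sets)
  ped <- cohort$pedigree
  fams <- unique(ped$family_id)
  all_genotypes <- do.call(rbind, lapply(cohort$families,
                                         function(f) f$genotypes))
  r1 <- list(); seg <- list()
  counts <- list()
  for (f in fams) {
    fdat <- cohort$families[[f]]
    v1 <- filter_round1(fdat$variants, config)
    s1 <- segregation_filter(v1, fdat$genotypes,
                             ped[ped$family_id == f, , drop = FALSE],
                             config)
    r1[[f]] <- v1
    seg[[f]] <- s1
    counts[[f]] <- c(input = nrow(fdat$variants), round1 = nrow(v1),
                     segregating = nrow(s1))
  }
  seg <- cross_family_exclusion(seg, all_genotypes, ped,
                                external_exclusion, config)
  r2 <- list(); r3 <- list()
  for (f in fams) {
    v2 <- gene_function_prioritize(seg[[f]], gene_sets, round = 2L)
    v3 <- gene_function_prioritize(v2, gene_sets, round = 3L)
    v2$family_id <- rep(f, nrow(v2))
    v3$family_id <- rep(f, nrow(v3))
    r2[[f]] <- v2
    r3[[f]] <- v3
    counts[[f]] <- c(counts[[f]], cross_family = nrow(seg[[f]]),
                     round2 = nrow(v2), round3 = nrow(v3))
  }
  attrition <- data.frame(family_id = fams,
                          do.call(rbind, counts[fams]),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(round1 = r1, round2 = r2, round3 = r3, attrition = attrition)
}

#' Default gene sets matching the bundled synthetic cohort
#'
#' The real study curated gene function by hand against the literature; that
#' judgment is irreproducible, so function assignment enters the pipeline as
#' declarative, user-supplied gene lists. These defaults cover the genes the
#' synthetic simulator plants, plus exclusion fodder used in tests.
#'
#' @return Gene-set configuration list.
#' @export
default_gene_sets <- function() {
  list(
    prioritized = list(
      cancer = c("ANXA10", "ASXL1", "CFTR", "HIC1", "KLF3", "MCM8",
                 "PDLIM2", "POLD1", "WNK2", "CANDX1"),
      senescence = c("INO80", "TP53BP1", "WRN", "DOT1L", "CANDX2"),
      epigenetics = c("DOT1L", "MCM3AP")
    ),
    excluded = list(
      non_cancer_disease = c("NCDIS1", "NCDIS2"),
      vague_function = c("VAGUE1")
    )
  )
}
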