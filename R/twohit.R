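#' Paired germline-somatic coverage QC
#'
#' A good-quality somatic sample shares most of the germline high-coverage
#' footprint. The shared fraction is `|germline intersect somatic| /
#' |germline|`; samples below `min_shared_fraction` (default 0.70) are
#' excluded from paired analysis.
#'
#' @param germline_callable,somatic_callable `GRanges` of callable regions.
#' @param min_shared_fraction Pass threshold (default 0.7, `>=`).
#' @return List with `pass` (logical) and `fraction`.
#' @export
paired_qc <- function(germline_callable, somatic_callable,
                      min_shared_fraction = 0.70) {
  g <- GenomicRanges::reduce(germline_callable)
  if (length(g) == 0L || sum(as.numeric(BiocGenerics::width(g))) == 0)
    stopf("empty germline callable region set")
  inter <- GenomicRanges::intersect(g, GenomicRanges::reduce(somatic_callable))
  frac <- sum(as.numeric(BiocGenerics::width(inter))) /
    sum(as.numeric(BiocGenerics::width(g)))
  list(pass = frac >= min_shared_fraction, fraction = frac)
}

#' Scan a somatic sample for second-hit SNVs/indels in candidate genes
#'
#' For each germline candidate gene, somatic missense/truncating variants in
#' the same gene with depth `>= min_depth` and alternative allele frequency
#' `>= aaf_threshold` are reported as second hits (the germline site itself
#' can never be its own second hit).
#'
#' @param candidates Variant table of germline candidates with `family_id`
#'   (and `gene`).
#' @param somatic A somatic sample object: list with `sample_id`,
#'   `family_id`, `mutations` (variant table) and `depths` (data.frame
#'   `vid`, `ref_count`, `alt_count`, `depth`).
#' @param aaf_threshold Minimum somatic AAF (default 0.20, `>=`).
#' @param min_depth Minimum somatic depth (default 10, `>=`).
#' @param damaging_only Restrict somatic hits to missense/truncating impact
#'   (default TRUE).
#' @return data.frame of second-hit events: `gene`, `family_id`,
#'   `germline_vid`, `second_hit` (`somatic_snv`/`somatic_indel`),
#'   `somatic_vid`, `aaf`, `depth`.
#' @export
second_hit_scan <- function(candidates, somatic, aaf_threshold = 0.20,
                            min_depth = 10L, damaging_only = TRUE) {
  empty <- data.frame(gene = character(0), family_id = character(0),
                      germline_vid = character(0), second_hit = character(0),
                      somatic_vid = character(0), aaf = numeric(0),
                      depth = integer(0), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L || nrow(somatic$mutations) == 0L) return(empty)
  mut <- merge(somatic$mutations, somatic$depths, by = "vid")
  mut$aaf <- ifelse(mut$depth > 0, mut$alt_count / mut$depth, 0)
  keep <- mut$depth >= min_depth & mut$aaf >= aaf_threshold &
    mut$var_class %in% c("SNV", "insertion", "deletion")
  if (damaging_only)
    keep <- keep & mut$impact %in% c("missense", "truncating")
  mut <- mut[keep & !is.na(mut$gene) & mut$gene != "", , drop = FALSE]
  if (nrow(mut) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    hits <- mut[mut$gene == cand$gene & mut$vid != cand$vid, , drop = FALSE]
    if (nrow(hits) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      gene = cand$gene, family_id = cand$family_id,
      germline_vid = cand$vid,
      second_hit = ifelse(hits$var_class == "SNV", "somatic_snv",
                          "somatic_indel"),
      somatic_vid = hits$vid, aaf = hits$aaf, depth = hits$depth,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact-binomial allelic-imbalance test at one germline het site
#'
#' Tests the somatic allele counts at a germline-heterozygous site against
#' the balanced null `alt ~ Binomial(depth, 0.5)` with a two-sided exact
#' binomial p-value. A site calls LOH (of the wild-type allele) only when
#' the imbalance is significant (`p < alpha`), the effect size passes the
#' floor (`|aaf - 0.5| >= delta`), and the *variant* allele is the retained
#' one - wild-type retention contradicts the two-hit model.
#'
#' @param depth,alt_count Somatic read counts at the site.
#' @param alpha Significance level (default 0.01).
#' @param delta Minimum allelic deviation from 0.5 (default 0.15).
#' @param min_depth Minimum depth; shallower sites are skipped with a
#'   reason code (default 10).
#' @param gene,chrom,pos Optional annotation carried into the result.
#' @return One-row data.frame: `gene`, `chrom`, `pos`, `depth`, `alt_count`,
#'   `aaf`, `p_value`, `direction` (`variant_retained`/`variant_lost`/
#'   `balanced`), `call`, `skipped`, `skip_reason`.
#' @export
loh_test <- function(depth, alt_count, alpha = 0.01, delta = 0.15,
                     min_depth = 10L, gene = NA_character_,
                     chrom = NA_character_, pos = NA_integer_) {
  if (is.na(depth) || depth < min_depth) {
    return(data.frame(gene = gene, chrom = chrom, pos = pos,
                      depth = depth, alt_count = alt_count, aaf = NA_real_,
                      p_value = NA_real_, direction = NA_character_,
                      call = FALSE, skipped = TRUE,
                      skip_reason = "depth_below_minimum",
                      stringsAsFactors = FALSE))
  }
  aaf <- alt_count / depth
  p <- stats::binom.test(alt_count, depth, p = 0.5,
                         alternative = "two.sided")$p.value
  direction <- if (abs(aaf - 0.5) < delta) "balanced"
               else if (aaf > 0.5) "variant_retained" else "variant_lost"
  call <- p < alpha && abs(aaf - 0.5) >= delta &&
    direction == "variant_retained"
  data.frame(gene = gene, chrom = chrom, pos = pos, depth = depth,
             alt_count = alt_count, aaf = aaf, p_value = p,
             direction = direction, call = call, skipped = FALSE,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Aggregate per-site LOH results to a gene-level call
#'
#' The candidate (germline-variant) site anchors the decision: the gene
#' calls LOH when the candidate site itself calls, or when at least half
#' (`ceiling(k/2)`) of the `k` testable sites in the gene are imbalanced in
#' a consistent retained-haplotype direction and the candidate site's
#' direction is `variant_retained`.
#'
#' @param loh_results data.frame of [loh_test()] rows for one gene.
#' @param candidate_index Row index of the candidate site (default 1).
#' @param alpha Significance level used for the per-site imbalance check.
#' @return List with `call`, `n_sites` (testable), `n_imbalanced`,
#'   `candidate_call`, `direction`.
#' @export
gene_loh_aggregate <- function(loh_results, candidate_index = 1L,
                               alpha = 0.01) {
  testable <- loh_results[!loh_results$skipped, , drop = FALSE]
  cand <- loh_results[candidate_index, ]
  k <- nrow(testable)
  if (k == 0L || isTRUE(cand$skipped)) {
    return(list(call = FALSE, n_sites = k, n_imbalanced = 0L,
                candidate_call = FALSE, direction = NA_character_))
  }
  imb <- !is.na(testable$p_value) & testable$p_value < alpha &
    testable$direction != "balanced"
  retained_dir <- testable$direction[imb]
  consistent <- length(retained_dir) > 0L &&
    length(unique(retained_dir)) == 1L
  majority <- sum(imb) >= ceiling(k / 2)
  call <- isTRUE(cand$call) ||
    (majority && consistent && identical(cand$direction, "variant_retained"))
  list(call = call, n_sites = k, n_imbalanced = sum(imb),
       candidate_call = isTRUE(cand$call),
       direction = if (consistent) unique(retained_dir) else NA_character_)
}

#' Filter an unpaired somatic sample against a panel of normals
#'
#' Without a paired germline sample, somatic calls are cleaned against a
#' pooled-normal panel: variants present in at least `min_panel_samples`
#' panel samples are removed as germline leakage or recurrent artifacts.
#'
#' @param mutations Somatic variant table.
#' @param panel data.frame with `vid` and `n_samples` (panel carrier
#'   counts).
#' @param min_panel_samples Removal threshold (default 1: present in any
#'   panel sample removes the variant).
#' @return Filtered variant table.
#' @export
unpaired_filter <- function(mutations, panel, min_panel_samples = 1L) {
  if (nrow(mutations) == 0L) return(mutations)
  bad <- panel$vid[panel$n_samples >= min_panel_samples]
  out <- mutations[!(mutations$vid %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble two-hit evidence for a family's candidate genes
#'
#' Runs the second-hit SNV/indel scan and per-gene LOH testing for one
#' paired somatic sample against the family's germline candidates, and
#' reduces to one evidence record per (gene, family): `second_hit` is
#' `somatic_snv`/`somatic_indel` when a qualifying somatic variant exists,
#' `loh` when the gene-level LOH call fires, else `none`. SNV/indel hits
#' take precedence over LOH in the summary label; a sample's hypermutation
#' class is carried as a caveat column, not used to alter calls.
#'
#' @param candidates Germline candidate variant table for the family
#'   (columns incl. `vid`, `gene`, `family_id`).
#' @param somatic Somatic sample object (see [second_hit_scan()]); for LOH
#'   it must also provide `loh_sites`, a data.frame of germline het sites
#'   with somatic counts: `gene`, `vid`, `chrom`, `pos`, `depth`,
#'   `alt_count`, `is_candidate`.
#' @param aaf_threshold,min_depth,alpha,delta Module thresholds.
#' @param load_class Optional hypermutation class caveat for the sample.
#' @return data.frame with one row per candidate: `gene`, `family_id`,
#'   `germline_vid`, `second_hit`, `detail`, `tmb_class`.
#' @export
integrate_two_hits <- function(candidates, somatic, aaf_threshold = 0.20,
                               min_depth = 10L, alpha = 0.01, delta = 0.15,
                               load_class = NA_character_) {
  if (nrow(candidates) == 0L) {
    return(data.frame(gene = character(0), family_id = character(0),
                      germline_vid = character(0), second_hit = character(0),
                      detail = character(0), tmb_class = character(0),
                      stringsAsFactors = FALSE))
  }
  snv_hits <- second_hit_scan(candidates, somatic, aaf_threshold, min_depth)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    hit <- snv_hits[snv_hits$germline_vid == cand$vid, , drop = FALSE]
    if (nrow(hit) > 0L) {
      hit <- hit[order(-hit$aaf), ][1L, ]
      rows[[i]] <- data.frame(
        gene = cand$gene, family_id = cand$family_id,
        germline_vid = cand$vid, second_hit = hit$second_hit,
        detail = sprintf("%s aaf=%.3f depth=%d", hit$somatic_vid, hit$aaf,
                         hit$depth),
        tmb_class = load_class, stringsAsFactors = FALSE)
      next
    }
    second <- "none"; detail <- ""
    sites <- somatic$loh_sites
    if (!is.null(sites) && nrow(sites) > 0L) {
      gs <- sites[sites$gene == cand$gene, , drop = FALSE]
      cand_row <- which(gs$vid == cand$vid)
      if (length(cand_row) == 1L) {
        res <- do.call(rbind, lapply(seq_len(nrow(gs)), function(j) {
          loh_test(gs$depth[j], gs$alt_count[j], alpha, delta, min_depth,
                   gene = gs$gene[j], chrom = gs$chrom[j], pos = gs$pos[j])
        }))
        agg <- gene_loh_aggregate(res, candidate_index = cand_row, alpha)
        if (agg$call) {
          second <- "loh"
          detail <- sprintf("loh sites=%d imbalanced=%d aaf=%.3f",
                            agg$n_sites, agg$n_imbalanced,
                            res$aaf[cand_row])
        }
      }
    }
    rows[[i]] <- data.frame(gene = cand$gene, family_id = cand$family_id,
                            germline_vid = cand$vid, second_hit = second,
                            detail = detail, tmb_class = load_class,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
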