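#' Default end-to-end run configuration
#'
#' Collects every module's thresholds (defaults as documented per module),
#' the simulator configuration and the seed into one serializable object; a
#' run is reproducible from this object alone.
#'
#' @param seed Master seed.
#' @param outdir Optional output directory for report artifacts.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, outdir = NULL) {
  structure(list(
    seed = as.integer(seed),
    sim = default_sim_config(seed),
    filter = default_filter_config(),
    gene_sets = default_gene_sets(),
    min_shared_fraction = 0.70,
    aaf_threshold = 0.20,
    min_depth = 10L,
    alpha = 0.01,
    delta = 0.15,
    prune_threshold = 0.05,
    min_cosine_drop = 0.01,
    outdir = outdir
  ), class = "run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> prioritize -> paired QC -> two-hit integration -> somatic
#' profiling -> candidate table. Deterministic given the config seed. The
#' final candidate table merges germline-only (`G`) and paired (`G-S paired
#' analysis`) evidence exactly once per (gene, family); the two-hit scan is
#' applied to the function-prioritized (round-3) candidate set of each
#' family with a passing paired somatic sample.
#'
#' @param config A `run_config` ([default_run_config()]).
#' @return A `cohort_summary`: list with `cohort`, `prioritization`,
#'   `qc` (per-sample paired-QC ledger), `two_hit`, `profiles` (per-sample
#'   burden/refits/flags/drivers), `burden` (data.frame), `sbs_weights` /
#'   `id_weights` (samples x signatures matrices), `drivers`, `candidates`
#'   (final table) and `paths` when `config$outdir` is set.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cohort <- simulate_cohort(config$sim)
  pri <- prioritize_cohort(cohort, config$gene_sets, config$filter)

  seqlen <- length(cohort$reference[[1]])
  m <- config$sim$callable_margin
  germline_callable <- GenomicRanges::GRanges(
    names(cohort$reference)[1], IRanges::IRanges(m + 1L, seqlen - m))

  qc <- list(); usable <- list()
  for (f in names(cohort$somatic)) {
    s <- cohort$somatic[[f]]$sample
    res <- paired_qc(germline_callable, s$callable,
                     config$min_shared_fraction)
    qc[[f]] <- data.frame(sample_id = s$sample_id, family_id = f,
                          paired = s$paired, shared_fraction = res$fraction,
                          qc_pass = res$pass, stringsAsFactors = FALSE)
    if (res$pass) usable[[f]] <- s
  }
  qc <- if (length(qc) > 0L) do.call(rbind, qc) else
    data.frame(sample_id = character(0), family_id = character(0),
               paired = logical(0), shared_fraction = numeric(0),
               qc_pass = logical(0), stringsAsFactors = FALSE)
  rownames(qc) <- NULL

  profiles <- list(); burden <- list(); two_hit <- list(); drivers <- list()
  for (f in names(usable)) {
    s <- usable[[f]]
    if (!s$paired && nrow(cohort$panel) > 0L) {
      keep <- unpaired_filter(s$mutations, cohort$panel)
      s$depths <- s$depths[s$depths$vid %in% keep$vid, , drop = FALSE]
      s$mutations <- keep
    }
    n_snv <- sum(s$mutations$var_class == "SNV")
    n_indel <- sum(s$mutations$var_class %in% c("insertion", "deletion"))
    b <- compute_burden(n_snv, n_indel, footprint_mb(s$callable),
                        sample_id = s$sample_id)
    sbs_vec <- build_catalog(s$mutations, cohort$reference, "SBS96",
                             s$sample_id)
    id_vec <- build_catalog(s$mutations, cohort$reference, "ID",
                            s$sample_id)
    sbs_fit <- refit_signatures(sbs_vec, cohort$catalogs$SBS96,
                                config$prune_threshold,
                                config$min_cosine_drop)
    id_fit <- refit_signatures(id_vec, cohort$catalogs$ID,
                               config$prune_threshold,
                               config$min_cosine_drop)
    drv <- driver_report(s)
    profiles[[f]] <- list(sample_id = s$sample_id, burden = b,
                          sbs = sbs_fit, id = id_fit,
                          flags = flag_aetiology(sbs_fit),
                          drivers = drv)
    burden[[f]] <- b
    drivers[[f]] <- drv
    if (s$paired) {
      cand <- pri$round3[[f]]
      two_hit[[f]] <- integrate_two_hits(
        cand, s, config$aaf_threshold, config$min_depth, config$alpha,
        config$delta, load_class = b$load_class)
    }
  }
  burden <- if (length(burden) > 0L) do.call(rbind, burden) else NULL
  if (!is.null(burden)) rownames(burden) <- NULL
  two_hit_tab <- if (length(two_hit) > 0L) do.call(rbind, two_hit) else
    NULL
  if (!is.null(two_hit_tab)) rownames(two_hit_tab) <- NULL
  drivers <- if (length(drivers) > 0L) do.call(rbind, drivers) else NULL
  if (!is.null(drivers)) rownames(drivers) <- NULL

  weight_matrix <- function(fits, catalog) {
    sigs <- colnames(catalog$signatures)
    mat <- matrix(0, nrow = length(fits), ncol = length(sigs),
                  dimnames = list(vapply(fits, `[[`, character(1),
                                         "sample_id"), sigs))
    for (i in seq_along(fits)) {
      w <- fits[[i]]$weights
      mat[i, names(w)] <- w
    }
    mat[order(rownames(mat)), , drop = FALSE]
  }
  sbs_weights <- weight_matrix(lapply(profiles, function(p)
    list(sample_id = p$sample_id, weights = p$sbs$weights)),
    cohort$catalogs$SBS96)
  id_weights <- weight_matrix(lapply(profiles, function(p)
    list(sample_id = p$sample_id, weights = p$id$weights)),
    cohort$catalogs$ID)

  candidates <- build_candidate_table(pri, two_hit_tab)

  summary <- structure(list(
    config = config, cohort = cohort, prioritization = pri, qc = qc,
    two_hit = two_hit_tab, profiles = profiles, burden = burden,
    sbs_weights = sbs_weights, id_weights = id_weights, drivers = drivers,
    candidates = candidates
  ), class = "cohort_summary")
  if (!is.null(config$outdir))
    summary$paths <- write_run_artifacts(summary, config$outdir)
  summary
}

# final candidate table: one row per surviving (gene, family) variant;
# evidence G-S when a two-hit record with second_hit != none backs the gene
build_candidate_table <- function(pri, two_hit_tab) {
  rows <- list()
  for (f in names(pri$round3)) {
    tab <- pri$round3[[f]]
    if (nrow(tab) == 0L) next
    for (i in seq_len(nrow(tab))) {
      v <- tab[i, ]
      evid <- "G"
      if (!is.null(two_hit_tab)) {
        hit <- two_hit_tab[two_hit_tab$family_id == f &
                             two_hit_tab$gene == v$gene &
                             two_hit_tab$second_hit != "none", ,
                           drop = FALSE]
        if (nrow(hit) > 0L) evid <- "G-S paired analysis"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = v$gene, family_id = f,
        variant = if (nzchar(v$protein_change)) v$protein_change else v$vid,
        predictor_score = if (v$impact == "truncating") NA_integer_ else
          v$predictor_score,
        max_pop_af = v$maf, evidence = evid,
        selection_criterion = v$selection_criterion,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene = character(0), family_id = character(0),
               variant = character(0), predictor_score = integer(0),
               max_pop_af = numeric(0), evidence = character(0),
               selection_criterion = character(0), stringsAsFactors = FALSE)
  out <- out[radix_order(out$family_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# write candidate table, burden, weight matrices, driver table, attrition,
# QC ledger and a manifest with a config hash
write_run_artifacts <- function(summary, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  p$candidates <- file.path(outdir, "candidate_genes.tsv")
  write_candidate_table(summary$candidates, p$candidates)
  p$attrition <- file.path(outdir, "attrition.tsv")
  write.table(summary$prioritization$attrition, p$attrition, sep = "\t",
              quote = FALSE, row.names = FALSE)
  p$qc <- file.path(outdir, "qc_ledger.tsv")
  write.table(summary$qc, p$qc, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(summary$burden)) {
    p$burden <- file.path(outdir, "burden.tsv")
    write.table(summary$burden, p$burden, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (nm in c("sbs_weights", "id_weights")) {
    p[[nm]] <- file.path(outdir, paste0(nm, ".tsv"))
    mat <- summary[[nm]]
    write.table(data.frame(sample_id = rownames(mat),
                           round(mat, 6), check.names = FALSE),
                p[[nm]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(summary$drivers)) {
    p$drivers <- file.path(outdir, "driver_report.tsv")
    drv <- summary$drivers
    drv$aaf <- round(drv$aaf, 6)
    write.table(drv, p$drivers, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(summary$two_hit)) {
    p$two_hit <- file.path(outdir, "two_hit_evidence.tsv")
    write.table(summary$two_hit, p$two_hit, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  cfg_json <- file.path(outdir, "run_config.json")
  cfg <- summary$config
  cfg$gene_sets <- lapply(cfg$gene_sets, lapply, as.list)
  jsonlite::write_json(strip_for_json(cfg), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "serrata",
    version = as.character(utils::packageVersion("serrata")),
    seed = summary$config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    n_families = length(summary$cohort$families),
    n_somatic_profiled = length(summary$profiles)
  )
  p$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p$config <- cfg_json
  p
}

# drop non-serializable elements (data.frames survive; functions/envs do not
# occur in run configs, but keep this defensive)
strip_for_json <- function(x) {
  if (is.list(x)) lapply(x, strip_for_json) else x
}

#' Render a human-readable cohort report
#'
#' Plain-text report: prioritization attrition, QC exclusions, per-sample
#' burden with load class, signature contributions, aetiology flags, driver
#' matrix, the final candidate table, and a cohort footer with mean +/- sd
#' TMB recomputed from the per-sample values.
#'
#' @param summary A `cohort_summary` from [run_pipeline()].
#' @param path Optional file to write; otherwise the lines are returned.
#' @return Character vector of report lines, invisibly when `path` given.
#' @export
render_report <- function(summary, path = NULL) {
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add("serrata cohort report")
  add("=====================")
  add("families analysed: %d", length(summary$cohort$families))
  add("somatic samples profiled: %d", length(summary$profiles))
  excl <- summary$qc[!summary$qc$qc_pass, , drop = FALSE]
  if (nrow(excl) > 0L) {
    add("QC exclusions:")
    for (i in seq_len(nrow(excl)))
      add("  %s (shared high-coverage fraction %.2f < threshold)",
          excl$sample_id[i], excl$shared_fraction[i])
  } else add("QC exclusions: none")
  add("")
  add("Prioritization attrition (variants per family):")
  at <- summary$prioritization$attrition
  for (i in seq_len(nrow(at)))
    add("  %-8s input=%d round1=%d shared=%d crossfam=%d round2=%d round3=%d",
        at$family_id[i], at$input[i], at$round1[i], at$segregating[i],
        at$cross_family[i], at$round2[i], at$round3[i])
  add("")
  if (!is.null(summary$burden)) {
    add("Somatic burden per sample:")
    b <- summary$burden
    for (i in seq_len(nrow(b)))
      add("  %-10s TMB=%.2f/Mb (SNV %.2f, indel %.2f) -> %s",
          b$sample_id[i], b$tmb[i], b$snv_tmb[i], b$indel_burden[i],
          b$load_class[i])
    add("")
    add("Signature contributions (SBS):")
    mat <- summary$sbs_weights
    for (i in seq_len(nrow(mat))) {
      w <- mat[i, , drop = TRUE]
      w <- w[w > 0]
      add("  %-10s %s", rownames(mat)[i],
          paste(sprintf("%s=%.2f", names(w), w), collapse = " "))
    }
    add("")
  }
  if (!is.null(summary$drivers) && nrow(summary$drivers) > 0L) {
    add("Driver-gene variants (no AAF threshold; tiered at 20%%):")
    d <- summary$drivers
    for (i in seq_len(nrow(d)))
      add("  %-10s %-6s %-8s aaf=%.2f %s%s", d$sample_id[i], d$gene[i],
          d$protein_change[i], d$aaf[i], d$tier[i],
          ifelse(d$hotspot[i], " [hotspot]", ""))
    add("")
  }
  add("Candidate genes:")
  cand <- summary$candidates
  if (nrow(cand) == 0L) {
    add("  no candidates after prioritization")
  } else {
    for (i in seq_len(nrow(cand)))
      add("  %-8s %-8s %-12s evidence=%s (%s)", cand$family_id[i],
          cand$gene[i], cand$variant[i], cand$evidence[i],
          cand$selection_criterion[i])
  }
  if (!is.null(summary$burden)) {
    add("")
    add("cohort TMB mean +/- sd: %.2f +/- %.2f mut/Mb",
        mean(summary$burden$tmb), sd(summary$burden$tmb))
  }
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}
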