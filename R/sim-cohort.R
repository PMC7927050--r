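#' Simulate a full synthetic cohort
#'
#' Builds the synthetic reference, gene map and signature catalogs, then
#' simulates every family's germline variants and (per plan) somatic sample,
#' an optional cross-family decoy variant (segregating in one family,
#' mis-segregating in another, so the cross-family exclusion rule fires), and
#' the pooled-normal panel for the unpaired sample. All randomness derives
#' from `config$seed`; two calls with the same config are identical.
#'
#' @param config A `sim_config` from [default_sim_config()].
#' @param include_somatic Set `FALSE` to simulate germline only (faster;
#'   used by germline-only analyses and tests).
#' @param outdir Optional directory; when given, all cohort artifacts are
#'   written to disk (reference FASTA + index, gene map TSV, PED, per-family
#'   germline VCFs, per-sample somatic VCFs and callable BEDs, LOH-site and
#'   panel TSVs, truth tables) and the paths are recorded in the returned
#'   object's `paths` element.
#' @return A cohort object: list with `config`, `reference`, `gene_map`,
#'   `catalogs`, `pedigree`, `families` (per family: `members`, `variants`,
#'   `genotypes`, `truth`), `somatic` (per family: sample object + truth),
#'   `panel`, and `truth` (cohort-level summary of planted events).
#' @export
simulate_cohort <- function(config = default_sim_config(),
                            include_somatic = TRUE, outdir = NULL) {
  seed <- config$seed
  reference <- make_reference(config$reference_length_mb, seed = seed)
  special <- unique(c(config$causal$gene, driver_genes(),
                      unlist(default_gene_sets()$excluded,
                             use.names = FALSE)))
  gene_map <- make_gene_map(reference, special_genes = special)
  ctx_index <- if (include_somatic) build_context_index(reference) else NULL
  sbs_catalog <- synthetic_sbs_catalog()
  id_catalog <- synthetic_id_catalog()

  protected <- unique(c(config$causal$gene, driver_genes()))
  mask <- gene_map_granges(gene_map[gene_map$gene %in% protected, ])

  families <- list()
  ped_rows <- list()
  used <- integer(0)
  for (i in seq_along(config$families)) {
    f <- config$families[i]
    fam <- simulate_family_germline(
      f, config$affected_counts[[f]], config, reference, gene_map,
      seed = seed + 1000L + i, used_positions = used)
    used <- fam$used_positions
    families[[f]] <- fam[c("members", "variants", "genotypes", "truth")]
    has_som <- include_somatic &&
      f %in% config$somatic$family_id[!config$somatic$unpaired]
    ped_rows[[f]] <- data.frame(
      family_id = f, sample_id = fam$members, father = "0", mother = "0",
      sex = rep_len(c(1L, 2L), length(fam$members)), affected = TRUE,
      sequenced_germline = TRUE,
      has_somatic = has_som & seq_along(fam$members) == 1L,
      stringsAsFactors = FALSE)
  }
  pedigree <- do.call(rbind, ped_rows)
  rownames(pedigree) <- NULL
  class(pedigree) <- c("sps_pedigree", "data.frame")

  decoy_vid <- NULL
  if (isTRUE(config$cross_family_decoy) && length(families) >= 2L) {
    # same rare damaging variant: het-shared in family 1, carried by only one
    # affected member of family 2 -> removed from both by the exclusion rule
    set.seed(seed + 77L)
    filler <- gene_map$gene[grepl("^GENE", gene_map$gene)]
    pos <- sample_gene_positions(gene_map, filler, 1L, used)
    used <- c(used, pos)
    row <- make_variant_row(reference, gene_map, "chr1", pos,
                            impact = "missense", votes = 5L, maf = 1e-5)
    decoy_vid <- row$vid
    f1 <- config$families[1]; f2 <- config$families[2]
    m1 <- families[[f1]]$members
    m2 <- families[[f2]]$members
    families[[f1]]$variants <- rbind(families[[f1]]$variants, row)
    families[[f1]]$genotypes <- rbind(
      families[[f1]]$genotypes, het_genotype(row$vid, m1,
                                             config$germline_depth))
    families[[f2]]$variants <- rbind(families[[f2]]$variants, row)
    families[[f2]]$genotypes <- rbind(
      families[[f2]]$genotypes,
      het_genotype(row$vid, m2[1L], config$germline_depth),
      hom_ref_genotype(row$vid, m2[-1L], config$germline_depth))
  }

  somatic <- list()
  panel <- data.frame(vid = character(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  if (include_somatic) {
    for (i in seq_len(nrow(config$somatic))) {
      f <- config$somatic$family_id[i]
      somatic[[f]] <- simulate_somatic(
        f, config, reference, gene_map, ctx_index, sbs_catalog, id_catalog,
        germline = families[[f]], mask = mask, seed = seed + 5000L + i)
    }
    unp <- config$somatic$family_id[config$somatic$unpaired]
    if (length(unp) == 1L) {
      set.seed(seed + 88L)
      leak <- somatic[[unp]]$truth$leakage_vids
      panel <- data.frame(
        vid = leak,
        n_samples = sample.int(min(80L, config$panel_size), length(leak),
                               replace = TRUE) + 1L,
        stringsAsFactors = FALSE)
    }
  }

  truth <- list(
    causal = do.call(rbind, lapply(families, function(x)
      data.frame(family_id = x$truth$family_id, gene = x$truth$causal_gene,
                 vid = x$truth$causal_vid, stringsAsFactors = FALSE))),
    second_hits = Filter(function(x) x$type != "none",
                         lapply(somatic, function(s) {
                           c(s$truth$second_hit,
                             list(family_id = s$truth$family_id))
                         })),
    decoy_vid = decoy_vid,
    survivors = vapply(families, function(x) x$truth$n_survivors,
                       integer(1))
  )
  cohort <- list(config = config, reference = reference,
                 gene_map = gene_map, catalogs = list(SBS96 = sbs_catalog,
                                                      ID = id_catalog),
                 pedigree = pedigree, families = families,
                 somatic = somatic, panel = panel, truth = truth)
  if (!is.null(outdir)) cohort$paths <- write_cohort(cohort, outdir)
  cohort
}

# write every cohort artifact in the formats the readers consume
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  contigs <- setNames(vapply(names(cohort$reference),
                             function(ch) length(cohort$reference[[ch]]),
                             integer(1)),
                      names(cohort$reference))
  p$reference <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(cohort$reference, p$reference)
  Rsamtools::indexFa(p$reference)
  p$gene_map <- file.path(outdir, "gene_map.tsv")
  write_gene_map(cohort$gene_map, p$gene_map)
  p$pedigree <- file.path(outdir, "cohort.ped")
  write_pedigree(cohort$pedigree, p$pedigree)
  p$sbs_catalog <- file.path(outdir, "sbs_catalog.tsv")
  write_signature_catalog(cohort$catalogs$SBS96, p$sbs_catalog)
  p$id_catalog <- file.path(outdir, "id_catalog.tsv")
  write_signature_catalog(cohort$catalogs$ID, p$id_catalog)
  dir.create(file.path(outdir, "germline"), showWarnings = FALSE)
  p$germline_vcf <- setNames(
    file.path(outdir, "germline", paste0(names(cohort$families), ".vcf")),
    names(cohort$families))
  for (f in names(cohort$families)) {
    write_annotated_vcf(cohort$families[[f]]$variants,
                        cohort$families[[f]]$genotypes,
                        p$germline_vcf[[f]], contigs = contigs)
  }
  if (length(cohort$somatic) > 0L) {
    dir.create(file.path(outdir, "somatic"), showWarnings = FALSE)
    fams <- names(cohort$somatic)
    p$somatic_vcf <- setNames(
      file.path(outdir, "somatic", paste0(fams, ".T.vcf")), fams)
    p$somatic_bed <- setNames(
      file.path(outdir, "somatic", paste0(fams, ".T.callable.bed")), fams)
    p$loh_sites <- setNames(
      file.path(outdir, "somatic", paste0(fams, ".T.loh_sites.tsv")), fams)
    for (f in fams) {
      s <- cohort$somatic[[f]]$sample
      g <- data.frame(vid = s$depths$vid, sample_id = s$sample_id,
                      gt = "het", ref_count = s$depths$ref_count,
                      alt_count = s$depths$alt_count,
                      depth = s$depths$depth, stringsAsFactors = FALSE)
      write_annotated_vcf(s$mutations, g, p$somatic_vcf[[f]],
                          contigs = contigs)
      write_callable_bed(s$callable, p$somatic_bed[[f]])
      if (!is.null(s$loh_sites))
        write.table(s$loh_sites, p$loh_sites[[f]], sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
  }
  p$panel <- file.path(outdir, "panel_of_normals.tsv")
  write.table(cohort$panel, p$panel, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p$truth_causal <- file.path(outdir, "truth_causal.tsv")
  write.table(cohort$truth$causal, p$truth_causal, sep = "\t",
              quote = FALSE, row.names = FALSE)
  p
}
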