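#' Read a pedigree (PED-like) file
#'
#' Tab-separated with columns `family_id`, `sample_id`, `father`, `mother`,
#' `sex`, `phenotype` (2 = affected, 1 = unaffected), and two optional 0/1
#' columns `sequenced` (germline exome available, default 1) and `somatic`
#' (a somatic sample from this individual was sequenced, default 0). A header
#' line starting with `#` is permitted.
#'
#' @param path Path to the PED file.
#' @return A data.frame of class `sps_pedigree` with logical columns
#'   `affected`, `sequenced_germline`, `has_somatic`.
#' @export
read_pedigree <- function(path) {
  raw <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 6L) stopf("PED file needs >= 6 columns, got %d", ncol(raw))
  ped <- data.frame(
    family_id = as.character(raw[[1]]), sample_id = as.character(raw[[2]]),
    father = as.character(raw[[3]]), mother = as.character(raw[[4]]),
    sex = as.integer(raw[[5]]), affected = raw[[6]] == 2,
    sequenced_germline = if (ncol(raw) >= 7L) raw[[7]] == 1 else TRUE,
    has_somatic = if (ncol(raw) >= 8L) raw[[8]] == 1 else FALSE,
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$sample_id))
    stopf("duplicate sample_id in pedigree: %s",
          paste(unique(ped$sample_id[duplicated(ped$sample_id)]),
                collapse = ", "))
  ok <- tapply(ped$affected & ped$sequenced_germline, ped$family_id, any)
  if (!all(ok))
    stopf("family with no affected, sequenced member: %s",
          paste(names(ok)[!ok], collapse = ", "))
  class(ped) <- c("sps_pedigree", "data.frame")
  ped
}

#' Write a pedigree file
#' @param ped Pedigree data.frame as returned by [read_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$family_id, ped$sample_id, ped$father, ped$mother,
                    ped$sex, ifelse(ped$affected, 2L, 1L),
                    ifelse(ped$sequenced_germline, 1L, 0L),
                    ifelse(ped$has_somatic, 1L, 0L))
  writeLines(c("#family_id\tsample_id\tfather\tmother\tsex\tphenotype\tsequenced\tsomatic",
               do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Read callable regions from a BED file
#'
#' BED is 0-based half-open on disk; the returned `GRanges` is 1-based
#' inclusive (the conversion is handled by `rtracklayer`).
#'
#' @param path Path to a BED3+ file.
#' @return A reduced `GRanges` of callable regions.
#' @export
read_callable_bed <- function(path) {
  GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
}

#' Write callable regions to a BED file
#' @param gr `GRanges` of callable regions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callable_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a signature catalog TSV (COSMIC layout)
#'
#' First column holds category labels (96 SBS or 83 ID categories, any row
#' order), remaining columns one signature profile each. Profiles must be
#' non-negative and sum to 1 within 1e-6 (they are renormalised exactly);
#' anything else is an error.
#'
#' @param path Path to the TSV.
#' @return A `signature_catalog`: list with `scheme` (`"SBS96"` or `"ID"`),
#'   `categories`, and `signatures` (matrix, categories x signatures,
#'   columns summing to 1).
#' @export
read_signature_catalog <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  cats <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- cats
  new_signature_catalog(mat)
}

new_signature_catalog <- function(mat) {
  cats <- rownames(mat)
  scheme <- if (setequal(cats, sbs96_categories())) "SBS96"
            else if (setequal(cats, id_categories())) "ID"
            else stopf("catalog categories match neither the SBS96 nor the ID scheme")
  ref_order <- if (scheme == "SBS96") sbs96_categories() else id_categories()
  mat <- mat[ref_order, , drop = FALSE]
  if (any(is.na(mat)) || any(mat < 0))
    stopf("signature profiles must be non-negative and complete")
  sums <- colSums(mat)
  off <- abs(sums - 1) > 1e-6
  if (any(off))
    stopf("signature profile(s) not summing to 1: %s",
          paste(colnames(mat)[off], collapse = ", "))
  mat <- sweep(mat, 2L, sums, "/")
  structure(list(scheme = scheme, categories = ref_order, signatures = mat),
            class = "signature_catalog")
}

#' Write a signature catalog TSV
#' @param catalog A `signature_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(Type = catalog$categories,
                   as.data.frame(catalog$signatures),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the final candidate-gene table
#'
#' One row per selected (gene, family) variant, in the layout of the study's
#' headline table: gene, family, variant (HGVS), predictor score, maximum
#' population allele frequency, evidence class (`G` for germline-only,
#' `G-S paired analysis` when a somatic second hit supports the gene) and the
#' selection criterion. Rows are ordered by family then gene so output is
#' deterministic.
#'
#' @param candidates data.frame with columns `gene`, `family_id`, `variant`,
#'   `predictor_score`, `max_pop_af`, `evidence`, `selection_criterion`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("gene", "family_id", "variant", "predictor_score",
            "max_pop_af", "evidence", "selection_criterion")
  if (nrow(candidates) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  miss <- setdiff(cols, names(candidates))
  if (length(miss) > 0L)
    stopf("candidate table lacks column(s): %s", paste(miss, collapse = ", "))
  cand <- candidates[radix_order(candidates$family_id, candidates$gene), cols]
  cand$max_pop_af <- ifelse(is.na(cand$max_pop_af) | cand$max_pop_af == 0,
                            "N/A", sprintf("%.8g", cand$max_pop_af))
  cand$predictor_score <- ifelse(is.na(cand$predictor_score), "N/A",
                                 as.character(cand$predictor_score))
  write.table(cand, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the gene map
#'
#' Genes are modelled as named, non-overlapping intervals on the synthetic
#' reference (only gene membership matters to the analysis). The on-disk
#' format is a GFF-like TSV: `chrom`, `start`, `end` (1-based inclusive),
#' `gene`.
#'
#' @param path Path to the gene-map TSV.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_map <- function(path) {
  gm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(gm))) stopf("gene map needs columns %s",
                                       paste(need, collapse = ", "))
  gm
}

#' @rdname read_gene_map
#' @param gene_map Gene-map data.frame.
#' @export
write_gene_map <- function(gene_map, path) {
  write.table(gene_map[, c("chrom", "start", "end", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gene_map_granges <- function(gene_map) {
  GenomicRanges::GRanges(gene_map$chrom,
                         IRanges::IRanges(gene_map$start, gene_map$end),
                         gene = gene_map$gene)
}

# gene symbol at (chrom, pos), "" when intergenic; gene intervals are
# non-overlapping, so an interval-index lookup suffices
gene_at <- function(gene_map, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  out <- rep("", length(pos))
  for (ch in unique(chrom)) {
    gm <- gene_map[gene_map$chrom == ch, , drop = FALSE]
    gm <- gm[order(gm$start), , drop = FALSE]
    sel <- chrom == ch
    idx <- findInterval(pos[sel], gm$start)
    ok <- idx >= 1L & pos[sel] <= gm$end[pmax(idx, 1L)]
    res <- rep("", sum(sel))
    res[ok] <- gm$gene[idx[ok]]
    out[sel] <- res
  }
  out
}
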