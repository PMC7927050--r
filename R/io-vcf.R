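#' Read an annotated VCF into variant and genotype tables
#'
#' Parses a VCF v4.x file whose annotation is carried as INFO tags (the
#' pipeline consumes annotation, it never computes it): `GENE` (string),
#' `IMPACT` (per-ALT string), `PAF_<db>` (per-ALT float population allele
#' frequency, one tag per database), `PRED_<tool>` (per-ALT `D`/`T`/`U`
#' verdict for each of [predictor_tools()]), and `HGVSP` (per-ALT protein
#' change). Multi-allelic records are decomposed into one row per ALT allele.
#'
#' The derived `maf` column is the maximum over all population frequencies
#' present for the variant, and 0 when the variant is absent from every
#' database (a deliberately conservative joint reading of multiple frequency
#' resources).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_filter Optional character vector; keep genotypes only for
#'   these samples.
#' @return List with elements `variants` (data.frame, one row per
#'   (record, ALT) with columns `vid`, `chrom`, `pos`, `ref`, `alt`,
#'   `var_class`, `gene`, `impact`, `protein_change`, `maf`, `paf.<db>` and
#'   `pred.<tool>` columns) and `genotypes` (data.frame with `vid`,
#'   `sample_id`, `gt` in `hom_ref`/`het`/`hom_alt`/`missing`, `ref_count`,
#'   `alt_count`, `depth`).
#' @export
read_annotated_vcf <- function(path, sample_filter = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  hdr <- tryCatch(
    VariantAnnotation::scanVcfHeader(path),
    error = function(e) stopf("malformed VCF '%s': %s", path,
                              conditionMessage(e))
  )
  # site-only files: skip genotype parsing entirely (expand() chokes on
  # FORMAT declarations without sample columns)
  param <- if (length(VariantAnnotation::samples(hdr)) == 0L)
    VariantAnnotation::ScanVcfParam(geno = NA) else
    VariantAnnotation::ScanVcfParam()
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, param = param),
    error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e))
  )
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  evcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(evcf)
  info <- VariantAnnotation::info(evcf)
  alt_index <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  if (any(alt == ref))
    stopf("VCF '%s': ALT equals REF at %s:%d", path,
          chrom[alt == ref][1], pos[alt == ref][1])

  get_info_chr <- function(tag, default = "") {
    if (!tag %in% names(info)) return(rep(default, length(chrom)))
    v <- as.character(info[[tag]])
    ifelse(is.na(v) | v == ".", default, v)
  }

  impact_raw <- get_info_chr("IMPACT", "other")
  impact <- normalize_impact(impact_raw)

  variants <- data.frame(
    vid = variant_id(chrom, pos, ref, alt),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    var_class = variant_class(ref, alt),
    gene = get_info_chr("GENE", ""),
    impact = impact,
    protein_change = get_info_chr("HGVSP", ""),
    stringsAsFactors = FALSE
  )

  paf_tags <- grep("^PAF_", names(info), value = TRUE)
  for (tag in paf_tags) {
    v <- suppressWarnings(as.numeric(info[[tag]]))
    variants[[sub("^PAF_", "paf.", tag)]] <- v
  }

  tools <- predictor_tools()
  pred_tags <- grep("^PRED_", names(info), value = TRUE)
  extra <- setdiff(sub("^PRED_", "", pred_tags), tools)
  if (length(extra) > 0L)
    stopf("VCF '%s' carries predictor tag(s) outside the configured six: %s",
          path, paste(extra, collapse = ", "))
  for (tl in tools) {
    tag <- paste0("PRED_", tl)
    v <- if (tag %in% names(info)) as.character(info[[tag]]) else
      rep("U", nrow(variants))
    v[is.na(v) | !(v %in% c("D", "T", "U"))] <- "U"
    variants[[paste0("pred.", tl)]] <- v
  }
  variants <- recompute_maf(variants)

  genotypes <- empty_genotype_table()
  gt_mat <- tryCatch(VariantAnnotation::geno(evcf)$GT,
                     error = function(e) NULL)
  samples <- colnames(gt_mat)
  if (!is.null(sample_filter)) samples <- intersect(samples, sample_filter)
  if (length(samples) > 0L && nrow(variants) > 0L) {
    ad <- VariantAnnotation::geno(evcf)$AD
    dp <- VariantAnnotation::geno(evcf)$DP
    out <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      s <- samples[j]
      gts <- gt_mat[, s]
      gt <- gt_code(gts, alt_index)
      if (!is.null(ad) && length(dim(ad)) == 3L) {
        rc <- as.integer(ad[, s, 1L])
        ac <- as.integer(ad[, s, 2L])
      } else {
        rc <- rep(NA_integer_, nrow(variants))
        ac <- rc
      }
      dpt <- if (!is.null(dp)) as.integer(dp[, s]) else
        as.integer(rc + ac)
      out[[j]] <- data.frame(
        vid = variants$vid, sample_id = s, gt = gt,
        ref_count = rc, alt_count = ac, depth = dpt,
        stringsAsFactors = FALSE
      )
    }
    genotypes <- do.call(rbind, out)
    rownames(genotypes) <- NULL
  }
  list(variants = variants, genotypes = genotypes)
}

# map raw impact strings onto the four impact classes; unknown strings give a
# record-level warning and fall back to "other"
normalize_impact <- function(x) {
  known <- impact_classes()
  trunc_syn <- c("stop_gained", "nonsense", "frameshift", "frameshift_variant",
                 "splice_acceptor", "splice_donor", "splice_acceptor_variant",
                 "splice_donor_variant")
  mis_syn <- c("missense_variant", "nonsynonymous")
  syn_syn <- c("synonymous_variant")
  out <- x
  out[x %in% trunc_syn] <- "truncating"
  out[x %in% mis_syn] <- "missense"
  out[x %in% syn_syn] <- "synonymous"
  bad <- !(out %in% known)
  if (any(bad)) {
    warnf("unknown IMPACT string(s) %s; coded as 'other'",
          paste(unique(x[bad]), collapse = ", "))
    out[bad] <- "other"
  }
  out
}

# genotype class of one sample for the alt allele with (per-record) index i
gt_code <- function(gt_strings, alt_index) {
  alleles <- strsplit(gt_strings, "[/|]")
  vapply(seq_along(gt_strings), function(k) {
    a <- alleles[[k]]
    if (length(a) == 0L || any(a == ".")) return("missing")
    hits <- sum(a == as.character(alt_index[k]))
    if (hits == 0L) "hom_ref" else if (hits == length(a)) "hom_alt" else "het"
  }, character(1))
}

#' Write variant and genotype tables as an annotated VCF
#'
#' Inverse of [read_annotated_vcf()] for biallelic rows (each table row
#' becomes one VCF record). Emits the INFO/FORMAT schema the reader expects,
#' so write-then-read round-trips variant and genotype content exactly.
#'
#' @param variants Variant table (see [read_annotated_vcf()]).
#' @param genotypes Genotype table; may be empty for a site-only VCF.
#' @param path Output path.
#' @param contigs Named integer vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, genotypes, path,
                                contigs = NULL) {
  assert_variant_table(variants)
  samples <- sort(unique(genotypes$sample_id))
  paf_cols <- grep("^paf\\.", names(variants), value = TRUE)
  tools <- predictor_tools()

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=serrata",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"Impact class\">",
    "##INFO=<ID=HGVSP,Number=A,Type=String,Description=\"Protein change\">",
    sprintf("##INFO=<ID=PAF_%s,Number=A,Type=Float,Description=\"Population allele frequency (%s)\">",
            sub("^paf\\.", "", paf_cols), sub("^paf\\.", "", paf_cols)),
    sprintf("##INFO=<ID=PRED_%s,Number=A,Type=String,Description=\"Predictor verdict (%s): D/T/U\">",
            tools, tools),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples) > 0L) c("FORMAT", samples)), collapse = "\t")
  )

  ord <- radix_order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]

  info_field <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    parts <- c(
      paste0("GENE=", ifelse(v$gene == "", ".", v$gene)),
      paste0("IMPACT=", v$impact),
      if (nzchar(v$protein_change)) paste0("HGVSP=", v$protein_change)
    )
    for (pc in paf_cols) {
      val <- v[[pc]]
      if (!is.na(val))
        parts <- c(parts, sprintf("PAF_%s=%.8g", sub("^paf\\.", "", pc), val))
    }
    for (tl in tools) {
      verdict <- v[[paste0("pred.", tl)]]
      if (!is.na(verdict) && verdict != "U")
        parts <- c(parts, paste0("PRED_", tl, "=", verdict))
    }
    paste(parts, collapse = ";")
  }, character(1))

  lines <- paste(variants$chrom, variants$pos, ".", variants$ref,
                 variants$alt, ".", "PASS", info_field, sep = "\t")

  if (length(samples) > 0L) {
    key <- paste(genotypes$vid, genotypes$sample_id, sep = "\r")
    gmap <- setNames(seq_len(nrow(genotypes)), key)
    gt_str <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")
    for (i in seq_len(nrow(variants))) {
      cells <- vapply(samples, function(s) {
        k <- gmap[[paste(variants$vid[i], s, sep = "\r")]]
        if (is.null(k)) return("./.:.,.:.")
        g <- genotypes[k, ]
        sprintf("%s:%s,%s:%s", gt_str[[g$gt]],
                ifelse(is.na(g$ref_count), ".", g$ref_count),
                ifelse(is.na(g$alt_count), ".", g$alt_count),
                ifelse(is.na(g$depth), ".", g$depth))
      }, character(1))
      lines[i] <- paste(c(lines[i], "GT:AD:DP", cells), collapse = "\t")
    }
  }

  writeLines(c(hdr, lines), path)
  invisible(path)
}
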