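# Internal helpers shared across modules. Nothing here is exported.

# canonical variant key
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# locale-independent ordering for deterministic table output
radix_order <- function(...) order(..., method = "radix")

# reverse complement for plain character vectors of ACGTN strings
revcomp_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# classify ref/alt pair into a variant class
variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  cls <- character(length(ref))
  cls[nr == 1L & na == 1L] <- "SNV"
  cls[nr == 1L & na > 1L] <- "insertion"
  cls[nr > 1L & na == 1L] <- "deletion"
  cls[nr > 1L & na > 1L] <- "MNV"
  cls
}

# substring of a reference chromosome, NA-safe at sequence bounds
ref_window <- function(reference, chrom, start, end) {
  seq <- reference[[chrom]]
  if (is.null(seq)) stopf("chromosome '%s' not in reference", chrom)
  n <- length(seq)
  if (start < 1L || end > n) return(NA_character_)
  as.character(Biostrings::subseq(seq, start, end))
}

# empty prototype for the variant table used throughout the package
empty_variant_table <- function() {
  tools <- predictor_tools()
  df <- data.frame(
    vid = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), var_class = character(0),
    gene = character(0), impact = character(0),
    protein_change = character(0), maf = numeric(0),
    stringsAsFactors = FALSE
  )
  for (tl in tools) df[[paste0("pred.", tl)]] <- character(0)
  df
}

empty_genotype_table <- function() {
  data.frame(
    vid = character(0), sample_id = character(0), gt = character(0),
    ref_count = integer(0), alt_count = integer(0), depth = integer(0),
    stringsAsFactors = FALSE
  )
}

# recompute maf = max over present population frequencies (paf.* columns)
recompute_maf <- function(variants) {
  paf_cols <- grep("^paf\\.", names(variants), value = TRUE)
  if (length(paf_cols) == 0L || nrow(variants) == 0L) {
    variants$maf <- rep(0, nrow(variants))
    return(variants)
  }
  m <- as.matrix(variants[, paf_cols, drop = FALSE])
  mx <- apply(m, 1L, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  variants$maf <- as.numeric(mx)
  variants
}

assert_variant_table <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "impact", "maf")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0L)
    stopf("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  invisible(variants)
}
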