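#' Classify SNVs into SBS96 trinucleotide-context categories
#'
#' Categories are pyrimidine-centred: when the reference base is a purine the
#' substitution and both flanks are reverse-complemented, so a mutation and
#' its reverse-complement representation always map to the same label
#' (strand involution).
#'
#' @param reference `DNAStringSet` named by chromosome.
#' @param chrom,pos,ref,alt Parallel vectors describing SNVs (single-base
#'   ref and alt).
#' @return Character vector of SBS96 labels; `NA` when the trinucleotide
#'   context contains `N` or falls off the sequence end (unclassifiable).
#' @export
sbs96_classify <- function(reference, chrom, pos, ref, alt) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  stopifnot(length(ref) == n, length(alt) == n)
  if (n == 0L) return(character(0))
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stopf("sbs96_classify expects single-base SNVs")
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    seq <- reference[[ch]]
    if (is.null(seq)) stopf("chromosome '%s' not in reference", ch)
    len <- length(seq)
    p <- pos[idx]
    inner <- p > 1L & p < len
    ctx <- rep(NA_character_, length(idx))
    if (any(inner)) {
      v <- Biostrings::Views(seq, start = p[inner] - 1L, end = p[inner] + 1L)
      ctx[inner] <- as.character(v)
    }
    centre <- substr(ctx, 2L, 2L)
    bad_ref <- !is.na(ctx) & centre != ref[idx]
    if (any(bad_ref))
      stopf("reference mismatch at %s:%d (FASTA %s, VCF REF %s)",
            ch, p[bad_ref][1], centre[bad_ref][1], ref[idx][bad_ref][1])
    out[idx] <- ctx
  }
  has_n <- grepl("N", out, fixed = TRUE)
  out[has_n] <- NA_character_
  ok <- !is.na(out)
  if (any(ok)) {
    ctx <- out[ok]
    a <- alt[ok]
    purine <- substr(ctx, 2L, 2L) %in% c("A", "G")
    ctx[purine] <- revcomp_chr(ctx[purine])
    a[purine] <- chartr("ACGT", "TGCA", a[purine])
    out[ok] <- paste0(substr(ctx, 1L, 1L), "[", substr(ctx, 2L, 2L), ">",
                      a, "]", substr(ctx, 3L, 3L))
  }
  out
}

#' Classify small insertions/deletions into ID83 categories
#'
#' Expects VCF-style anchored alleles: a pure insertion has `ref` equal to the
#' first base of `alt`, a pure deletion has `alt` equal to the first base of
#' `ref`. Anything else (complex substitutions) is unclassifiable (`NA`).
#' See [id_categories()] for the bin grammar (homopolymer run length for 1 bp
#' events, tandem-repeat unit count for longer events, microhomology bins for
#' non-repeated deletions).
#'
#' @param reference `DNAStringSet` named by chromosome.
#' @param chrom,pos,ref,alt Parallel vectors of VCF-style indel records.
#' @return Character vector of ID83 labels, `NA` for unclassifiable events.
#' @export
id_classify <- function(reference, chrom, pos, ref, alt) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  stopifnot(length(ref) == n, length(alt) == n)
  vapply(seq_len(n), function(i) {
    id_classify_one(reference, chrom[i], pos[i], ref[i], alt[i])
  }, character(1))
}

id_classify_one <- function(reference, chrom, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(NA_character_)
  is_ins <- na > nr
  if (is_ins) {
    if (nr != 1L || substr(alt, 1L, 1L) != ref) return(NA_character_)
    unit <- substr(alt, 2L, na)
  } else {
    if (na != 1L || substr(ref, 1L, 1L) != alt) return(NA_character_)
    unit <- substr(ref, 2L, nr)
  }
  if (grepl("N", unit, fixed = TRUE)) return(NA_character_)
  L <- nchar(unit)
  seqlen <- length(reference[[chrom]])
  # window generous enough to count runs/repeats up to the 6+/5+ caps
  win_lo <- max(1L, pos - 8L * L - 8L)
  win_hi <- min(seqlen, pos + 9L * L + 8L)
  win <- ref_window(reference, chrom, win_lo, win_hi)
  if (is.na(win)) return(NA_character_)
  # offset of the base *after* the anchor within the window (1-based)
  anchor <- pos - win_lo + 1L
  if (is_ins) {
    n_copies <- count_tandem_copies(win, anchor + 1L, unit, deleted = FALSE)
    if (L == 1L) {
      base <- if (unit %in% c("A", "G")) chartr("AG", "TC", unit) else unit
      k <- min(n_copies, 5L)
      lab <- if (n_copies >= 5L) "5+" else as.character(k)
      sprintf("1:Ins:%s:%s", base, lab)
    } else {
      size <- if (L >= 5L) "5+" else as.character(L)
      lab <- if (n_copies >= 5L) "5+" else as.character(n_copies)
      sprintf("%s:Ins:R:%s", size, lab)
    }
  } else {
    # deleted segment occupies window positions anchor+1 .. anchor+L
    n_copies <- count_tandem_copies(win, anchor + 1L, unit, deleted = TRUE)
    if (L == 1L) {
      base <- if (unit %in% c("A", "G")) chartr("AG", "TC", unit) else unit
      lab <- if (n_copies >= 6L) "6+" else as.character(n_copies)
      sprintf("1:Del:%s:%s", base, lab)
    } else {
      size <- if (L >= 5L) "5+" else as.character(L)
      if (n_copies >= 2L) {
        lab <- if (n_copies >= 6L) "6+" else as.character(n_copies)
        sprintf("%s:Del:R:%s", size, lab)
      } else {
        mh <- microhomology_length(win, anchor + 1L, unit)
        if (mh >= 1L) {
          cap <- if (L >= 5L) 5L else L - 1L
          lab <- if (L >= 5L && mh >= 5L) "5+" else as.character(min(mh, cap))
          sprintf("%s:Del:M:%s", size, lab)
        } else {
          sprintf("%s:Del:R:1", size)
        }
      }
    }
  }
}

# Tandem copies of `unit` at window position `at`. For deletions `at` is the
# start of the deleted copy (counted); for insertions `at` is the insertion
# point and only pre-existing copies on either side are counted.
count_tandem_copies <- function(win, at, unit, deleted) {
  L <- nchar(unit)
  n <- 0L
  if (deleted) {
    n <- 1L
    p <- at + L
  } else {
    p <- at
  }
  while (p + L - 1L <= nchar(win) && substr(win, p, p + L - 1L) == unit) {
    n <- n + 1L
    p <- p + L
  }
  p <- at - L
  while (p >= 1L && substr(win, p, p + L - 1L) == unit) {
    n <- n + 1L
    p <- p - L
  }
  n
}

# Longest flanking microhomology of a deleted segment starting at window
# position `at`: max over (prefix of unit matching sequence right of the
# segment) and (suffix of unit matching sequence left of it), capped at L-1.
microhomology_length <- function(win, at, unit) {
  L <- nchar(unit)
  right_start <- at + L
  mh_r <- 0L
  while (mh_r < L - 1L &&
         right_start + mh_r <= nchar(win) &&
         substr(unit, mh_r + 1L, mh_r + 1L) ==
           substr(win, right_start + mh_r, right_start + mh_r)) {
    mh_r <- mh_r + 1L
  }
  mh_l <- 0L
  while (mh_l < L - 1L && at - 1L - mh_l >= 1L &&
         substr(unit, L - mh_l, L - mh_l) ==
           substr(win, at - 1L - mh_l, at - 1L - mh_l)) {
    mh_l <- mh_l + 1L
  }
  max(mh_r, mh_l)
}

#' Build a mutation-category count vector for one sample
#'
#' Counts classifiable mutations of the requested scheme over its categories;
#' mutations of the other type (e.g. indels under `scheme = "SBS96"`) and
#' unclassifiable events are tallied separately so that
#' `sum(counts) + unclassified + other_type == nrow(mutations)`.
#'
#' @param mutations Variant table (needs `chrom`, `pos`, `ref`, `alt`,
#'   `var_class`).
#' @param reference `DNAStringSet` named by chromosome.
#' @param scheme `"SBS96"` or `"ID"`.
#' @param sample_id Optional sample label carried in the result.
#' @return A `catalog_vector`: list with `scheme`, `sample_id`, `counts`
#'   (named integer vector over the scheme categories), `unclassified`
#'   (mutations of the right type without a valid context) and `other_type`.
#' @export
build_catalog <- function(mutations, reference, scheme = c("SBS96", "ID"),
                          sample_id = NA_character_) {
  scheme <- match.arg(scheme)
  cats <- if (scheme == "SBS96") sbs96_categories() else id_categories()
  counts <- setNames(integer(length(cats)), cats)
  if (nrow(mutations) == 0L) {
    return(structure(list(scheme = scheme, sample_id = sample_id,
                          counts = counts, unclassified = 0L,
                          other_type = 0L),
                     class = "catalog_vector"))
  }
  is_snv <- mutations$var_class == "SNV"
  sel <- if (scheme == "SBS96") is_snv else
    mutations$var_class %in% c("insertion", "deletion")
  m <- mutations[sel, , drop = FALSE]
  labels <- if (scheme == "SBS96") {
    sbs96_classify(reference, m$chrom, m$pos, m$ref, m$alt)
  } else {
    id_classify(reference, m$chrom, m$pos, m$ref, m$alt)
  }
  tab <- table(factor(labels[!is.na(labels)], levels = cats))
  counts[] <- as.integer(tab)
  structure(list(scheme = scheme, sample_id = sample_id, counts = counts,
                 unclassified = sum(is.na(labels)),
                 other_type = nrow(mutations) - nrow(m)),
            class = "catalog_vector")
}

#' Tumor mutational burden and hypermutation class
#'
#' Burden is mutations per megabase of callable footprint. SNV and indel
#' burdens are reported separately and combined; the hypermutation class is
#' assigned on the combined burden with strict thresholds: `> 10` mut/Mb is
#' hypermutated, `> 100` mut/Mb is ultra-hypermutated (a sample at exactly
#' 10 is non-hypermutated).
#'
#' @param n_snv,n_indel Counts of somatic SNVs and indels.
#' @param footprint_mb Callable footprint in Mb (must be > 0).
#' @param sample_id Optional sample label.
#' @return data.frame (one row) with `sample_id`, `n_snv`, `n_indel`,
#'   `footprint_mb`, `snv_tmb`, `indel_burden`, `tmb`, `load_class`.
#' @export
compute_burden <- function(n_snv, n_indel, footprint_mb,
                           sample_id = NA_character_) {
  if (!is.finite(footprint_mb) || footprint_mb <= 0)
    stopf("footprint_mb must be positive")
  snv_tmb <- n_snv / footprint_mb
  indel_burden <- n_indel / footprint_mb
  tmb <- (n_snv + n_indel) / footprint_mb
  load_class <- if (tmb > 100) "ultra_hypermutated"
                else if (tmb > 10) "hypermutated"
                else "non_hypermutated"
  data.frame(sample_id = sample_id, n_snv = n_snv, n_indel = n_indel,
             footprint_mb = footprint_mb, snv_tmb = snv_tmb,
             indel_burden = indel_burden, tmb = tmb,
             load_class = load_class, stringsAsFactors = FALSE)
}

# callable footprint of a GRanges in Mb
footprint_mb <- function(gr) {
  sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(gr)))) / 1e6
}
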