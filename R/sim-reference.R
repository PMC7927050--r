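#' Generate the synthetic reference sequence
#'
#' A deterministic pseudo-random nucleotide sequence (uniform base
#' composition, single chromosome `chr1`) used consistently by the simulator
#' and the context classifiers. A synthetic reference instead of GRCh37
#' keeps the package download-free and desk-scale; at >= 1 Mb all 32
#' pyrimidine-centred trinucleotides are guaranteed present (checked).
#'
#' @param length_mb Sequence length in megabases (>= 1).
#' @param seed Integer seed; fixes the sequence byte-for-byte.
#' @param path Optional FASTA output path; when given the sequence is
#'   written and faidx-indexed.
#' @return A `DNAStringSet` named `chr1`, invisibly when `path` is given.
#' @export
make_reference <- function(length_mb = 5, seed = 1, path = NULL) {
  if (length_mb < 1) stopf("reference length must be >= 1 Mb")
  n <- as.integer(length_mb * 1e6)
  seq_chr <- local({
    set.seed(seed)
    rawToChar(as.raw(c(65L, 67L, 71L, 84L)[sample.int(4L, n,
                                                      replace = TRUE)]))
  })
  ref <- Biostrings::DNAStringSet(seq_chr)
  names(ref) <- "chr1"
  if (any(Biostrings::trinucleotideFrequency(ref[[1]]) == 0L))
    stopf("reference too short: some trinucleotide contexts are absent")
  if (!is.null(path)) {
    Biostrings::writeXStringSet(ref, path)
    Rsamtools::indexFa(path)
    return(invisible(ref))
  }
  ref
}

# Index of the reference used for context-aware mutation placement:
#  $sbs  - named list, "<chrom>:<trinuc>" with pyrimidine-normalised
#          trinucleotide (e.g. "chr1:ACG", centre C/T) -> integer positions
#          of the centre base
#  $runs - per chromosome and base (C/T), homopolymer run starts split by
#          run length capped at 7 (bins "1".."6", "7" = length >= 7)
build_context_index <- function(reference) {
  sbs <- list()
  runs <- list()
  for (ch in names(reference)) {
    x <- as.integer(charToRaw(as.character(reference[[ch]])))
    b <- match(x, c(65L, 67L, 71L, 84L)) - 1L  # A C G T -> 0..3
    n <- length(b)
    f5 <- b[seq_len(n - 2L)]
    ce <- b[seq_len(n - 2L) + 1L]
    f3 <- b[seq_len(n - 2L) + 2L]
    code <- (3L - f3) * 16L + (3L - ce) * 4L + (3L - f5)
    pyr <- which(ce == 1L | ce == 3L)
    code[pyr] <- f5[pyr] * 16L + ce[pyr] * 4L + f3[pyr]
    pos <- seq_len(n - 2L) + 1L
    ok <- !is.na(code)
    grp <- split(pos[ok], code[ok])
    bases <- c("A", "C", "G", "T")
    labs <- vapply(as.integer(names(grp)), function(cd) {
      paste0(bases[cd %/% 16L + 1L], bases[(cd %/% 4L) %% 4L + 1L],
             bases[cd %% 4L + 1L])
    }, character(1))
    names(grp) <- paste(ch, labs, sep = ":")
    sbs <- c(sbs, grp)
    r <- rle(b)
    starts <- cumsum(r$lengths) - r$lengths + 1L
    by_base <- list()
    for (bb in c("C", "T")) {
      vv <- if (bb == "C") 1L else 3L
      sel <- which(r$values == vv)
      by_base[[bb]] <- split(starts[sel],
                             pmin(r$lengths[sel], 7L))
    }
    runs[[ch]] <- by_base
  }
  list(sbs = sbs, runs = runs)
}

#' Lay out the synthetic gene map
#'
#' Tiles the reference with fixed-width gene intervals (20 kb gene,
#' 5 kb intergenic gap) and assigns the cohort's special gene symbols -
#' planted candidate genes, driver genes and exclusion-list fodder - to
#' evenly spread slots, filling the rest with `GENE0001`-style symbols.
#' Only gene membership matters downstream, so intervals are deliberately
#' simple and non-overlapping.
#'
#' @param reference `DNAStringSet` from [make_reference()].
#' @param special_genes Character vector of symbols to spread over the map.
#' @param gene_width,gap Interval geometry in bp.
#' @return Gene-map data.frame (`chrom`, `start`, `end`, `gene`).
#' @export
make_gene_map <- function(reference, special_genes = character(0),
                          gene_width = 20000L, gap = 5000L) {
  ch <- names(reference)[1]
  len <- length(reference[[ch]])
  pitch <- gene_width + gap
  n_genes <- len %/% pitch
  if (n_genes < length(special_genes) * 2L)
    stopf("reference too short for %d special genes", length(special_genes))
  start <- (seq_len(n_genes) - 1L) * pitch + gap %/% 2L + 1L
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  if (length(special_genes) > 0L) {
    slots <- round(seq(2L, n_genes - 1L, length.out = length(special_genes)))
    genes[slots] <- special_genes
  }
  data.frame(chrom = ch, start = start, end = start + gene_width - 1L,
             gene = genes, stringsAsFactors = FALSE)
}

#' Synthetic SBS signature profiles
#'
#' Deterministic stand-ins for the COSMIC SBS profiles used by the study
#' (the true profiles are an external database and do not ship here). Each
#' profile is a valid distribution over the 96 categories and mimics the
#' qualitative focus of its namesake: SBS1 concentrates C>T at NpCpG
#' (5-methylcytosine deamination), SBS5 is the broadest (clock-like) shape,
#' spread over all T>C contexts, SBS15 and SBS21 are MMR-deficiency-like
#' (C>T at GpCpH and T>C at ApTpN respectively), and SBS54 is a
#' contamination/artifact-like shape on T>A. Peak masses are chosen so the
#' profiles are mutually well conditioned for non-negative least squares -
#' the property refitting tests require - rather than to reproduce COSMIC
#' numerically.
#'
#' @return A `signature_catalog` with scheme `SBS96`.
#' @export
synthetic_sbs_catalog <- function() {
  cats <- sbs96_categories()
  mk <- function(assign, peak) {
    floor_w <- (1 - peak) / 96
    p <- rep(floor_w, 96)
    names(p) <- cats
    tot <- sum(unlist(assign))
    for (cat in names(assign))
      p[[cat]] <- p[[cat]] + peak * assign[[cat]] / tot
    p / sum(p)
  }
  npg <- paste0(c("A", "C", "G", "T"), "[C>T]G")
  tcn <- cats[grepl("T>C", cats, fixed = TRUE)]
  gcn <- paste0("G[C>T]", c("A", "C", "T"))
  atn <- paste0("A[T>C]", c("A", "C", "G", "T"))
  ta <- cats[grepl("T>A", cats, fixed = TRUE)]
  mat <- cbind(
    SBS1 = mk(setNames(as.list(rep(1, 4)), npg), 0.8),
    SBS5 = mk(setNames(as.list(rep(1, 16)), tcn), 0.6),
    SBS15 = mk(setNames(as.list(rep(1, 3)), gcn), 0.8),
    SBS21 = mk(setNames(as.list(rep(1, 4)), atn), 0.8),
    SBS54 = mk(setNames(as.list(rep(1, length(ta))), ta), 0.7)
  )
  rownames(mat) <- cats
  new_signature_catalog(mat)
}

#' Synthetic ID signature profiles
#'
#' Deterministic stand-ins for the COSMIC ID profiles: ID1 is 1 bp T
#' insertion at long T homopolymers, ID2 is 1 bp T deletion at long T
#' homopolymers (both clock-like and elevated under MMR deficiency), and an
#' ID12-like profile concentrated on short-run 1 bp C events. All mass sits
#' in 1 bp bins so that every sampled category is placeable on the synthetic
#' reference.
#'
#' @return A `signature_catalog` with scheme `ID`.
#' @export
synthetic_id_catalog <- function() {
  cats <- id_categories()
  mk <- function(assign) {
    p <- setNames(rep(0, length(cats)), cats)
    for (cat in names(assign)) p[[cat]] <- assign[[cat]]
    p / sum(p)
  }
  id1 <- mk(list("1:Ins:T:3" = 0.1, "1:Ins:T:4" = 0.3, "1:Ins:T:5+" = 0.6))
  id2 <- mk(list("1:Del:T:4" = 0.1, "1:Del:T:5" = 0.3, "1:Del:T:6+" = 0.6))
  id12 <- mk(list("1:Del:C:1" = 0.3, "1:Del:C:2" = 0.3, "1:Ins:C:0" = 0.25,
                  "1:Ins:C:1" = 0.15))
  mat <- cbind(ID1 = id1, ID2 = id2, ID12 = id12)
  rownames(mat) <- cats
  new_signature_catalog(mat)
}
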