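#' The six pathogenicity predictor tools consumed from VCF annotation
#'
#' Variant deleteriousness is summarised as the number of "deleterious"
#' verdicts among six standard predictors (conservation and protein-impact
#' based). Verdicts arrive as `PRED_<tool>` INFO tags with values
#' `D` (deleterious), `T` (tolerated) or `U` (unavailable).
#'
#' @return Character vector of the six tool names.
#' @export
predictor_tools <- function() {
  c("PhyloP", "SIFT", "PolyPhen", "MutationTaster", "GERP", "LRT")
}

#' Variant impact classes
#'
#' `truncating` covers nonsense, frameshift and essential-splice (+/-1,2)
#' changes; everything that is neither synonymous, missense nor truncating is
#' `other`.
#'
#' @return Character vector of the four impact classes.
#' @export
impact_classes <- function() {
  c("synonymous", "missense", "truncating", "other")
}

#' Cancer driver genes reported without the somatic AAF confidence threshold
#'
#' BRAF/KRAS (serrated-pathway oncogenes), the replicative polymerases
#' POLE/POLD1 and the DNA mismatch-repair genes. Somatic variants in these
#' genes are always reported, tiered by alternative allele frequency.
#'
#' @return Character vector of ten gene symbols.
#' @export
driver_genes <- function() {
  c("BRAF", "KRAS", "POLE", "POLD1",
    "MLH1", "MLH3", "MSH2", "MSH3", "MSH6", "PMS2")
}

#' Known driver hotspot protein changes
#'
#' Exact HGVS-p short strings matched by string equality (no codon
#' recomputation).
#'
#' @return Named character vector, names are gene symbols.
#' @export
driver_hotspots <- function() {
  c(BRAF = "V600E", KRAS = "A146T")
}

#' SBS96 category labels
#'
#' The 96 pyrimidine-centred single-base-substitution categories in COSMIC
#' layout: substitution-major order (C>A, C>G, C>T, T>A, T>C, T>G), then 5'
#' flank, then 3' flank, e.g. `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f3 = bases, f5 = bases, sub = subs,
                      stringsAsFactors = FALSE)[, c("sub", "f5", "f3")]
  grid <- grid[order(match(grid$sub, subs), match(grid$f5, bases),
                     match(grid$f3, bases)), ]
  paste0(grid$f5, "[", grid$sub, "]", grid$f3)
}

#' ID83 indel category labels
#'
#' The 83 small insertion/deletion categories, COSMIC-style. Label grammar is
#' `<size>:<Del|Ins>:<C|T|R|M>:<n>`:
#'
#' * `1:Del:C:k` / `1:Del:T:k` - 1 bp deletion of a C or T (pyrimidine
#'   strand), `k` = homopolymer run length of that base in the reference
#'   *including* the deleted copy, binned 1..5, `6+`.
#' * `1:Ins:C:k` / `1:Ins:T:k` - 1 bp insertion, `k` = copies of the inserted
#'   base already present around the insertion point, binned 0..4, `5+`.
#' * `<L>:Del:R:k` - deletion of an L bp unit (L in 2,3,4,`5+`), `k` = tandem
#'   copies of the unit in the reference including the deleted copy, binned
#'   1..5, `6+`.
#' * `<L>:Ins:R:k` - insertion of an L bp unit, `k` = tandem copies already
#'   present, binned 0..4, `5+`.
#' * `<L>:Del:M:m` - deletion of an L bp unit with no tandem copy but with
#'   `m` bp of flanking microhomology (L in 2,3,4,`5+`; `m` capped at L-1,
#'   `5+` top bin for L=`5+`).
#'
#' @return Character vector of length 83.
#' @export
id_categories <- function() {
  run_del <- c("1", "2", "3", "4", "5", "6+")
  run_ins <- c("0", "1", "2", "3", "4", "5+")
  c(
    paste0("1:Del:C:", run_del),
    paste0("1:Del:T:", run_del),
    paste0("1:Ins:C:", run_ins),
    paste0("1:Ins:T:", run_ins),
    paste0(rep(c("2", "3", "4", "5+"), each = 6), ":Del:R:", run_del),
    paste0(rep(c("2", "3", "4", "5+"), each = 6), ":Ins:R:", run_ins),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5+:Del:M:", c("1", "2", "3", "4", "5+"))
  )
}

#' Default aetiology flag map for signature annotation
#'
#' Groups refitted signatures into interpretive classes: clock-like
#' (age-correlated) processes, DNA mismatch-repair deficiency, and likely
#' artifact/contamination signals.
#'
#' @return Named list of character vectors of signature names.
#' @export
default_flag_map <- function() {
  list(
    clock_like     = c("SBS1", "SBS5", "ID1", "ID2"),
    mmr_deficiency = c("SBS15", "SBS21", "ID1", "ID2"),
    artifact       = c("SBS54")
  )
}
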