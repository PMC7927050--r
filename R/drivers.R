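#' Report somatic variants in cancer driver genes
#'
#' Driver genes (see [driver_genes()]) are reported without the somatic AAF
#' confidence threshold: every variant is listed and tiered instead -
#' `high` confidence at AAF >= 0.20, `low` below. Known hotspot protein
#' changes ([driver_hotspots()]) are matched by exact string equality on the
#' normalised short HGVS-p (e.g. `V600E`).
#'
#' @param somatic Somatic sample object (list with `sample_id`, `mutations`,
#'   `depths`; see [second_hit_scan()]).
#' @param genes Driver gene symbols (default [driver_genes()]).
#' @param hotspots Named character vector of hotspot protein changes.
#' @param high_aaf High-confidence tier threshold (default 0.20, `>=`).
#' @return data.frame with `sample_id`, `gene`, `vid`, `protein_change`,
#'   `aaf`, `depth`, `tier`, `hotspot`.
#' @export
driver_report <- function(somatic, genes = driver_genes(),
                          hotspots = driver_hotspots(), high_aaf = 0.20) {
  empty <- data.frame(sample_id = character(0), gene = character(0),
                      vid = character(0), protein_change = character(0),
                      aaf = numeric(0), depth = integer(0),
                      tier = character(0), hotspot = logical(0),
                      stringsAsFactors = FALSE)
  mut <- somatic$mutations
  if (is.null(mut) || nrow(mut) == 0L) return(empty)
  mut <- merge(mut, somatic$depths, by = "vid")
  mut <- mut[mut$gene %in% genes, , drop = FALSE]
  if (nrow(mut) == 0L) return(empty)
  aaf <- ifelse(mut$depth > 0, mut$alt_count / mut$depth, 0)
  hs <- !is.na(hotspots[mut$gene]) & mut$protein_change == hotspots[mut$gene]
  out <- data.frame(
    sample_id = somatic$sample_id, gene = mut$gene, vid = mut$vid,
    protein_change = mut$protein_change, aaf = aaf, depth = mut$depth,
    tier = ifelse(aaf >= high_aaf, "high", "low"),
    hotspot = as.logical(hs), stringsAsFactors = FALSE
  )
  out <- out[radix_order(out$gene, out$vid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
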