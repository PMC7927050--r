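# Shared fixtures and independent oracles. Everything is built in code at
# test time; expensive cohort objects are cached for the duration of the
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# default germline-only cohort, seed 1
germline_cohort <- function() {
  cached("germline1", function()
    simulate_cohort(default_sim_config(1L), include_somatic = FALSE))
}

# default full cohort, seed 1
full_cohort <- function() {
  cached("full1", function() simulate_cohort(default_sim_config(1L)))
}

prioritized_germline <- function() {
  cached("pri1", function() prioritize_cohort(germline_cohort()))
}

# small literal reference for hand-checkable context tests
literal_reference <- function(seq_chr) {
  ref <- Biostrings::DNAStringSet(seq_chr)
  names(ref) <- "chr1"
  ref
}

# build one variant-table row without touching a reference
test_variant <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "C",
                         gene = "GENE1", impact = "missense",
                         votes = 0L, maf = NA_real_, hgvsp = "") {
  tools <- predictor_tools()
  verd <- rep("T", 6L)
  if (votes > 0L) verd[seq_len(votes)] <- "D"
  if (impact != "missense") verd <- rep("U", 6L)
  row <- data.frame(
    vid = paste(chrom, pos, ref, alt, sep = ":"), chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt,
    var_class = if (nchar(ref) == nchar(alt)) "SNV" else
      if (nchar(ref) > nchar(alt)) "deletion" else "insertion",
    gene = gene, impact = impact, protein_change = hgvsp,
    maf = ifelse(is.na(maf), 0, maf), stringsAsFactors = FALSE)
  row$paf.gnomAD <- maf
  for (i in seq_along(tools)) row[[paste0("pred.", tools[i])]] <- verd[i]
  row
}

test_genotype <- function(vid, sample_id, gt = "het", depth = 60L) {
  alt <- switch(gt, het = depth %/% 2L, hom_alt = depth, hom_ref = 0L,
                missing = 0L)
  data.frame(vid = vid, sample_id = sample_id, gt = gt,
             ref_count = depth - alt, alt_count = alt, depth = depth,
             stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# exact two-sided binomial p-value by direct enumeration of the point-mass
# criterion (independent of stats::binom.test)
oracle_binom_p <- function(alt, depth, p0 = 0.5) {
  d <- dbinom(0:depth, depth, p0)
  sum(d[d <= d[alt + 1L] * (1 + 1e-7)])
}

# exhaustive 0.01-grid search for a 2-signature refit
oracle_grid_refit <- function(v, s1, s2) {
  vn <- v / sum(v)
  grid <- seq(0, 1, by = 0.01)
  sse <- vapply(grid, function(w) sum((vn - (w * s1 + (1 - w) * s2))^2),
                numeric(1))
  grid[which.min(sse)]
}

# brute-force microhomology length of a deleted segment (string scanning)
oracle_mh <- function(seq_chr, del_start, del_len) {
  unit <- substr(seq_chr, del_start, del_start + del_len - 1L)
  right <- 0L
  while (right < del_len - 1L &&
         substr(unit, right + 1L, right + 1L) ==
           substr(seq_chr, del_start + del_len + right,
                  del_start + del_len + right)) right <- right + 1L
  left <- 0L
  while (left < del_len - 1L &&
         substr(unit, del_len - left, del_len - left) ==
           substr(seq_chr, del_start - 1L - left, del_start - 1L - left))
    left <- left + 1L
  max(left, right)
}

# naive per-variant re-evaluation of the full three-round filter stack;
# plain loops, no shared helpers with the implementation
oracle_prioritize <- function(cohort, gene_sets = default_gene_sets(),
                              maf_threshold = 0.001, min_votes = 3L) {
  tools <- paste0("pred.", predictor_tools())
  ped <- cohort$pedigree
  fams <- unique(ped$family_id)
  seg <- list()
  for (f in fams) {
    v <- cohort$families[[f]]$variants
    g <- cohort$families[[f]]$genotypes
    members <- ped$sample_id[ped$family_id == f & ped$affected &
                               ped$sequenced_germline]
    keep <- character(0)
    for (i in seq_len(nrow(v))) {
      score <- 0L
      for (tl in tools) if (v[[tl]][i] == "D") score <- score + 1L
      pass1 <- v$maf[i] < maf_threshold &&
        v$impact[i] %in% c("missense", "truncating") &&
        (v$impact[i] == "truncating" || score >= min_votes)
      if (!pass1) next
      shared <- TRUE
      for (m in members) {
        gm <- g[g$vid == v$vid[i] & g$sample_id == m, ]
        if (nrow(gm) == 0L || !(gm$gt[1] %in% c("het", "hom_alt")))
          shared <- FALSE
      }
      if (shared) keep <- c(keep, v$vid[i])
    }
    seg[[f]] <- keep
  }
  # cross-family: drop a vid when any family observing it fails sharing
  bad <- character(0)
  for (vid in unique(unlist(seg))) {
    for (f in fams) {
      g <- cohort$families[[f]]$genotypes
      carried <- g[g$vid == vid & g$gt %in% c("het", "hom_alt"), ]
      if (nrow(carried) == 0L) next
      members <- ped$sample_id[ped$family_id == f & ped$affected &
                                 ped$sequenced_germline]
      all_carry <- TRUE
      for (m in members) {
        gm <- g[g$vid == vid & g$sample_id == m, ]
        if (nrow(gm) == 0L || !(gm$gt[1] %in% c("het", "hom_alt")))
          all_carry <- FALSE
      }
      if (!all_carry) bad <- c(bad, vid)
    }
  }
  seg <- lapply(seg, function(k) setdiff(k, bad))
  excl <- unique(unlist(gene_sets$excluded))
  pri <- unique(unlist(gene_sets$prioritized))
  r2 <- list(); r3 <- list()
  for (f in fams) {
    v <- cohort$families[[f]]$variants
    vids2 <- character(0); vids3 <- character(0)
    for (vid in seg[[f]]) {
      gene <- v$gene[v$vid == vid][1]
      if (gene %in% excl) next
      vids2 <- c(vids2, vid)
      if (gene %in% pri) vids3 <- c(vids3, vid)
    }
    r2[[f]] <- vids2; r3[[f]] <- vids3
  }
  list(segregating = seg, round2 = r2, round3 = r3)
}
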