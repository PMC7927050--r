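# Germline cohort simulation: planted causal variants shared by all affected
# members, calibrated shared background surviving round 1, and noise variants
# that each violate at least one round-1 or segregation criterion.

# random SNV alt alleles different from ref (vectorized)
alt_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  alts <- vapply(bases, function(b) setdiff(bases, b),
                 character(3))  # 3 x 4, column per ref base
  pick <- sample.int(3L, length(ref), replace = TRUE)
  alts[cbind(pick, match(ref, bases))]
}

# build a block of variant-table rows at given positions (vectorized);
# `impact`, `votes`, `maf`, `hgvsp`, `indel` recycle to length(pos)
make_variant_rows <- function(reference, gene_map, chrom, pos, gene = NULL,
                              impact, votes = 0L, maf = NA_real_,
                              hgvsp = "", indel = FALSE, del = TRUE) {
  n <- length(pos)
  impact <- rep_len(impact, n); votes <- rep_len(as.integer(votes), n)
  maf <- rep_len(maf, n); hgvsp <- rep_len(hgvsp, n)
  indel <- rep_len(indel, n); del <- rep_len(del, n)
  chrom <- rep_len(chrom, n)
  seq1 <- reference[[chrom[1]]]
  base_at <- function(p) as.character(Biostrings::Views(seq1, p, p))
  ref <- character(n); alt <- character(n)
  if (any(!indel)) {
    r <- base_at(pos[!indel])
    ref[!indel] <- r
    alt[!indel] <- alt_base(r)
  }
  if (any(indel)) {
    anchor <- base_at(pos[indel])
    nxt <- base_at(pos[indel] + 1L)
    isdel <- del[indel]
    ref[indel] <- ifelse(isdel, paste0(anchor, nxt), anchor)
    ins <- sample(c("A", "C", "G", "T"), sum(indel), replace = TRUE)
    alt[indel] <- ifelse(isdel, anchor, paste0(anchor, ins))
  }
  if (is.null(gene)) gene <- gene_at(gene_map, chrom, pos)
  tools <- predictor_tools()
  verd <- matrix("U", nrow = n, ncol = 6L)
  mis <- impact == "missense"
  verd[mis, ] <- "T"
  for (i in which(mis & votes > 0L)) verd[i, sample.int(6L, votes[i])] <- "D"
  out <- data.frame(
    vid = variant_id(chrom, pos, ref, alt), chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt,
    var_class = variant_class(ref, alt), gene = gene, impact = impact,
    protein_change = hgvsp, maf = ifelse(is.na(maf), 0, maf),
    stringsAsFactors = FALSE
  )
  out$paf.gnomAD <- maf
  for (i in seq_along(tools)) out[[paste0("pred.", tools[i])]] <- verd[, i]
  out
}

make_variant_row <- make_variant_rows  # single-row alias used in places

# het genotype rows with binomial allele depths for vids x samples
het_genotype <- function(vid, sample_id, mean_depth) {
  grid <- expand.grid(sample_id = sample_id, vid = vid,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  depth <- pmax(10L, rpois(n, mean_depth))
  alt <- pmin(pmax(rbinom(n, depth, 0.5), 1L), depth - 1L)
  data.frame(vid = grid$vid, sample_id = grid$sample_id, gt = "het",
             ref_count = depth - alt, alt_count = alt, depth = depth,
             stringsAsFactors = FALSE)
}

hom_ref_genotype <- function(vid, sample_id, mean_depth) {
  grid <- expand.grid(sample_id = sample_id, vid = vid,
                      stringsAsFactors = FALSE)
  depth <- pmax(10L, rpois(nrow(grid), mean_depth))
  data.frame(vid = grid$vid, sample_id = grid$sample_id, gt = "hom_ref",
             ref_count = depth, alt_count = 0L, depth = depth,
             stringsAsFactors = FALSE)
}

# sample n distinct SNV positions inside the given genes, avoiding `used`
sample_gene_positions <- function(gene_map, genes, n, used) {
  rows <- gene_map[gene_map$gene %in% genes, , drop = FALSE]
  out <- integer(0)
  guard <- 0L
  while (length(out) < n && guard < 50L) {
    guard <- guard + 1L
    g <- rows[sample.int(nrow(rows), n - length(out), replace = TRUE), ,
              drop = FALSE]
    p <- g$start + floor(runif(nrow(g)) * (g$end - g$start - 2L)) + 1L
    p <- setdiff(unique(p), c(used, out))
    out <- c(out, p)
  }
  if (length(out) < n) stopf("could not place %d distinct variants", n)
  out[seq_len(n)]
}

#' Simulate one family's germline variants
#'
#' Plants the family's causal variant heterozygous in every affected member,
#' draws `Poisson(round1_survivor_mean - 1)` shared background variants built
#' to pass the round-1 filters, and adds background noise classes that each
#' violate one criterion: too-common variants, low-vote missense, synonymous
#' changes, and rare damaging variants carried by a single member (round-1
#' pass, segregation fail). Also emits a few common heterozygous SNPs inside
#' the causal gene as allelic-imbalance support sites for downstream LOH
#' testing.
#'
#' @param family_id Family identifier.
#' @param n_affected Number of affected, sequenced members.
#' @param config A `sim_config`.
#' @param reference,gene_map Synthetic reference and gene map.
#' @param seed Integer seed (fully determines the family's output).
#' @param used_positions Positions already consumed elsewhere in the cohort.
#' @return List with `members` (sample ids), `variants`, `genotypes`,
#'   `truth` (causal gene/vid, flanking het vids, survivor count) and
#'   `used_positions` (updated).
#' @export
simulate_family_germline <- function(family_id, n_affected, config,
                                     reference, gene_map, seed,
                                     used_positions = integer(0)) {
  set.seed(seed)
  members <- sprintf("%s.A%d", family_id, seq_len(n_affected))
  ca <- config$causal[config$causal$family_id == family_id, ]
  if (nrow(ca) != 1L) stopf("no causal spec for family %s", family_id)
  filler <- gene_map$gene[grepl("^GENE", gene_map$gene)]
  excl <- unlist(default_gene_sets()$excluded, use.names = FALSE)
  excl <- intersect(excl, gene_map$gene)
  vrows <- list(); grows <- list()
  used <- used_positions

  # planted causal variant
  cg <- gene_map[gene_map$gene == ca$gene, ]
  cpos <- cg$start + 500L
  causal <- make_variant_rows(reference, gene_map, cg$chrom, cpos,
                              gene = ca$gene, impact = ca$impact,
                              votes = ca$votes, maf = ca$maf,
                              hgvsp = ca$hgvsp,
                              indel = ca$impact == "truncating")
  used <- c(used, cpos, cpos + 1L)
  vrows$causal <- causal
  grows$causal <- het_genotype(causal$vid, members, config$germline_depth)

  # shared background surviving round 1 (the 24.5-per-family calibration)
  n_surv <- rpois(1L, max(0, config$round1_survivor_mean - 1))
  if (n_surv > 0L) {
    n_excl <- if (length(excl) > 0L)
      rbinom(1L, n_surv, config$excluded_gene_fraction) else 0L
    gene_pool <- c(sample(filler, max(1L, n_surv - n_excl), replace = TRUE),
                   if (n_excl > 0L) sample(excl, n_excl, replace = TRUE))
    pos <- sample_gene_positions(gene_map, unique(gene_pool), n_surv, used)
    used <- c(used, pos, pos + 1L)
    trunc <- runif(n_surv) < 0.10
    vrows$surv <- make_variant_rows(
      reference, gene_map, "chr1", pos,
      impact = ifelse(trunc, "truncating", "missense"),
      votes = ifelse(trunc, 0L, sample(3:6, n_surv, replace = TRUE)),
      maf = ifelse(runif(n_surv) < 0.3, NA_real_,
                   runif(n_surv, 0, 9.9e-4)),
      indel = trunc)
    grows$surv <- het_genotype(vrows$surv$vid, members,
                               config$germline_depth)
  }

  noise_block <- function(n, impact, votes_lo, votes_hi, maf_lo, maf_hi) {
    pos <- sample_gene_positions(gene_map, filler, n, used)
    used <<- c(used, pos)
    make_variant_rows(reference, gene_map, "chr1", pos, impact = impact,
                      votes = sample(votes_lo:votes_hi, n, replace = TRUE),
                      maf = runif(n, maf_lo, maf_hi))
  }
  # noise: shared but common (fails MAF)
  if (config$n_common > 0L) {
    tab <- noise_block(config$n_common, "missense", 0L, 6L, 1.1e-3, 5e-2)
    vrows$common <- tab
    grows$common <- het_genotype(tab$vid, members, config$germline_depth)
  }
  # noise: rare missense, < 3 deleterious votes
  if (config$n_lowvote > 0L) {
    tab <- noise_block(config$n_lowvote, "missense", 0L, 2L, 0, 9.9e-4)
    vrows$lowvote <- tab
    grows$lowvote <- het_genotype(tab$vid, members, config$germline_depth)
  }
  # noise: rare but synonymous
  if (config$n_synonymous > 0L) {
    tab <- noise_block(config$n_synonymous, "synonymous", 0L, 0L, 0, 9.9e-4)
    vrows$syn <- tab
    grows$syn <- het_genotype(tab$vid, members, config$germline_depth)
  }
  # noise: round-1 pass but carried by a single member
  if (config$n_unshared > 0L && n_affected > 1L) {
    tab <- noise_block(config$n_unshared, "missense", 3L, 6L, 0, 9.9e-4)
    vrows$unshared <- tab
    carrier <- sample(members, nrow(tab), replace = TRUE)
    gl <- lapply(seq_len(nrow(tab)), function(i)
      rbind(het_genotype(tab$vid[i], carrier[i], config$germline_depth),
            hom_ref_genotype(tab$vid[i], setdiff(members, carrier[i]),
                             config$germline_depth)))
    grows$unshared <- do.call(rbind, gl)
  }

  # common het SNPs inside the causal gene: LOH support sites
  flank_vids <- character(0)
  if (config$n_flanking_het > 0L) {
    fpos <- cpos + seq_len(config$n_flanking_het) * 2000L
    fpos <- setdiff(fpos, used)
    used <- c(used, fpos)
    tab <- make_variant_rows(reference, gene_map, "chr1", fpos,
                             impact = "synonymous",
                             maf = runif(length(fpos), 0.1, 0.4))
    flank_vids <- tab$vid
    vrows$flank <- tab
    grows$flank <- het_genotype(tab$vid, members, config$germline_depth)
  }

  variants <- do.call(rbind, unname(vrows))
  rownames(variants) <- NULL
  genotypes <- do.call(rbind, unname(grows))
  rownames(genotypes) <- NULL
  list(
    members = members,
    variants = variants,
    genotypes = genotypes,
    truth = list(family_id = family_id, causal_gene = ca$gene,
                 causal_vid = causal$vid, causal_pos = cpos,
                 flanking_vids = flank_vids, n_survivors = n_surv + 1L),
    used_positions = used
  )
}
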