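# Somatic sample simulation: signature-mixture mutation placement with
# context awareness, beta-binomial allele-frequency noise, planted drivers,
# second-hit SNVs and LOH resampling at germline het sites.

# beta-binomial alt counts around a mean AAF (mildly overdispersed by default)
rbetabinom_alt <- function(n, depth, mu, concentration) {
  p <- rbeta(n, mu * concentration, (1 - mu) * concentration)
  alt <- rbinom(n, depth, p)
  pmin(pmax(alt, 1L), depth)
}

parse_sbs_label <- function(lab) {
  list(f5 = substr(lab, 1L, 1L), ref = substr(lab, 3L, 3L),
       alt = substr(lab, 5L, 5L), f3 = substr(lab, 7L, 7L))
}

# place SBS mutations for sampled category labels; returns data.frame
# (pos, ref, alt); updates env$blocked
place_sbs <- function(cats, ctx_index, reference, env, cal_lo, cal_hi) {
  out <- vector("list", 0L)
  tab <- table(cats)
  for (lab in names(tab)) {
    k <- as.integer(tab[[lab]])
    p <- parse_sbs_label(lab)
    key <- paste0("chr1:", p$f5, p$ref, p$f3)
    bucket <- ctx_index$sbs[[key]]
    if (is.null(bucket)) stopf("no reference position with context %s", key)
    cand <- bucket[bucket >= cal_lo & bucket <= cal_hi]
    cand <- cand[!env$blocked[cand]]
    if (length(cand) < k)
      stopf("reference exhausted for context %s (need %d, have %d)",
            key, k, length(cand))
    pos <- if (length(cand) == 1L) cand else sample(cand, k)
    env$blocked[pos] <- TRUE
    ref <- substring(as.character(Biostrings::Views(reference[["chr1"]],
                                                    pos, pos)), 1L, 1L)
    alt <- ifelse(ref %in% c("C", "T"), p$alt,
                  chartr("ACGT", "TGCA", p$alt))
    out[[length(out) + 1L]] <- data.frame(pos = pos, ref = ref, alt = alt,
                                          category = lab,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# place indels for a vector of sampled ID83 category labels; 1 bp bins are
# resolved in batch from the homopolymer-run index, other bins by bounded
# rejection sampling against the classifier itself
place_id <- function(cats, ctx_index, reference, env, cal_lo, cal_hi) {
  out <- list()
  tab <- table(cats)
  runs <- ctx_index$runs[["chr1"]]
  seq1 <- reference[["chr1"]]
  base_at <- function(p) as.character(Biostrings::Views(seq1, p, p))
  for (lab in names(tab)) {
    k <- as.integer(tab[[lab]])
    parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
    size <- parts[1]; kind <- parts[2]; sub <- parts[3]; ctx <- parts[4]
    if (size == "1" && sub %in% c("C", "T") &&
        !(kind == "Ins" && ctx == "0")) {
      is_del <- kind == "Del"
      bins <- if (is_del) {
        if (ctx == "6+") c("6", "7") else ctx
      } else {
        if (ctx == "5+") c("5", "6", "7") else ctx
      }
      starts <- unlist(runs[[sub]][bins], use.names = FALSE)
      if (is.null(starts) || length(starts) == 0L)
        stopf("no reference position with required context for %s", lab)
      starts <- starts[starts > cal_lo + 1L & starts < cal_hi - 8L]
      anchors <- starts - 1L
      ok <- !env$blocked[anchors] & !env$blocked[starts]
      cand <- anchors[ok]
      if (length(cand) < k)
        stopf("reference exhausted for category %s", lab)
      pos <- if (length(cand) == 1L) cand else sample(cand, k)
      env$blocked[pos] <- TRUE
      env$blocked[pos + 1L] <- TRUE
      a <- base_at(pos)
      res <- if (is_del) {
        data.frame(pos = pos, ref = paste0(a, sub), alt = a,
                   category = lab, stringsAsFactors = FALSE)
      } else {
        data.frame(pos = pos, ref = a, alt = paste0(a, sub),
                   category = lab, stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- res
    } else if (size == "1" && kind == "Ins" && ctx == "0" &&
               sub %in% c("C", "T")) {
      # insertion with no pre-existing copy: anchor where neither neighbour
      # is the inserted base
      got <- 0L; tries <- 0L; rows <- list()
      while (got < k && tries < 60L) {
        tries <- tries + 1L
        pos <- sample.int(cal_hi - cal_lo - 2L, 2L * (k - got)) + cal_lo
        pos <- unique(pos)
        a <- base_at(pos)
        nx <- base_at(pos + 1L)
        okp <- a != sub & nx != sub & !env$blocked[pos] &
          !env$blocked[pos + 1L]
        pos <- pos[okp][seq_len(min(sum(okp), k - got))]
        if (length(pos) > 0L) {
          env$blocked[pos] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            pos = pos, ref = a[okp][seq_along(pos)],
            alt = paste0(a[okp][seq_along(pos)], sub), category = lab,
            stringsAsFactors = FALSE)
          got <- got + length(pos)
        }
      }
      if (got < k) stopf("could not place category %s", lab)
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    } else {
      # generic bins: bounded per-event rejection against the classifier
      for (j in seq_len(k))
        out[[length(out) + 1L]] <- place_id_generic(lab, reference, env,
                                                    cal_lo, cal_hi)
    }
  }
  do.call(rbind, out)
}

place_id_generic <- function(lab, reference, env, cal_lo, cal_hi,
                             max_tries = 500L) {
  parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
  size <- parts[1]; kind <- parts[2]
  L <- if (size == "5+") 5L else as.integer(size)
  for (i in seq_len(max_tries)) {
    pos <- sample.int(cal_hi - cal_lo - 2L * L - 2L, 1L) + cal_lo
    if (kind == "Del") {
      ref <- ref_window(reference, "chr1", pos, pos + L)
      alt <- substr(ref, 1L, 1L)
    } else {
      ref <- ref_window(reference, "chr1", pos, pos)
      unit <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
      alt <- paste0(ref, unit)
    }
    got <- id_classify_one(reference, "chr1", pos, ref, alt)
    span <- pos:(pos + nchar(ref) - 1L)
    if (identical(got, lab) && !any(env$blocked[span])) {
      env$blocked[span] <- TRUE
      return(data.frame(pos = pos, ref = ref, alt = alt, category = lab,
                        stringsAsFactors = FALSE))
    }
  }
  stopf("no reference position with required context for category %s", lab)
}

#' Simulate one somatic sample
#'
#' Draws `round(TMB x footprint)` substitutions whose SBS96 categories follow
#' the sample's signature mixture (each placed at a reference position with
#' the matching trinucleotide context) and indels likewise from the ID
#' mixture; read depths are Poisson around the configured mean and baseline
#' allele frequencies beta-binomial around 0.45. Planted events per the
#' family's plan: driver mutations at configured AAF, a second-hit SNV in the
#' family's causal gene at high AAF, or LOH implemented by resampling alt
#' counts at the germline causal variant and its flanking het sites from
#' `Binomial(depth, retained_fraction)` favouring the variant allele.
#' Background placement avoids candidate and driver gene intervals, so
#' planted two-hit events are identifiable by construction.
#'
#' @param family_id Family whose sample to simulate.
#' @param config A `sim_config`.
#' @param reference,gene_map,ctx_index Reference assets
#'   (`ctx_index` from `build_context_index`).
#' @param sbs_catalog,id_catalog Signature catalogs.
#' @param germline The family's [simulate_family_germline()] output.
#' @param mask `GRanges` of intervals excluded from background placement.
#' @param seed Integer seed.
#' @return List with `sample` (somatic sample object: `sample_id`,
#'   `family_id`, `paired`, `mutations`, `depths`, `callable`, `loh_sites`)
#'   and `truth`.
#' @export
simulate_somatic <- function(family_id, config, reference, gene_map,
                             ctx_index, sbs_catalog, id_catalog, germline,
                             mask = NULL, seed = 1L) {
  set.seed(seed)
  sc <- config$somatic[config$somatic$family_id == family_id, ]
  if (nrow(sc) != 1L) stopf("no somatic spec for family %s", family_id)
  sample_id <- paste0(family_id, ".T")
  seqlen <- length(reference[["chr1"]])
  m <- config$callable_margin
  cal_lo <- m + 1L
  cal_hi <- if (sc$qc_fail) {
    m + as.integer((seqlen - 2L * m) * config$qc_truncate_fraction)
  } else seqlen - m
  callable <- GenomicRanges::GRanges("chr1", IRanges::IRanges(cal_lo, cal_hi))
  fp <- footprint_mb(callable)

  env <- new.env(parent = emptyenv())
  env$blocked <- logical(seqlen)
  if (!is.null(mask)) {
    for (i in seq_along(mask)) {
      env$blocked[BiocGenerics::start(mask)[i]:BiocGenerics::end(mask)[i]] <- TRUE
    }
  }

  n_snv <- as.integer(round(sc$tmb * fp))
  n_indel <- as.integer(round(sc$indel_burden * fp))
  w_sbs <- config$sbs_weights[[family_id]]
  w_id <- config$id_weights[[family_id]]

  mix <- function(catalog, w) {
    wfull <- setNames(numeric(ncol(catalog$signatures)),
                      colnames(catalog$signatures))
    wfull[names(w)] <- w
    drop(catalog$signatures %*% wfull)
  }
  rows <- list()
  if (n_snv > 0L) {
    cats <- sample(sbs_catalog$categories, n_snv, replace = TRUE,
                   prob = mix(sbs_catalog, w_sbs))
    rows$sbs <- place_sbs(cats, ctx_index, reference, env, cal_lo, cal_hi)
  }
  if (n_indel > 0L) {
    icats <- sample(id_catalog$categories, n_indel, replace = TRUE,
                    prob = mix(id_catalog, w_id))
    rows$id <- place_id(icats, ctx_index, reference, env, cal_lo, cal_hi)
  }
  bg <- do.call(rbind, rows)
  tools <- predictor_tools()
  mk_mut <- function(pos, ref, alt, gene, impact, hgvsp = "") {
    df <- data.frame(
      vid = variant_id("chr1", pos, ref, alt), chrom = "chr1",
      pos = as.integer(pos), ref = ref, alt = alt,
      var_class = variant_class(ref, alt), gene = gene, impact = impact,
      protein_change = hgvsp, maf = 0, stringsAsFactors = FALSE)
    df$paf.gnomAD <- NA_real_
    for (tl in tools) df[[paste0("pred.", tl)]] <- "U"
    df
  }
  muts <- list(); depths <- list()
  if (!is.null(bg) && nrow(bg) > 0L) {
    is_snv <- nchar(bg$ref) == 1L & nchar(bg$alt) == 1L
    impact <- character(nrow(bg))
    impact[is_snv] <- sample(c("missense", "synonymous", "other"),
                             sum(is_snv), replace = TRUE,
                             prob = c(0.4, 0.3, 0.3))
    impact[!is_snv] <- "other"
    tab <- mk_mut(bg$pos, bg$ref, bg$alt,
                  gene_at(gene_map, "chr1", bg$pos), impact)
    depth <- pmax(10L, rpois(nrow(tab), config$somatic_depth))
    alt_n <- rbetabinom_alt(nrow(tab), depth, config$baseline_aaf,
                            config$aaf_overdispersion)
    muts$bg <- tab
    depths$bg <- data.frame(vid = tab$vid, ref_count = depth - alt_n,
                            alt_count = alt_n, depth = depth,
                            stringsAsFactors = FALSE)
  }

  # planted driver mutations
  drv <- config$drivers[config$drivers$family_id == family_id, ,
                        drop = FALSE]
  drv_truth <- NULL
  if (nrow(drv) > 0L) {
    dtab <- list(); ddep <- list()
    for (i in seq_len(nrow(drv))) {
      g <- gene_map[gene_map$gene == drv$gene[i], ]
      pos <- g$start + 120L * i
      ref <- ref_window(reference, "chr1", pos, pos)
      tab <- mk_mut(pos, ref, alt_base(ref), drv$gene[i],
                    impact = if (grepl("fs$", drv$protein_change[i]))
                      "truncating" else "missense",
                    hgvsp = drv$protein_change[i])
      depth <- pmax(20L, rpois(1L, config$somatic_depth))
      alt_n <- max(1L, as.integer(round(depth * drv$aaf[i])))
      dtab[[i]] <- tab
      ddep[[i]] <- data.frame(vid = tab$vid, ref_count = depth - alt_n,
                              alt_count = alt_n, depth = depth,
                              stringsAsFactors = FALSE)
    }
    muts$drv <- do.call(rbind, dtab)
    depths$drv <- do.call(rbind, ddep)
    drv_truth <- cbind(drv, vid = muts$drv$vid,
                       stringsAsFactors = FALSE)
  }

  # planted second-hit SNV in the family's causal gene
  sh_truth <- NULL
  if (identical(sc$second_hit, "snv")) {
    cgene <- germline$truth$causal_gene
    g <- gene_map[gene_map$gene == cgene, ]
    pos <- g$start + 900L
    ref <- ref_window(reference, "chr1", pos, pos)
    tab <- mk_mut(pos, ref, alt_base(ref), cgene, impact = "truncating",
                  hgvsp = "Q300*")
    depth <- pmax(20L, rpois(1L, config$somatic_depth))
    alt_n <- as.integer(round(depth * config$second_hit_aaf))
    muts$sh <- tab
    depths$sh <- data.frame(vid = tab$vid, ref_count = depth - alt_n,
                            alt_count = alt_n, depth = depth,
                            stringsAsFactors = FALSE)
    sh_truth <- list(type = "snv", gene = cgene, vid = tab$vid,
                     aaf = alt_n / depth)
  }

  # germline-leakage variants for the unpaired sample (panel-of-normals fodder)
  leakage_vids <- character(0)
  if (isTRUE(sc$unpaired) && config$n_leakage > 0L) {
    filler <- gene_map$gene[grepl("^GENE", gene_map$gene)]
    pos <- sample_gene_positions(gene_map, filler, config$n_leakage,
                                 which(env$blocked))
    env$blocked[pos] <- TRUE
    ref <- substring(as.character(Biostrings::Views(reference[["chr1"]],
                                                    pos, pos)), 1L, 1L)
    tab <- mk_mut(pos, ref, alt_base(ref), gene_at(gene_map, "chr1", pos),
                  impact = "other")
    depth <- pmax(10L, rpois(length(pos), config$somatic_depth))
    alt_n <- rbinom(length(pos), depth, 0.5)
    alt_n <- pmin(pmax(alt_n, 1L), depth)
    muts$leak <- tab
    depths$leak <- data.frame(vid = tab$vid, ref_count = depth - alt_n,
                              alt_count = alt_n, depth = depth,
                              stringsAsFactors = FALSE)
    leakage_vids <- tab$vid
  }

  # allelic state at germline het sites in the causal gene (LOH or balanced)
  loh_planted <- identical(sc$second_hit, "loh")
  site_vids <- c(germline$truth$causal_vid, germline$truth$flanking_vids)
  loh_sites <- NULL
  if (!isTRUE(sc$unpaired) && length(site_vids) > 0L) {
    parts <- strsplit(site_vids, ":", fixed = TRUE)
    loh_sites <- data.frame(
      gene = germline$truth$causal_gene, vid = site_vids,
      chrom = vapply(parts, `[[`, character(1), 1L),
      pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
      is_candidate = site_vids == germline$truth$causal_vid,
      stringsAsFactors = FALSE)
    depth <- pmax(20L, rpois(nrow(loh_sites), config$somatic_depth))
    pr <- if (loh_planted) config$retained_fraction else 0.5
    loh_sites$depth <- depth
    loh_sites$alt_count <- rbinom(nrow(loh_sites), depth, pr)
  }

  mutations <- do.call(rbind, muts)
  depth_tab <- do.call(rbind, depths)
  if (is.null(mutations)) {
    mutations <- empty_variant_table()
    depth_tab <- data.frame(vid = character(0), ref_count = integer(0),
                            alt_count = integer(0), depth = integer(0),
                            stringsAsFactors = FALSE)
  }
  rownames(mutations) <- NULL
  rownames(depth_tab) <- NULL

  sample_obj <- list(
    sample_id = sample_id, family_id = family_id,
    paired = !isTRUE(sc$unpaired), qc_fail = isTRUE(sc$qc_fail),
    mutations = mutations, depths = depth_tab, callable = callable,
    loh_sites = loh_sites
  )
  truth <- list(
    family_id = family_id, sample_id = sample_id,
    sbs_weights = w_sbs, id_weights = w_id,
    tmb = sc$tmb, indel_burden = sc$indel_burden,
    n_snv = n_snv, n_indel = n_indel,
    sbs_categories = if (!is.null(rows$sbs)) rows$sbs$category else
      character(0),
    id_categories = if (!is.null(rows$id)) rows$id$category else
      character(0),
    second_hit = sh_truth %||%
      (if (loh_planted) list(type = "loh",
                             gene = germline$truth$causal_gene,
                             sites = site_vids) else
         list(type = "none")),
    drivers = drv_truth, leakage_vids = leakage_vids,
    qc_fail = isTRUE(sc$qc_fail), unpaired = isTRUE(sc$unpaired),
    footprint_mb = fp
  )
  list(sample = sample_obj, truth = truth)
}
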