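#' Default synthetic-cohort configuration
#'
#' The default configuration *is* the study's stated world: 16 families with
#' affected counts 2 (x13), 3, 4 and 6 (39 affected in all), one somatic
#' sample per family except one family with no sample and one failing
#' paired-coverage QC, one unpaired somatic sample cleaned against a pooled
#' normal panel, an expected 24.5 round-1 shared survivors per family,
#' clock-like-dominant signature mixtures with MMR-deficiency admixture in
#' the hypermutated samples, per-sample SNV/indel burdens anchored to the
#' cohort's reported values (27.6 and 89 mut/Mb hypermutated, 100.6 indels/Mb
#' ultra-hypermutated), planted second hits (one somatic SNV family, one LOH
#' family), and driver hotspots at stated allele frequencies. Values the
#' study does not state (depths, noise shapes, purity) are fixed once at
#' field-realistic levels and documented in the methods vignette.
#'
#' @param seed Integer master seed; every random draw in the simulator
#'   derives from it.
#' @return A `sim_config` list; fields are documented inline and may be
#'   overridden before passing to [simulate_cohort()].
#' @export
default_sim_config <- function(seed = 1L) {
  families <- sprintf("SPS.%d", 1:16)
  affected <- setNames(rep(2L, 16), families)
  affected[c("SPS.9", "SPS.10", "SPS.11")] <- c(3L, 4L, 6L)

  causal <- data.frame(
    family_id = families,
    gene = c("WRN", "KLF3", "CFTR", "MCM3AP", "MCM8", "INO80", "POLD1",
             "PDLIM2", "TP53BP1", "WNK2", "DOT1L", "ANXA10", "ASXL1",
             "HIC1", "CANDX1", "CANDX2"),
    impact = c("missense", "missense", "missense", "missense", "truncating",
               "missense", "truncating", "missense", "missense", "missense",
               "missense", "missense", "missense", "missense", "missense",
               "missense"),
    votes = c(4L, 4L, 6L, 4L, 0L, 5L, 0L, 3L, 6L, 5L, 5L, 6L, 6L, 3L, 5L,
              4L),
    maf = c(7.95e-6, 2.03e-4, NA, 5.02e-4, NA, 2.2e-4, NA, NA, 8e-6,
            7.88e-5, 3.49e-5, 3.6e-5, 6.68e-4, NA, 1e-5, 2e-5),
    hgvsp = c("E675Q", "S92L", "P1332H", "E531G", "", "R1424P", "K648fs",
              "P130L", "E1279K", "A1607V", "V1103M", "D231G", "G704R",
              "Q432R", "A100T", "G200R"),
    stringsAsFactors = FALSE
  )

  somatic <- data.frame(
    family_id = setdiff(families, "SPS.10"),
    stringsAsFactors = FALSE
  )
  somatic$tmb <- c(3, 27.6, 15, 4, 5, 3, 110, 13, 2, 14, 3, 2.5, 11, 4,
                   89)[match(somatic$family_id,
                             setdiff(families, "SPS.10"))]
  somatic$indel_burden <- 1
  somatic$indel_burden[somatic$family_id == "SPS.7"] <- 100.6
  somatic$indel_burden[somatic$family_id == "SPS.2"] <- 8.4
  somatic$indel_burden[somatic$family_id == "SPS.16"] <- 5
  somatic$second_hit <- "none"
  somatic$second_hit[somatic$family_id == "SPS.7"] <- "snv"
  somatic$second_hit[somatic$family_id == "SPS.14"] <- "loh"
  somatic$qc_fail <- somatic$family_id == "SPS.5"
  somatic$unpaired <- somatic$family_id == "SPS.16"

  base_sbs <- c(SBS1 = 0.55, SBS5 = 0.45)
  sbs_weights <- setNames(rep(list(base_sbs), nrow(somatic)),
                          somatic$family_id)
  sbs_weights[["SPS.2"]] <- c(SBS1 = 0.25, SBS5 = 0.35, SBS15 = 0.25,
                              SBS21 = 0.15)
  sbs_weights[["SPS.7"]] <- c(SBS1 = 0.15, SBS5 = 0.20, SBS15 = 0.30,
                              SBS21 = 0.25, SBS54 = 0.10)
  sbs_weights[["SPS.13"]] <- c(SBS1 = 0.50, SBS5 = 0.42, SBS15 = 0.08)
  sbs_weights[["SPS.14"]] <- c(SBS1 = 0.50, SBS5 = 0.42, SBS15 = 0.08)
  sbs_weights[["SPS.16"]] <- c(SBS1 = 0.35, SBS5 = 0.35, SBS15 = 0.30)

  base_id <- c(ID1 = 0.6, ID2 = 0.4)
  id_weights <- setNames(rep(list(base_id), nrow(somatic)),
                         somatic$family_id)
  for (f in c("SPS.2", "SPS.7", "SPS.16"))
    id_weights[[f]] <- c(ID1 = 0.5, ID2 = 0.45, ID12 = 0.05)

  drivers <- rbind(
    data.frame(family_id = c("SPS.2", "SPS.6", "SPS.7", "SPS.15"),
               gene = "BRAF", protein_change = "V600E", aaf = 0.35,
               stringsAsFactors = FALSE),
    data.frame(family_id = c("SPS.1", "SPS.3", "SPS.9"), gene = "BRAF",
               protein_change = "V600E", aaf = 0.12,
               stringsAsFactors = FALSE),
    data.frame(family_id = "SPS.14", gene = "KRAS",
               protein_change = "A146T", aaf = 0.25,
               stringsAsFactors = FALSE),
    data.frame(family_id = "SPS.7", gene = "MLH1",
               protein_change = "R687Q", aaf = 0.30,
               stringsAsFactors = FALSE),
    data.frame(family_id = c("SPS.7", "SPS.2", "SPS.2", "SPS.4", "SPS.8",
                             "SPS.11", "SPS.14"),
               gene = c("MSH2", "MSH3", "MSH6", "MSH2", "MLH3", "MSH6",
                        "MSH2"),
               protein_change = c("R359S", "K383fs", "T1219I", "G162R",
                                  "E1451K", "S144I", "P349L"),
               aaf = c(0.15, 0.08, 0.09, 0.10, 0.12, 0.10, 0.11),
               stringsAsFactors = FALSE),
    data.frame(family_id = c("SPS.3", "SPS.7", "SPS.8"), gene = "POLE",
               protein_change = c("S297F", "V411L", "P286R"),
               aaf = c(0.12, 0.15, 0.10), stringsAsFactors = FALSE)
  )

  structure(list(
    seed = as.integer(seed),
    reference_length_mb = 5,
    families = families,
    affected_counts = affected,
    causal = causal,
    # germline background (per family unless noted)
    round1_survivor_mean = 24.5,  # expected shared round-1 survivors incl. causal
    n_common = 30L,       # shared but too frequent (MAF >= 0.1%)
    n_lowvote = 25L,      # rare missense with < 3 deleterious votes
    n_synonymous = 25L,   # rare but synonymous
    n_unshared = 20L,     # would pass round 1 but carried by one member only
    excluded_gene_fraction = 0.10,  # survivors landing in excluded gene sets
    cross_family_decoy = TRUE,      # same variant segregating in SPS.1, not in SPS.2
    n_flanking_het = 3L,  # common het SNPs per causal gene (LOH support sites)
    germline_depth = 80,
    # somatic model
    somatic = somatic,
    sbs_weights = sbs_weights,
    id_weights = id_weights,
    drivers = drivers,
    somatic_depth = 100,
    baseline_aaf = 0.45,
    aaf_overdispersion = 50,   # beta-binomial concentration (mildly overdispersed)
    second_hit_aaf = 0.35,
    retained_fraction = 0.80,  # LOH retained-allele fraction (purity proxy)
    qc_truncate_fraction = 0.50,
    n_leakage = 20L,           # germline-leakage variants in the unpaired sample
    panel_size = 110L,
    callable_margin = 1000L
  ), class = "sim_config")
}
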