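# cohort_sim: reference, gene map, germline and somatic generators

test_that("synthetic reference is deterministic and context-complete", {
  r1 <- make_reference(1, seed = 7)
  r2 <- make_reference(1, seed = 7)
  expect_identical(as.character(r1[[1]]), as.character(r2[[1]]))
  r3 <- make_reference(1, seed = 8)
  expect_false(identical(as.character(r1[[1]]), as.character(r3[[1]])))
  idx <- build_context_index(r1)
  # all 32 pyrimidine-centred trinucleotide buckets populated
  expect_equal(length(idx$sbs), 32L)
  expect_true(all(vapply(idx$sbs, length, integer(1)) > 0L))
})

test_that("fasta written to disk is byte-identical across runs", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  make_reference(1, seed = 5, path = f1)
  make_reference(1, seed = 5, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".fai")))
})

test_that("family germline simulation plants a shared causal variant", {
  cohort <- germline_cohort()
  for (f in c("SPS.1", "SPS.11")) {
    fam <- cohort$families[[f]]
    cvid <- fam$truth$causal_vid
    g <- fam$genotypes[fam$genotypes$vid == cvid, ]
    expect_setequal(g$sample_id, fam$members)
    expect_true(all(g$gt == "het"))
  }
  # six affected members in SPS.11
  expect_equal(length(cohort$families[["SPS.11"]]$members), 6L)
})

test_that("truncating causal variants pass round 1 on impact alone", {
  cohort <- germline_cohort()
  fam <- cohort$families[["SPS.7"]]  # frameshift causal, all verdicts U
  cv <- fam$variants[fam$variants$vid == fam$truth$causal_vid, ]
  expect_equal(cv$impact, "truncating")
  expect_equal(predictor_score(cv), 0L)
  r1 <- filter_round1(fam$variants)
  expect_true(cv$vid %in% r1$vid)
})

test_that("germline simulation is deterministic under a fixed seed", {
  cfg <- default_sim_config(3L)
  ref <- make_reference(cfg$reference_length_mb, cfg$seed)
  gm <- make_gene_map(ref, unique(c(cfg$causal$gene, driver_genes())))
  f1 <- simulate_family_germline("SPS.4", 2L, cfg, ref, gm, seed = 99L)
  f2 <- simulate_family_germline("SPS.4", 2L, cfg, ref, gm, seed = 99L)
  expect_identical(f1$variants, f2$variants)
  expect_identical(f1$genotypes, f2$genotypes)
})

test_that("default cohort has the study shape", {
  cohort <- full_cohort()
  expect_equal(length(cohort$families), 16L)
  expect_equal(nrow(cohort$pedigree), 39L)
  counts <- table(cohort$pedigree$family_id)
  expect_equal(sort(as.integer(counts)), c(rep(2L, 13), 3L, 4L, 6L))
  # somatic: one sample per family except SPS.10; SPS.5 built to fail QC
  expect_equal(length(cohort$somatic), 15L)
  expect_false("SPS.10" %in% names(cohort$somatic))
  expect_true(cohort$somatic[["SPS.5"]]$sample$qc_fail)
  expect_false(cohort$somatic[["SPS.16"]]$sample$paired)
})

test_that("planted events are recoverable from the truth table", {
  cohort <- full_cohort()
  # every causal variant is present in its family's emitted variants
  for (f in names(cohort$families)) {
    fam <- cohort$families[[f]]
    expect_true(fam$truth$causal_vid %in% fam$variants$vid)
  }
  # planted second hits exist in the somatic mutation lists
  for (sh in cohort$truth$second_hits) {
    if (sh$type == "snv") {
      s <- cohort$somatic[[sh$family_id]]$sample
      expect_true(sh$vid %in% s$mutations$vid)
    }
    if (sh$type == "loh") {
      s <- cohort$somatic[[sh$family_id]]$sample
      expect_true(all(sh$sites %in% s$loh_sites$vid))
    }
  }
  # background SNVs re-classify to exactly the emitted truth categories
  s <- cohort$somatic[["SPS.2"]]$sample
  tr <- cohort$somatic[["SPS.2"]]$truth
  planted_vids <- tr$drivers$vid
  snvs <- s$mutations[s$mutations$var_class == "SNV" &
                        !(s$mutations$vid %in% planted_vids), ]
  labs <- sbs96_classify(cohort$reference, snvs$chrom, snvs$pos, snvs$ref,
                         snvs$alt)
  expect_equal(table(factor(labs, levels = sbs96_categories())),
               table(factor(tr$sbs_categories,
                            levels = sbs96_categories())))
})

test_that("sampled SBS categories follow the signature mixture", {
  # chi-square goodness of fit of emitted category counts against the
  # mixture distribution, on a dedicated high-burden sample
  cfg <- default_sim_config(7L)
  cfg$families <- "SPS.1"
  cfg$affected_counts <- cfg$affected_counts["SPS.1"]
  cfg$somatic <- cfg$somatic[cfg$somatic$family_id == "SPS.1", ]
  cfg$somatic$tmb <- 400  # ~2,000 mutations over the ~5 Mb footprint
  cfg$somatic$indel_burden <- 0
  cfg$sbs_weights <- list(SPS.1 = c(SBS1 = 0.6, SBS5 = 0.4))
  cfg$cross_family_decoy <- FALSE
  co <- simulate_cohort(cfg)
  tr <- co$somatic[["SPS.1"]]$truth
  obs <- table(factor(tr$sbs_categories, levels = sbs96_categories()))
  mixp <- drop(co$catalogs$SBS96$signatures[, c("SBS1", "SBS5")] %*%
                 c(0.6, 0.4))
  # lump rare categories so chi-square asymptotics hold
  keep <- mixp * sum(obs) >= 5
  o <- as.numeric(obs[keep])
  p <- mixp[keep]
  if (any(!keep)) {
    o <- c(o, sum(obs[!keep]))
    p <- c(p, sum(mixp[!keep]))
  }
  pval <- suppressWarnings(stats::chisq.test(o, p = p / sum(p))$p.value)
  expect_gt(pval, 1e-3)
  expect_equal(tr$n_snv, length(tr$sbs_categories))
})

test_that("LOH plan resamples alt counts towards the retained fraction", {
  cohort <- full_cohort()
  s <- cohort$somatic[["SPS.14"]]$sample  # planted LOH family
  aaf <- s$loh_sites$alt_count / s$loh_sites$depth
  expect_true(all(aaf > 0.6))  # Binomial(depth~100, 0.8) draws
  s0 <- cohort$somatic[["SPS.1"]]$sample  # balanced family
  aaf0 <- s0$loh_sites$alt_count / s0$loh_sites$depth
  expect_true(all(abs(aaf0 - 0.5) < 0.25))
})

test_that("zero target burden yields zero mutation records", {
  cfg <- default_sim_config(2L)
  cfg$families <- "SPS.1"
  cfg$affected_counts <- cfg$affected_counts["SPS.1"]
  cfg$somatic <- cfg$somatic[cfg$somatic$family_id == "SPS.1", ]
  cfg$somatic$tmb <- 0
  cfg$somatic$indel_burden <- 0
  cfg$drivers <- cfg$drivers[0, ]
  cfg$cross_family_decoy <- FALSE
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$somatic[["SPS.1"]]$sample$mutations), 0L)
})

test_that("cohort simulation is fully deterministic under its seed", {
  cfg <- default_sim_config(11L)
  cfg$families <- cfg$families[1:3]
  cfg$affected_counts <- cfg$affected_counts[cfg$families]
  cfg$somatic <- cfg$somatic[cfg$somatic$family_id %in% cfg$families, ]
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$families[["SPS.2"]]$variants,
                   c2$families[["SPS.2"]]$variants)
  expect_identical(c1$somatic[["SPS.3"]]$sample$mutations,
                   c2$somatic[["SPS.3"]]$sample$mutations)
  expect_identical(c1$somatic[["SPS.3"]]$sample$depths,
                   c2$somatic[["SPS.3"]]$sample$depths)
})
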