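# germline_prioritizer: predictor scores, round-1 filters, segregation,
# cross-family exclusion, gene-function rounds, oracle equivalence

test_that("predictor_score counts deleterious verdicts only", {
  v6 <- test_variant(votes = 6L)
  v3 <- test_variant(pos = 101L, votes = 3L)
  v0 <- test_variant(pos = 102L, impact = "truncating")  # all unavailable
  tab <- rbind(v6, v3, v0)
  expect_equal(predictor_score(tab), c(6L, 3L, 0L))
  bad <- tab
  bad$pred.NovelTool <- "D"
  expect_error(predictor_score(bad), "outside the configured six")
})

test_that("round-1 filter applies strict MAF, impact and vote thresholds", {
  cfg <- default_filter_config()
  cases <- rbind(
    test_variant(pos = 1L, votes = 4L, maf = 5e-4),      # keep
    test_variant(pos = 2L, votes = 4L, maf = 2e-3),      # MAF too high
    test_variant(pos = 3L, impact = "synonymous"),        # impact
    test_variant(pos = 4L, impact = "truncating"),        # keep, score 0
    test_variant(pos = 5L, votes = 2L, maf = 1e-4),      # votes
    test_variant(pos = 6L, votes = 3L, maf = 1e-4),      # boundary votes >=
    test_variant(pos = 7L, votes = 4L, maf = 1e-3),      # boundary maf <
    test_variant(pos = 8L, impact = "other", votes = 6L) # impact
  )
  out <- filter_round1(cases, cfg)
  expect_equal(out$pos, c(1L, 4L, 6L))
  expect_equal(out$predictor_score, c(4L, 0L, 3L))
})

make_family <- function(n = 2L, fam = "F1") {
  data.frame(family_id = fam, sample_id = sprintf("%s.S%d", fam, 1:n),
             father = "0", mother = "0", sex = 1L, affected = TRUE,
             sequenced_germline = TRUE, has_somatic = FALSE,
             stringsAsFactors = FALSE)
}

test_that("segregation keeps variants carried by every affected member", {
  ped <- make_family(2L)
  v <- rbind(test_variant(pos = 1L, votes = 4L),
             test_variant(pos = 2L, votes = 4L),
             test_variant(pos = 3L, votes = 4L))
  g <- rbind(
    test_genotype(v$vid[1], "F1.S1", "het"),
    test_genotype(v$vid[1], "F1.S2", "het"),
    test_genotype(v$vid[2], "F1.S1", "het"),
    test_genotype(v$vid[2], "F1.S2", "hom_ref"),
    test_genotype(v$vid[3], "F1.S1", "hom_alt"),
    test_genotype(v$vid[3], "F1.S2", "het"))
  out <- segregation_filter(v, g, ped)
  expect_setequal(out$vid, v$vid[c(1, 3)])  # hom_alt still a carrier
  expect_true(all(out$inheritance_model == "dominant"))
})

test_that("missing genotypes fail the shared rule unless ignored", {
  ped <- make_family(2L)
  v <- test_variant(pos = 9L, votes = 5L)
  g <- test_genotype(v$vid, "F1.S1", "het")  # S2 absent entirely
  expect_equal(nrow(segregation_filter(v, g, ped)), 0L)
  cfg <- default_filter_config()
  cfg$missing_genotype <- "ignore"
  expect_equal(nrow(segregation_filter(v, g, ped, cfg)), 1L)
})

test_that("recessive model needs hom-alt or an unphased compound het", {
  ped <- make_family(2L)
  cfg <- default_filter_config()
  cfg$inheritance <- "recessive"
  hom <- test_variant(pos = 1L, votes = 4L)
  g_hom <- rbind(test_genotype(hom$vid, "F1.S1", "hom_alt"),
                 test_genotype(hom$vid, "F1.S2", "hom_alt"))
  out <- segregation_filter(hom, g_hom, ped, cfg)
  expect_equal(out$inheritance_model, "recessive")

  # two het-shared variants in one gene: compound-het surrogate
  comp <- rbind(test_variant(pos = 2L, votes = 4L, gene = "GX"),
                test_variant(pos = 3L, votes = 4L, gene = "GX"),
                test_variant(pos = 4L, votes = 4L, gene = "GY"))
  g_comp <- do.call(rbind, lapply(comp$vid, function(vid)
    rbind(test_genotype(vid, "F1.S1", "het"),
          test_genotype(vid, "F1.S2", "het"))))
  out <- segregation_filter(comp, g_comp, ped, cfg)
  expect_setequal(out$gene, "GX")  # singleton het gene GY fails recessive
})

test_that("cross-family exclusion removes inconsistent segregators", {
  ped <- rbind(make_family(2L, "F1"), make_family(2L, "F2"))
  v <- test_variant(pos = 50L, votes = 5L)
  # segregates in F1; carried by only one of two affecteds in F2
  g <- rbind(test_genotype(v$vid, "F1.S1", "het"),
             test_genotype(v$vid, "F1.S2", "het"),
             test_genotype(v$vid, "F2.S1", "het"),
             test_genotype(v$vid, "F2.S2", "hom_ref"))
  res <- cross_family_exclusion(list(F1 = v), g, ped)
  expect_equal(nrow(res$F1), 0L)

  # consistently segregating in both families -> kept in both
  g2 <- g
  g2$gt[g2$sample_id == "F2.S2"] <- "het"
  res2 <- cross_family_exclusion(list(F1 = v, F2 = v), g2, ped)
  expect_equal(nrow(res2$F1), 1L)
  expect_equal(nrow(res2$F2), 1L)

  # external exclusion list always wins
  res3 <- cross_family_exclusion(list(F1 = v), g2, ped,
                                 external_exclusion = v$vid)
  expect_equal(nrow(res3$F1), 0L)
})

test_that("gene-function rounds exclude then prioritize with labels", {
  gs <- list(
    prioritized = list(cancer = "CGENE", senescence = "SGENE",
                       epigenetics = c("EGENE", "SEGENE")),
    excluded = list(non_cancer_disease = "NCD", vague_function = "VG"))
  gs$prioritized$senescence <- c("SGENE", "SEGENE")
  v <- rbind(test_variant(pos = 1L, gene = "CGENE", votes = 4L),
             test_variant(pos = 2L, gene = "SGENE", votes = 4L),
             test_variant(pos = 3L, gene = "SEGENE", votes = 4L),
             test_variant(pos = 4L, gene = "NCD", votes = 4L),
             test_variant(pos = 5L, gene = "NOSET", votes = 4L))
  r2 <- gene_function_prioritize(v, gs, round = 2L)
  expect_false("NCD" %in% r2$gene)
  expect_true("NOSET" %in% r2$gene)
  r3 <- gene_function_prioritize(r2, gs, round = 3L)
  expect_setequal(r3$gene, c("CGENE", "SGENE", "SEGENE"))
  crit <- setNames(r3$selection_criterion, r3$gene)
  expect_equal(crit[["CGENE"]], "Involvement in cancer development")
  expect_equal(crit[["SGENE"]], "Senescence candidate")
  expect_equal(crit[["SEGENE"]],
               "Senescence and epigenetics regulator candidate")

  bad <- gs
  bad$excluded$non_cancer_disease <- c("NCD", "CGENE")
  expect_error(gene_function_prioritize(v, bad, 2L), "both prioritized")
})

test_that("rounds are monotone and recall the planted causal variants", {
  cohort <- germline_cohort()
  pri <- prioritized_germline()
  for (f in names(pri$round3)) {
    s1 <- pri$round1[[f]]$vid
    s2 <- pri$round2[[f]]$vid
    s3 <- pri$round3[[f]]$vid
    expect_true(all(s3 %in% s2))
    expect_true(all(s2 %in% s1))
  }
  truth <- cohort$truth$causal
  r3 <- do.call(rbind, pri$round3)
  expect_true(all(truth$vid %in% r3$vid))
})

test_that("three-round output matches the brute-force oracle exactly", {
  cohort <- germline_cohort()
  pri <- prioritized_germline()
  oracle <- oracle_prioritize(cohort)
  for (f in names(pri$round3)) {
    # oracle 'segregating' corresponds to post-cross-family retention
    expect_setequal(pri$round2[[f]]$vid, oracle$round2[[f]])
    expect_setequal(pri$round3[[f]]$vid, oracle$round3[[f]])
  }
})
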