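# mutational_profile: burden, SBS96/ID83 classification, refitting, drivers

test_that("burden classes use strict thresholds on combined burden", {
  expect_equal(compute_burden(1380L, 0L, 50)$tmb, 27.6)
  expect_equal(compute_burden(1380L, 0L, 50)$load_class, "hypermutated")
  expect_equal(compute_burden(4450L, 0L, 50)$load_class, "hypermutated")
  b <- compute_burden(0L, 5030L, 50)
  expect_equal(b$indel_burden, 100.6)
  expect_equal(b$load_class, "ultra_hypermutated")
  expect_equal(compute_burden(500L, 0L, 50)$load_class,
               "non_hypermutated")  # exactly 10 mut/Mb
  expect_error(compute_burden(10L, 0L, 0), "positive")
})

test_that("every burden gets exactly one class (partition property)", {
  set.seed(1)
  classes <- vapply(seq_len(200), function(i) {
    compute_burden(sample.int(6000L, 1L), sample.int(600L, 1L),
                   runif(1, 1, 60))$load_class
  }, character(1))
  expect_true(all(classes %in% c("non_hypermutated", "hypermutated",
                                 "ultra_hypermutated")))
})

test_that("SBS96 classification follows the pyrimidine convention", {
  #         123456789
  ref <- literal_reference("TTACATGCC")
  # pos 4: context A-C-A, C>T  -> A[C>T]A
  expect_equal(sbs96_classify(ref, "chr1", 4L, "C", "T"), "A[C>T]A")
  # pos 6: context A-T-G, T>G  -> A[T>G]G (already pyrimidine-centred)
  expect_equal(sbs96_classify(ref, "chr1", 6L, "T", "G"), "A[T>G]G")
  # pos 5: context C-A-T, A>G -> revcomp A-T-G with T>C -> A[T>C]G
  expect_equal(sbs96_classify(ref, "chr1", 5L, "A", "G"), "A[T>C]G")
  # purine centre G>A in T-G-T -> A[C>T]A after normalisation
  ref2 <- literal_reference("TTGTT")
  expect_equal(sbs96_classify(ref2, "chr1", 3L, "G", "A"), "A[C>T]A")
  # REF mismatch against the FASTA is an error
  expect_error(sbs96_classify(ref, "chr1", 4L, "G", "A"),
               "reference mismatch")
  # N in context, or sequence edge -> unclassifiable
  refn <- literal_reference("ANCGA")
  expect_true(is.na(sbs96_classify(refn, "chr1", 3L, "C", "T")))
  expect_true(is.na(sbs96_classify(ref, "chr1", 1L, "T", "C")))
})

test_that("strand involution: revcomp representation gives the same label", {
  ref <- cached("ref_small", function() make_reference(1, seed = 13))
  n <- length(ref[[1]])
  rc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(ref[[1]]))
  names(rc) <- "chr1"
  set.seed(99)
  pos <- sample(2:(n - 1L), 300L)
  base <- substring(as.character(Biostrings::Views(ref[[1]], pos, pos)),
                    1, 1)
  alt <- alt_base(base)
  lab <- sbs96_classify(ref, "chr1", pos, base, alt)
  lab_rc <- sbs96_classify(rc, "chr1", n - pos + 1L,
                           chartr("ACGT", "TGCA", base),
                           chartr("ACGT", "TGCA", alt))
  expect_equal(lab, lab_rc)
})

test_that("all 96 categories are reachable on the synthetic reference", {
  ref <- cached("ref_small", function() make_reference(1, seed = 13))
  idx <- build_context_index(ref)
  labs <- character(0)
  for (key in names(idx$sbs)) {
    pos <- idx$sbs[[key]][1]
    base <- substring(as.character(Biostrings::Views(ref[[1]], pos, pos)),
                      1, 1)
    others <- setdiff(c("A", "C", "G", "T"), base)
    labs <- c(labs, sbs96_classify(ref, "chr1", rep(pos, 3), rep(base, 3),
                                   others))
  }
  expect_setequal(labs, sbs96_categories())
})

test_that("ID83 classification resolves runs, repeats and microhomology", {
  #                            1234567890123456789
  ref <- literal_reference("GGATTTTTTCAGCAGCAGGC")
  # delete one T from the 6-T run (anchor pos 4) -> 6+ homopolymer bin
  expect_equal(id_classify(ref, "chr1", 4L, "AT", "A"), "1:Del:T:6+")
  # insert one T inside the same run -> 5+ existing copies
  expect_equal(id_classify(ref, "chr1", 3L, "A", "AT"), "1:Ins:T:5+")
  # delete one CAG unit of the 3-copy repeat (anchor pos 9)
  expect_equal(id_classify(ref, "chr1", 9L, "CCAG", "C"), "3:Del:R:3")
  # insert another CAG -> 3 existing copies
  expect_equal(id_classify(ref, "chr1", 9L, "C", "CCAG"), "3:Ins:R:3")
  # A-deletion is counted on the pyrimidine strand as T
  ref2 <- literal_reference("GGAACG")
  expect_equal(id_classify(ref2, "chr1", 2L, "GA", "G"), "1:Del:T:2")
  # 1 bp insertion with no neighbouring copy
  expect_equal(id_classify(ref2, "chr1", 5L, "C", "CT"), "1:Ins:T:0")
  # complex substitution is unclassifiable
  expect_true(is.na(id_classify(ref2, "chr1", 2L, "GA", "GC")))
})

test_that("microhomology deletions match a brute-force MH oracle", {
  #          1         2
  # 123456789012345678901234
  s <- "GGTACGTACCCGGGTTTAAGGCAT"
  ref <- literal_reference(s)
  # deletions of length 4 at varying offsets; compare against string oracle
  for (start in 3:18) {
    del_len <- 4L
    unit <- substr(s, start, start + del_len - 1L)
    lab <- id_classify(ref, "chr1", start - 1L,
                       paste0(substr(s, start - 1L, start - 1L), unit),
                       substr(s, start - 1L, start - 1L))
    mh <- oracle_mh(s, start, del_len)
    copies_right <- 0L
    p <- start + del_len
    while (p + del_len - 1L <= nchar(s) &&
           substr(s, p, p + del_len - 1L) == unit) {
      copies_right <- copies_right + 1L; p <- p + del_len
    }
    p <- start - del_len
    while (p >= 1L && substr(s, p, p + del_len - 1L) == unit) {
      copies_right <- copies_right + 1L; p <- p - del_len
    }
    if (copies_right == 0L && mh >= 1L) {
      expect_equal(lab, sprintf("4:Del:M:%d", min(mh, 3L)),
                   info = sprintf("start %d", start))
    } else if (copies_right == 0L && mh == 0L) {
      expect_equal(lab, "4:Del:R:1", info = sprintf("start %d", start))
    }
  }
})

test_that("catalog vectors conserve counts across schemes", {
  cohort <- full_cohort()
  s <- cohort$somatic[["SPS.7"]]$sample
  n <- nrow(s$mutations)
  sbs <- build_catalog(s$mutations, cohort$reference, "SBS96", "x")
  id <- build_catalog(s$mutations, cohort$reference, "ID", "x")
  expect_equal(sum(sbs$counts) + sbs$unclassified + sbs$other_type, n)
  expect_equal(sum(id$counts) + id$unclassified + id$other_type, n)
  # SNVs counted by one scheme are the other scheme's other_type
  expect_equal(sbs$other_type, sum(id$counts) + id$unclassified)
  empty <- build_catalog(s$mutations[0, ], cohort$reference, "SBS96")
  expect_true(all(empty$counts == 0L))
})

test_that("NNLS matches exhaustive grid search on 2-signature problems", {
  catalog <- synthetic_sbs_catalog()
  S <- catalog$signatures
  set.seed(11)
  for (i in 1:10) {
    sigs <- sample(colnames(S), 2L)
    w <- runif(1, 0.1, 0.9)
    v <- as.vector(stats::rmultinom(1, 2000, w * S[, sigs[1]] +
                                      (1 - w) * S[, sigs[2]]))
    names(v) <- rownames(S)
    fit <- nnls_fit(S[, sigs], v / sum(v))
    w_hat <- fit$x[1] / sum(fit$x)
    w_grid <- oracle_grid_refit(v, S[, sigs[1]], S[, sigs[2]])
    expect_lt(abs(w_hat - w_grid), 0.011)
  }
})

test_that("refitting recovers exact and sampled mixtures", {
  catalog <- synthetic_sbs_catalog()
  S <- catalog$signatures
  # exact mixture: weights recovered to numerical precision
  v <- 0.7 * S[, "SBS1"] + 0.3 * S[, "SBS5"]
  counts <- setNames(round(v * 1e6), rownames(S))
  fit <- refit_signatures(counts, catalog)
  expect_equal(unname(fit$weights[c("SBS1", "SBS5")]), c(0.7, 0.3),
               tolerance = 1e-3)
  expect_gt(fit$cosine, 0.9999)
  # single signature: everything else pruned
  v1 <- setNames(round(S[, "SBS1"] * 1e5), rownames(S))
  fit1 <- refit_signatures(v1, catalog)
  expect_equal(names(fit1$weights), "SBS1")
  expect_equal(unname(fit1$weights), 1)
  # sampled 3-way mixture within +/- 0.05
  set.seed(11)
  truth <- c(SBS1 = 0.5, SBS5 = 0.3, SBS15 = 0.2)
  p <- drop(S[, names(truth)] %*% truth)
  v3 <- setNames(as.vector(stats::rmultinom(1, 2000, p)), rownames(S))
  fit3 <- refit_signatures(v3, catalog)
  expect_true(all(names(truth) %in% names(fit3$weights)))
  expect_true(all(abs(fit3$weights[names(truth)] - truth) <= 0.05))
  # zero vector: defined empty result
  fit0 <- refit_signatures(setNames(integer(96), rownames(S)), catalog)
  expect_equal(fit0$n_mutations, 0L)
  expect_equal(length(fit0$weights), 0L)
})

test_that("aetiology flags respect the reporting floor", {
  mk <- function(w) structure(list(weights = w, cosine = 1,
                                   n_mutations = 100L,
                                   pruned = character(0)),
                              class = "refit_result")
  f1 <- flag_aetiology(mk(c(SBS1 = 0.6, SBS5 = 0.4)))
  expect_true(f1$flagged[f1$flag == "clock_like"])
  expect_false(f1$flagged[f1$flag == "mmr_deficiency"])
  f2 <- flag_aetiology(mk(c(SBS1 = 0.7, SBS15 = 0.3)))
  expect_true(f2$flagged[f2$flag == "mmr_deficiency"])
  f3 <- flag_aetiology(mk(c(SBS1 = 0.98, SBS15 = 0.02)))
  expect_false(f3$flagged[f3$flag == "mmr_deficiency"])  # overfit guard
})

test_that("driver report tiers by AAF and highlights hotspots", {
  muts <- rbind(
    test_variant(pos = 1L, gene = "BRAF", hgvsp = "V600E"),
    test_variant(pos = 2L, gene = "BRAF", hgvsp = "V600E"),
    test_variant(pos = 3L, gene = "KRAS", hgvsp = "A146T"),
    test_variant(pos = 4L, gene = "MLH1", hgvsp = "R687Q"),
    test_variant(pos = 5L, gene = "GENE0001", hgvsp = "X1Y"))
  depths <- data.frame(
    vid = muts$vid, ref_count = c(68L, 88L, 80L, 50L, 50L),
    alt_count = c(32L, 12L, 20L, 50L, 50L),
    depth = c(100L, 100L, 100L, 100L, 100L), stringsAsFactors = FALSE)
  s <- list(sample_id = "T1", mutations = muts, depths = depths)
  rep <- driver_report(s)
  expect_equal(nrow(rep), 4L)  # GENE0001 is not a driver
  v600 <- rep[rep$protein_change == "V600E", ]
  expect_setequal(v600$tier, c("high", "low"))
  expect_true(all(v600$hotspot))
  # boundary: AAF exactly 0.20 tiers high
  a146 <- rep[rep$protein_change == "A146T", ]
  expect_equal(a146$tier, "high")
  expect_true(a146$hotspot)
  expect_false(rep$hotspot[rep$gene == "MLH1"])
})
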