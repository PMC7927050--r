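# formats_io: VCF, PED, catalogs, candidate table, BED

test_that("annotated VCF round-trips variant and genotype content", {
  cohort <- germline_cohort()
  fam <- cohort$families[["SPS.3"]]
  path <- tempfile(fileext = ".vcf")
  contigs <- c(chr1 = length(cohort$reference[[1]]))
  write_annotated_vcf(fam$variants, fam$genotypes, path, contigs = contigs)
  back <- read_annotated_vcf(path)

  expect_setequal(back$variants$vid, fam$variants$vid)
  a <- fam$variants[order(fam$variants$vid), ]
  b <- back$variants[order(back$variants$vid), names(a)]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b$maf, a$maf, tolerance = 1e-6)
  expect_equal(b$impact, a$impact)
  expect_equal(b$gene, a$gene)
  expect_equal(b$protein_change, a$protein_change)
  for (col in grep("^pred\\.", names(a), value = TRUE))
    expect_equal(b[[col]], a[[col]])

  key <- function(g) paste(g$vid, g$sample_id)
  ga <- fam$genotypes[order(key(fam$genotypes)), ]
  gb <- back$genotypes[order(key(back$genotypes)), names(ga)]
  rownames(ga) <- rownames(gb) <- NULL
  expect_equal(gb$gt, ga$gt)
  expect_equal(gb$alt_count, ga$alt_count)
  expect_equal(gb$depth, ga$depth)
})

test_that("multi-allelic records decompose with allele-count conservation", {
  txt <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"i\">",
    "##INFO=<ID=PAF_gnomAD,Number=A,Type=Float,Description=\"f\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "10", ".", "A", "C,T", ".", "PASS",
          "GENE=G1;IMPACT=missense,synonymous;PAF_gnomAD=0.001,0.002",
          "GT:AD:DP", "1/2:0,40,41:81", sep = "\t"),
    paste("chr1", "20", ".", "G", "A", ".", "PASS",
          "GENE=G2;IMPACT=missense", "GT:AD:DP", "0/1:30,30:60",
          sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(txt, f)
  out <- read_annotated_vcf(f)
  # 3 ALT alleles in input -> 3 decomposed variants, locus shared by two
  expect_equal(nrow(out$variants), 3L)
  expect_equal(sum(out$variants$pos == 10L), 2L)
  expect_setequal(out$variants$alt[out$variants$pos == 10L], c("C", "T"))
  # per-alt INFO is split correctly
  expect_equal(out$variants$impact[out$variants$vid == "chr1:10:A:C"],
               "missense")
  expect_equal(out$variants$maf[out$variants$vid == "chr1:10:A:T"], 0.002)
  # 1/2 genotype is het for each decomposed allele, with per-alt AD
  g <- out$genotypes
  expect_equal(g$gt[g$vid == "chr1:10:A:C"], "het")
  expect_equal(g$alt_count[g$vid == "chr1:10:A:C"], 40L)
  expect_equal(g$alt_count[g$vid == "chr1:10:A:T"], 41L)
})

test_that("maf derives as max over present frequencies, zero when absent", {
  v <- test_variant(maf = NA_real_)
  v$paf.KG <- NA_real_
  path <- tempfile(fileext = ".vcf")
  v2 <- test_variant(pos = 200L, maf = 3.6e-5)
  v2$paf.KG <- 1e-6
  write_annotated_vcf(rbind(v, v2), empty_gt <- data.frame(
    vid = character(0), sample_id = character(0), gt = character(0),
    ref_count = integer(0), alt_count = integer(0), depth = integer(0)),
    path, contigs = c(chr1 = 1000L))
  back <- read_annotated_vcf(path)
  expect_equal(back$variants$maf[back$variants$pos == 100L], 0)
  expect_equal(back$variants$maf[back$variants$pos == 200L], 3.6e-5,
               tolerance = 1e-9)
})

test_that("unknown impact strings warn and fall back to other", {
  expect_warning(out <- normalize_impact(c("missense", "weird_thing")),
                 "weird_thing")
  expect_equal(out, c("missense", "other"))
})

test_that("pedigree reading enforces family invariants", {
  path <- tempfile(fileext = ".ped")
  writeLines(c("FAM1\tS1\t0\t0\t1\t2",
               "FAM1\tS2\t0\t0\t2\t2"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "sps_pedigree")
  expect_equal(sum(ped$affected), 2L)

  writeLines(c(paste("FAM2", sprintf("S%d", 1:6), "0\t0\t1\t2",
                     sep = "\t")), path)
  expect_equal(sum(read_pedigree(path)$affected), 6L)

  writeLines(c("FAM1\tS1\t0\t0\t1\t2", "FAM1\tS1\t0\t0\t1\t2"), path)
  expect_error(read_pedigree(path), "duplicate")

  writeLines(c("FAM1\tS1\t0\t0\t1\t1"), path)
  expect_error(read_pedigree(path), "no affected")
})

test_that("signature catalogs round-trip and validate", {
  cat_sbs <- synthetic_sbs_catalog()
  path <- tempfile(fileext = ".tsv")
  write_signature_catalog(cat_sbs, path)
  back <- read_signature_catalog(path)
  expect_equal(back$scheme, "SBS96")
  expect_equal(back$signatures, cat_sbs$signatures, tolerance = 1e-6)
  expect_true(all(abs(colSums(back$signatures) - 1) < 1e-9))

  cat_id <- synthetic_id_catalog()
  write_signature_catalog(cat_id, path)
  expect_equal(read_signature_catalog(path)$scheme, "ID")

  broken <- cat_sbs
  broken$signatures[, 1] <- broken$signatures[, 1] * 0.9
  write_signature_catalog(broken, path)
  expect_error(read_signature_catalog(path), "not summing to 1")

  neg <- cat_sbs$signatures
  neg[1, 1] <- -neg[1, 1]
  expect_error(new_signature_catalog(neg), "non-negative")

  bad_cats <- cat_sbs$signatures[1:50, ]
  expect_error(new_signature_catalog(bad_cats), "neither")
})

test_that("candidate table writes deterministically with evidence labels", {
  path <- tempfile(fileext = ".tsv")
  cand <- data.frame(
    gene = c("HIC1", "ANXA10"), family_id = c("SPS.14", "SPS.12"),
    variant = c("Q432R", "D231G"), predictor_score = c(3L, 6L),
    max_pop_af = c(NA, 3.6e-5),
    evidence = c("G-S paired analysis", "G"),
    selection_criterion = c("Involvement in cancer development",
                            "Histological marker"),
    stringsAsFactors = FALSE)
  write_candidate_table(cand, path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(tab$gene, c("ANXA10", "HIC1"))  # family then gene order
  expect_equal(tab$evidence,
               c("G", "G-S paired analysis"))
  expect_equal(tab$max_pop_af, c("3.6e-05", "N/A"))

  write_candidate_table(cand[0, ], path)
  expect_equal(length(readLines(path)), 1L)  # header only
})

test_that("callable BED round-trips through 0-based half-open encoding", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1001, 5001),
                                                c(2000, 9000)))
  path <- tempfile(fileext = ".bed")
  write_callable_bed(gr, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, c(1000L, 5000L))  # 0-based starts on disk
  back <- read_callable_bed(path)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(gr))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(gr))
})

test_that("a written cohort loads back through the standard readers", {
  dir <- file.path(tempdir(), "cohort_rt")
  cfg <- default_sim_config(4L)
  cfg$families <- cfg$families[1:2]
  cfg$affected_counts <- cfg$affected_counts[1:2]
  cfg$somatic <- cfg$somatic[cfg$somatic$family_id %in% cfg$families, ]
  co <- simulate_cohort(cfg, outdir = dir)
  back <- load_cohort_dir(dir)
  expect_equal(names(back$families), names(co$families))
  v0 <- co$families[["SPS.1"]]$variants
  v1 <- back$families[["SPS.1"]]$variants
  expect_setequal(v1$vid, v0$vid)
  s0 <- co$somatic[["SPS.1"]]$sample
  s1 <- back$somatic[["SPS.1"]]$sample
  expect_setequal(s1$mutations$vid, s0$mutations$vid)
  expect_equal(footprint_mb(s1$callable), footprint_mb(s0$callable))
  expect_equal(sort(back$panel$vid), sort(co$panel$vid))
})
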