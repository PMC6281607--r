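test_that("read_cohort round-trips a small VCF with DP/GQ/AD", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    paste("chr1", 100, ".", "A", "C", ".", "PASS",
          "GENE=G1;EFFECT=missense_variant;PRED=d|d|b", "GT:DP:GQ:AD",
          "0/0:30:99:30,0", "0/1:25:80:13,12", "1/1:40:99:0,40",
          sep = "\t"),
    paste("chr1", 200, ".", "G", "T", ".", "PASS",
          "GENE=G1;EFFECT=stop_gained;LOF=1", "GT:DP:GQ:AD",
          "0/1:22:70:11,11", "./.:.:.:.", "0/0:35:99:35,0",
          sep = "\t")))
  sheet <- write_test_sheet(tempfile(fileext = ".tsv"),
                            c("S1", "S2", "S3"),
                            c("case", "control", "control"))
  x <- read_cohort(vcf, sheet)
  expect_s3_class(x, "cohort_matrix")
  expect_equal(dim(x$dosage), c(3L, 2L))
  expect_equal(unname(x$dosage[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(x$dosage[, 2]), c(1L, NA_integer_, 0L))
  expect_equal(unname(x$dp[, 1]), c(30L, 25L, 40L))
  expect_equal(unname(x$gq[, 2]), c(70L, NA_integer_, 99L))
  expect_equal(unname(x$ad_alt[, 1]), c(0L, 12L, 40L))
  expect_equal(x$sites$gene, c("G1", "G1"))
  expect_equal(x$sites$effect_term[2], "stop_gained")
  expect_true(x$sites$lof_flag[2])
  expect_equal(x$sites$pred1[1], "damaging")
  expect_equal(attr(x, "load_report")$n_unannotated, 0L)
})

test_that("read_cohort errors name the sample missing from the sheet", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        paste("chr1", 100, ".", "A", "C", ".", "PASS", ".",
                              "GT", "0/0", "0/1", "0/0", sep = "\t"),
                        samples = c("S1", "S9", "S3"))
  sheet <- write_test_sheet(tempfile(fileext = ".tsv"), c("S1", "S3"),
                            c("case", "control"))
  expect_error(read_cohort(vcf, sheet), "S9")
})

test_that("annotation sidecar wins over INFO, with a warning on conflict", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        paste("chr1", 100, ".", "A", "C", ".", "PASS",
                              "GENE=WRONG;EFFECT=missense_variant;PRED=b|b|b",
                              "GT", "0/1", "0/0", "0/0", sep = "\t"))
  sheet <- write_test_sheet(tempfile(fileext = ".tsv"),
                            c("S1", "S2", "S3"),
                            c("case", "control", "control"))
  ann <- tempfile(fileext = ".tsv")
  writeLines(c("site_id\tgene\teffect_term\tlof_flag\tpred1\tpred2\tpred3",
               "chr1:100:A:C\tRIGHT\tmissense_variant\tFALSE\td\td\td"),
             ann)
  expect_warning(x <- read_cohort(vcf, sheet, ann), "override")
  expect_equal(x$sites$gene, "RIGHT")
  expect_equal(x$sites$pred3, "damaging")
})

test_that("unannotated sites are retained and flagged in the load report", {
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        paste("chr1", 100, ".", "A", "C", ".", "PASS", ".",
                              "GT", "0/1", "0/0", "0/0", sep = "\t"))
  sheet <- write_test_sheet(tempfile(fileext = ".tsv"),
                            c("S1", "S2", "S3"),
                            c("case", "control", "control"))
  x <- read_cohort(vcf, sheet)
  expect_equal(n_sites(x), 1L)
  expect_false(x$sites$annotated)
  expect_equal(x$sites$pred1, "missing")
  expect_equal(attr(x, "load_report")$unannotated, "chr1:100:A:C")
})

test_that("multi-allelic splitting counts each alternate allele separately", {
  # identity on a bi-allelic record
  one <- split_multiallelic("chr1", 100L, "A", "C", c("0/1", "1/1"))
  expect_length(one, 1L)
  expect_equal(one[[1]]$dosage, c(1L, 2L))
  # het across two alts: one copy each
  two <- split_multiallelic("chr1", 100L, "A", c("C", "G"), "1/2")
  expect_equal(two[[1]]$dosage, 1L)
  expect_equal(two[[2]]$dosage, 1L)
  # hom for the first alt: (2, 0)
  hom <- split_multiallelic("chr1", 100L, "A", c("C", "G"), "1/1")
  expect_equal(hom[[1]]$dosage, 2L)
  expect_equal(hom[[2]]$dosage, 0L)
  # missing and malformed genotypes
  expect_true(is.na(split_multiallelic("chr1", 1L, "A", "C", "./.")[[1]]$dosage))
  expect_error(split_multiallelic("chr1", 1L, "A", "C", "0/x"), "malformed")
})

test_that("splitting conserves total alternate-allele count per sample", {
  set.seed(42)
  for (rep in 1:50) {
    n_alt <- sample(2:4, 1)
    gts <- replicate(8, paste(sample(0:n_alt, 2, replace = TRUE),
                              collapse = "/"))
    split <- split_multiallelic("chr1", 500L, "A",
                                c("C", "G", "T", "AA")[seq_len(n_alt)], gts)
    total <- Reduce(`+`, lapply(split, `[[`, "dosage"))
    expected <- vapply(strsplit(gts, "/"),
                       function(a) sum(as.integer(a) > 0), integer(1))
    expect_equal(total, expected)
  }
})

test_that("normalization left-aligns and is sequence-equivalent", {
  # SNV unchanged
  snv <- normalize_variant(list(chrom = "chr1", pos = 100L, ref = "A",
                                alt = "C"), "GA", 99L)
  expect_equal(snv$pos, 100L)
  expect_equal(snv$ref, "A")
  # single-T deletion in a T-run shifts to the leftmost placement
  del <- normalize_variant(list(chrom = "chr1", pos = 102L, ref = "CTT",
                                alt = "CT"), "ACTTTG", 101L)
  expect_equal(list(del$pos, del$ref, del$alt), list(102L, "CT", "C"))
  expect_equal(apply_edit("ACTTTG", 101L, 102L, "CTT", "CT"),
               apply_edit("ACTTTG", 101L, del$pos, del$ref, del$alt))
  # mismatching reference window is an error
  expect_error(normalize_variant(list(chrom = "chr1", pos = 102L,
                                      ref = "GG", alt = "G"),
                                 "ACTTTG", 101L), "disagrees")
})

test_that("normalization is idempotent and equivalence-preserving on random indels", {
  set.seed(7)
  for (i in 1:500) {
    cs <- random_indel_case()
    site <- list(chrom = "chr1", pos = cs$pos, ref = cs$ref, alt = cs$alt)
    n1 <- normalize_variant(site, cs$window, cs$start)
    n2 <- normalize_variant(n1, cs$window, cs$start)
    expect_identical(n1[c("pos", "ref", "alt")], n2[c("pos", "ref", "alt")])
    expect_equal(apply_edit(cs$window, cs$start, cs$pos, cs$ref, cs$alt),
                 apply_edit(cs$window, cs$start, n1$pos, n1$ref, n1$alt))
  }
})

test_that("BED masks use half-open intervals and merge overlaps", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t15\t30", "chr2\t5\t6"), bed)
  mask <- read_mask(bed)
  expect_equal(nrow(mask$chr1), 1L)          # [10,20) + [15,30) -> [10,30)
  expect_equal(unname(mask$chr1[1, ]), c(10L, 30L))
  expect_true(mask_contains(mask, "chr1", 11L))   # 1-based 11 -> 0-based 10
  expect_true(mask_contains(mask, "chr1", 30L))
  expect_false(mask_contains(mask, "chr1", 31L))  # half-open end
  expect_false(mask_contains(mask, "chr3", 11L))
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", bad)
  expect_error(read_mask(bad), "start >= end")
  bad2 <- tempfile(fileext = ".bed")
  writeLines("chr1\t20", bad2)
  expect_error(read_mask(bad2), "unparsable")
})

test_that("results writer round-trips, including empty and Inf cases", {
  path <- tempfile(fileext = ".tsv")
  write_results(data.frame(), path)
  empty <- read_results(path)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene", "class", "p") %in% names(empty)))
  set.seed(3)
  res <- data.frame(gene = sprintf("G%02d", 1:20),
                    class = sample(collapse_classes(), 20, replace = TRUE),
                    case_carriers = rbinom(20, 92, 0.05), case_n = 92L,
                    control_carriers = rbinom(20, 1051, 0.01),
                    control_n = 1051L,
                    or = c(Inf, runif(19, 0.5, 20)),
                    or_cmle = runif(20, 0.5, 20),
                    ci_low = runif(20, 0, 2), ci_high = c(Inf, runif(19, 2, 99)),
                    p = runif(20), q = runif(20),
                    bonferroni_significant = FALSE,
                    robustness = "reinforced", stringsAsFactors = FALSE)
  write_results(res, path)
  back <- read_results(path)
  expect_equal(back, res[, names(back)])
})

test_that("the study-sized fixture cohort loads with 92 cases and 1051 controls", {
  d <- tempfile("fix")
  fx <- study_fixtures(d)
  x <- read_cohort(fx$paths$vcf, fx$paths$sample_sheet,
                   fx$paths$annotation)
  expect_equal(sum(x$samples$status == "case"), 92L)
  expect_equal(sum(x$samples$status == "control"), 1051L)
  expect_identical(x$dosage, fx$cohort$dosage[, colnames(x$dosage)])
  unlink(d, recursive = TRUE)
})
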